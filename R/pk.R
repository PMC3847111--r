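#' Pharmacokinetic parameter sets
#'
#' Returns the fixed two-compartment PK constants for methylprednisolone.
#' The IV/infusion model is parameterized by clearance and central volume
#' (`CL`, `Vp`, `k12`, `k21`); the IM model by `kel`, `Vp`, `k12`, `k21`
#' together with bioavailability `F`, the fraction `Fr` absorbed through the
#' faster pathway, and absorption rate constants `ka1`, `ka2`. Both
#' parameterizations are kept exactly as reported rather than converted into
#' one another.
#'
#' @param route `"iv"` (injection and infusion regimens) or `"im"`.
#' @return Named list of PK constants.
#' @export
pk_params <- function(route = c("iv", "im")) {
  route <- match.arg(route)
  load_model_config()$pk[[route]]
}

#' Define a dosing regimen
#'
#' @param route One of `"iv_bolus"`, `"im_bolus"`, `"sc_infusion"`.
#' @param amount Dose in mg/kg for boluses, infusion rate in mg/kg/h for
#'   `"sc_infusion"`.
#' @param t_start Start time (h), default 0.
#' @param t_stop Stop time (h); required for infusions.
#' @return A `dose_regimen` object.
#' @export
dose_regimen <- function(route = c("iv_bolus", "im_bolus", "sc_infusion"),
                         amount, t_start = 0, t_stop = NULL) {
  route <- match.arg(route)
  if (amount < 0) stop("dose amount must be >= 0")
  if (t_start < 0) stop("t_start must be >= 0")
  if (route == "sc_infusion") {
    if (is.null(t_stop)) stop("infusion regimens need t_stop")
    if (t_stop <= t_start) stop("t_stop must exceed t_start")
  }
  structure(
    list(route = route, amount = amount, t_start = t_start, t_stop = t_stop),
    class = "dose_regimen"
  )
}

#' Saline (zero-dose) regimen helper
#' @param t_end Study length in hours (used for the formal infusion window).
#' @return A zero-rate infusion regimen.
#' @export
saline_regimen <- function(t_end = 168) {
  dose_regimen("sc_infusion", amount = 0, t_start = 0, t_stop = t_end)
}

# macro-constants of the 2-compartment disposition system
.disposition <- function(k10, k12, k21) {
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(s^2 - 4 * p)
  l1 <- (s + disc) / 2
  l2 <- (s - disc) / 2
  A <- (l1 - k21) / (l1 - l2)
  B <- (k21 - l2) / (l1 - l2)
  list(l1 = l1, l2 = l2, A = A, B = B)
}

# unit IV bolus response (dose 1 mg/kg), central concentration mg/L
.conc_bolus_unit <- function(t, Vp, d) {
  (d$A * exp(-d$l1 * t) + d$B * exp(-d$l2 * t)) / Vp
}

# zero-order infusion at unit rate starting at t = 0 (no stop)
.conc_infusion_unit <- function(t, Vp, d) {
  (d$A / d$l1 * (1 - exp(-d$l1 * t)) + d$B / d$l2 * (1 - exp(-d$l2 * t))) / Vp
}

# first-order absorption of a unit bioavailable amount at rate ka
.conc_absorption_unit <- function(t, Vp, d, ka) {
  term <- function(coef, lam) {
    if (abs(ka - lam) < 1e-12) {
      coef * ka * t * exp(-lam * t)
    } else {
      coef * ka * (exp(-lam * t) - exp(-ka * t)) / (ka - lam)
    }
  }
  (term(d$A, d$l1) + term(d$B, d$l2)) / Vp
}

#' Plasma methylprednisolone concentration
#'
#' Closed-form central-compartment concentration of the two-compartment model
#' for the three dosing routes. IV bolus gives the biexponential profile with
#' `C(0) = Dose/Vp`; infusions use zero-order input with washout after
#' `t_stop` by superposition; IM dosing superimposes two first-order
#' absorption pathways carrying `F*Dose*Fr` and `F*Dose*(1-Fr)`.
#'
#' @param t Time(s) in hours, `>= 0`.
#' @param regimen A [dose_regimen()].
#' @param params PK constants; defaults to the packaged set for the route.
#' @return Concentration(s) in mg/L.
#' @export
plasma_concentration <- function(t, regimen, params = NULL) {
  if (any(t < 0)) stop("negative time")
  if (!inherits(regimen, "dose_regimen")) stop("regimen must be a dose_regimen")
  if (is.null(params)) {
    params <- pk_params(if (regimen$route == "im_bolus") "im" else "iv")
  }
  if (regimen$amount == 0) {
    return(rep(0, length(t)))
  }
  tr <- pmax(t - regimen$t_start, 0)
  on <- as.numeric(t >= regimen$t_start)
  conc <- switch(regimen$route,
    iv_bolus = {
      .check_pk(params, c("CL", "Vp", "k12", "k21"), "iv_bolus")
      d <- .disposition(params$CL / params$Vp, params$k12, params$k21)
      regimen$amount * .conc_bolus_unit(tr, params$Vp, d)
    },
    sc_infusion = {
      .check_pk(params, c("CL", "Vp", "k12", "k21"), "sc_infusion")
      d <- .disposition(params$CL / params$Vp, params$k12, params$k21)
      dur <- regimen$t_stop - regimen$t_start
      base <- .conc_infusion_unit(tr, params$Vp, d)
      off <- ifelse(tr > dur, .conc_infusion_unit(pmax(tr - dur, 0), params$Vp, d), 0)
      regimen$amount * (base - off)
    },
    im_bolus = {
      .check_pk(params, c("kel", "Vp", "k12", "k21", "F", "Fr", "ka1", "ka2"), "im_bolus")
      d <- .disposition(params$kel, params$k12, params$k21)
      bio <- params$F * regimen$amount
      bio * (params$Fr * .conc_absorption_unit(tr, params$Vp, d, params$ka1) +
        (1 - params$Fr) * .conc_absorption_unit(tr, params$Vp, d, params$ka2))
    }
  )
  pmax(conc * on, 0)
}

.check_pk <- function(params, need, route) {
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("PK parameters missing for route ", route, ": ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
}

#' Convert a mass concentration to nanomolar
#'
#' @param c_mg_per_L Concentration in mg/L, `>= 0`.
#' @param mw Molecular weight in g/mol; defaults to [MPL_MW].
#' @return Concentration in nM (`c * 1e6 / mw`).
#' @export
to_nanomolar <- function(c_mg_per_L, mw = MPL_MW) {
  if (any(c_mg_per_L < 0)) stop("concentration must be >= 0")
  c_mg_per_L * 1e6 / mw
}

#' Concentration forcing function for a regimen
#'
#' Returns a vectorized function of time giving the plasma drug concentration
#' in nM, used as the driving input of every receptor model.
#'
#' @inheritParams plasma_concentration
#' @param mw Molecular weight for the nM conversion.
#' @return `function(t)` returning nM.
#' @export
concentration_fn <- function(regimen, params = NULL, mw = MPL_MW) {
  force(regimen); force(params); force(mw)
  function(t) to_nanomolar(plasma_concentration(t, regimen, params), mw)
}

#' Tidy PK time course
#'
#' @inheritParams plasma_concentration
#' @return `data.frame` with `time_h`, `conc_mg_per_L`, `conc_nM`.
#' @export
pk_time_course <- function(t, regimen, params = NULL) {
  conc <- plasma_concentration(t, regimen, params)
  data.frame(time_h = t, conc_mg_per_L = conc, conc_nM = to_nanomolar(conc))
}
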