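#' Systemic glucose-insulin-FFA parameters
#'
#' Constants of the coupled plasma glucose, insulin and free-fatty-acid
#' turnover system, with per-study-arm baselines `(G0, I0, FFA0)` selected by
#' `study` and `group` and never pooled. The FFA-to-insulin sensitivity
#' `S_FI` takes the acute value (13.3 per mM) for single-dose regimens and
#' the chronic value (28.9 per mM) for infusion regimens, where it is
#' additionally modulated by `exp(-kFI * t)`.
#'
#' @param study One of `"chronic_infusion"`, `"iv_injection"`,
#'   `"short_infusion"`, `"circadian_nadir"`.
#' @param group Arm label inside the study (e.g. `"0.3"`, `"50"`, `"im50"`,
#'   `"saline"`).
#' @param regimen_kind `"acute"` or `"chronic"`; selects `S_FI` and the
#'   presence of the `exp(-kFI t)` factor. Inferred from the study when
#'   `NULL` (infusion studies are chronic).
#' @return Named list of systemic constants including the selected `S_FI`.
#' @export
systemic_params <- function(study = "chronic_infusion", group = "saline",
                            regimen_kind = NULL) {
  raw <- load_model_config()$systemic
  p <- raw
  bl <- raw$baselines[[study]]
  if (is.null(bl)) stop("unknown study '", study, "'")
  arm <- bl[[group]]
  if (is.null(arm)) {
    stop("unknown group '", group, "' for study ", study,
      "; available: ", paste(names(bl), collapse = ", "))
  }
  p$G0 <- arm$G0; p$I0 <- arm$I0; p$FFA0 <- arm$FFA0
  p$baselines <- NULL
  if (is.null(regimen_kind)) {
    regimen_kind <- if (study %in% c("chronic_infusion", "short_infusion")) "chronic" else "acute"
  }
  if (!regimen_kind %in% c("acute", "chronic")) {
    stop("regimen_kind must be 'acute' or 'chronic'")
  }
  p$regimen_kind <- regimen_kind
  p$S_FI <- raw$S_FI[[regimen_kind]]
  p
}

#' Zero-order production rates from the steady-state condition
#'
#' The system is assumed stationary at time zero, which fixes the zero-order
#' production rates in closed form. With all stimulus deviations zero at
#' baseline and food intake (when modeled) at `Food0`:
#' \deqn{ks_G = kd_G G^0 / (1 + S_{Food} Food^0/24), \quad
#'       ks_I = kd_I I^0, \quad ks_F = kd_F FFA^0.}
#'
#' @param params Constants from [systemic_params()].
#' @param drivers0 Baseline driver list; only `Food` (kcal/day) is consumed,
#'   and only when `use_food` is `TRUE`.
#' @param use_food Whether exogenous food input enters glucose production
#'   (`FALSE` for studies where intake was not monitored, in which case
#'   `ks_G` is a combined endogenous/exogenous indicator).
#' @return Named vector `(ks_G, ks_I, ks_F)`.
#' @export
steady_state_rates <- function(params, drivers0 = list(Food = 0), use_food = FALSE) {
  if (any(c(params$G0, params$I0, params$FFA0) <= 0)) {
    stop("baselines must be positive")
  }
  foodfac <- if (use_food) 1 + params$S_Food * drivers0$Food / 24 else 1
  c(
    ks_G = params$kd_G * params$G0 / foodfac,
    ks_I = params$kd_I * params$I0,
    ks_F = params$kd_F * params$FFA0
  )
}

#' Fractional glucose-production gain from food intake
#'
#' Converts daily intake to kcal/h and applies the linear efficiency
#' `S_Food`; e.g. 120 kcal/day is 5 kcal/h, giving a fractional increase of
#' `0.000346 * 5 = 0.00173` (about 0.2%).
#'
#' @param Food Food intake in kcal/day, `>= 0`.
#' @param params Constants with `S_Food`; defaults to packaged values.
#' @return Dimensionless fractional increase in glucose production.
#' @export
food_glucose_gain <- function(Food, params = NULL) {
  if (any(Food < 0)) stop("food intake must be >= 0")
  if (is.null(params)) params <- load_model_config()$systemic
  params$S_Food * Food / 24
}

#' Systemic glucose-insulin-FFA right-hand side
#'
#' Glucose production is scaled by the rise of hepatic PEPCK activity
#' (linear), the rise of hepatic cAMP (Emax) and food intake (linear);
#' utilization is stimulated by the insulin excursion from baseline with the
#' sensitivity attenuated by the muscle IRS-1 mRNA ratio raised to
#' `lambda1`. Insulin production is driven by the glucose and FFA rises;
#' under chronic infusion the FFA drive is damped by `exp(-kFI t)`. FFA
#' production is stimulated by the adipose nuclear complex through an Emax
#' function and FFA disposal is enhanced by the insulin rise:
#' \deqn{dG/dt = ks_G (1 + S^{PEPCK} \Delta PEPCK)(1 + S_{max}^{cAMP}
#'   \Delta cAMP/(SC_{50}^{cAMP} + \Delta cAMP))(1 + S_{Food} Food/24)
#'   - kd_G (1 + S_{IG} (IRS1 ratio)^{\lambda_1} \Delta I) G}
#' \deqn{dI/dt = ks_I (1 + S_{GI} \Delta G + S_{FI} e^{-k_{FI} t} \Delta FFA) - kd_I I}
#' \deqn{dFFA/dt = ks_F (1 + S_{max}^F DRn/(SC_{50}^F + DRn))
#'   - kd_F (1 + S_{IF} \Delta I^+) FFA}
#' Stimulation-only deviations (`dPEPCK`, `dcAMP`, `dG`, `dFFA`, and `dI` in
#' the FFA equation) are floored at zero; the insulin deviation driving
#' glucose disposal is signed so insulin below baseline reduces utilization,
#' with the whole utilization factor floored at zero.
#'
#' @param state Named vector `(G, I, FFA)`.
#' @param drivers List with `PEPCK`, `cAMP`, `Food` (kcal/day), `IRS1_ratio`,
#'   `DRn` (adipose).
#' @param params Constants from [systemic_params()] (holds the selected
#'   `S_FI` and `regimen_kind`).
#' @param t Hours since infusion start (the `exp(-kFI t)` clock).
#' @param rates Zero-order rates from [steady_state_rates()].
#' @param use_food Include the food term in glucose production.
#' @return Named derivative vector.
#' @export
systemic_rhs <- function(state, drivers, params, t = 0,
                         rates = NULL, use_food = FALSE) {
  if (is.null(rates)) {
    rates <- steady_state_rates(params, list(Food = drivers$Food), use_food)
  }
  if (!params$regimen_kind %in% c("acute", "chronic")) {
    stop("unknown regimen_kind")
  }
  G <- state[["G"]]; I <- state[["I"]]; FFA <- state[["FFA"]]
  dpepck <- max(drivers$PEPCK - params$PEPCK0_ref, 0)
  dcamp <- max(drivers$cAMP - params$cAMP0_ref, 0)
  dG <- max(G - params$G0, 0)
  dI_signed <- I - params$I0
  dI_pos <- max(dI_signed, 0)
  dFFA <- max(FFA - params$FFA0, 0)
  irs <- max(drivers$IRS1_ratio, 1e-6)
  foodfac <- if (use_food) 1 + params$S_Food * drivers$Food / 24 else 1
  ffi <- if (params$regimen_kind == "chronic") exp(-params$kFI * t) else 1
  prod_G <- rates[["ks_G"]] *
    (1 + params$S_PEPCK * dpepck) *
    (1 + params$Smax_cAMP * dcamp / (params$SC50_cAMPG + dcamp)) *
    foodfac
  util_G <- params$kd_G * max(1 + params$S_IG * irs^params$lambda1 * dI_signed, 0) * G
  prod_I <- rates[["ks_I"]] * (1 + params$S_GI * dG + params$S_FI * ffi * dFFA)
  prod_F <- rates[["ks_F"]] *
    (1 + params$Smax_F * drivers$DRn / (params$SC50_F + drivers$DRn))
  util_F <- params$kd_F * (1 + params$S_IF * dI_pos) * FFA
  c(G = prod_G - util_G, I = prod_I - params$kd_I * I, FFA = prod_F - util_F)
}

#' Attach baseline driver references to systemic constants
#'
#' The PEPCK and cAMP stimulation terms act on deviations from the liver
#' baselines, so those references must travel with the systemic parameters.
#'
#' @param params Systemic constants.
#' @param liver Liver constants from [liver_params()].
#' @return Systemic constants with `PEPCK0_ref`, `cAMP0_ref`.
#' @export
with_liver_refs <- function(params, liver) {
  params$PEPCK0_ref <- liver$PEPCK0
  params$cAMP0_ref <- liver$cAMP0
  params
}
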