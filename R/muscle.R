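#' Skeletal-muscle insulin-signaling cascade parameters
#'
#' Constants for IL6R1 mRNA induction, the transit-compartment delay chain,
#' and IRS-1 mRNA turnover. IL6R1 and IRS-1 mRNA are simulated in
#' baseline-relative units (their absolute baselines are not reported), so
#' both baselines equal 1 and all downstream use is ratio-based. The
#' zero-order synthesis rates are derived for drug-free stationarity; for
#' IRS-1 this includes the baseline transit-signal inhibition
#' `ks_m = kd_IRS1m / (1 - 1/(IC50_IL6R1 + 1))`.
#'
#' @param N Number of transit compartments (reported value 5; parameterized
#'   for testing).
#' @return Named list of muscle-cascade constants.
#' @export
muscle_params <- function(N = NULL) {
  p <- load_model_config()$muscle_cascade
  if (!is.null(N)) p$N <- as.integer(N)
  if (p$N < 1 || p$N != round(p$N)) stop("N must be a positive integer")
  p$IL6R1m0 <- 1
  p$IRS1m0 <- 1
  p$ks_IL6R1m <- p$kd_IL6R1m * p$IL6R1m0
  inh0 <- (1 - p$IL6R1m0 / (p$IC50_IL6R1 + p$IL6R1m0))
  p$ks_m <- p$kd_IRS1m * p$IRS1m0 / inh0
  p
}

#' Baseline muscle-cascade state
#' @param params Constants from [muscle_params()].
#' @return Named state vector with all transit compartments at the IL6R1 mRNA
#'   baseline.
#' @export
muscle_init <- function(params) {
  y <- c(params$IL6R1m0, rep(params$IL6R1m0, params$N), params$IRS1m0)
  names(y) <- c("IL6R1m", paste0("TC", seq_len(params$N)), "IRS1m")
  y
}

#' Muscle cascade right-hand side
#'
#' IL6R1 mRNA production is stimulated by the nuclear drug-receptor complex
#' through an Emax function; the signal is relayed through `N` transit
#' compartments at rate `ke`; IRS-1 mRNA synthesis is inhibited both directly
#' by DRn and by the delayed transit signal:
#' \deqn{dIL6R1m/dt = ks (1 + S_{max} DRn/(SC_{50} + DRn)) - kd_{IL6R1m} IL6R1m}
#' \deqn{dTC_1/dt = k_e (IL6R1m - TC_1), \quad dTC_i/dt = k_e (TC_{i-1} - TC_i)}
#' \deqn{dIRS1m/dt = ks_m (1 - DRn/(IC50_{DRn} + DRn)) (1 - TC_N/(IC50_{IL6R1} + TC_N)) - kd_{IRS1m} IRS1m}
#'
#' @param state Named vector `(IL6R1m, TC1..TCN, IRS1m)`, all `>= 0`.
#' @param DRn Muscle nuclear drug-receptor complex (fmol/mg protein), `>= 0`.
#' @param params Constants from [muscle_params()].
#' @return Named derivative vector.
#' @export
muscle_rhs <- function(state, DRn, params) {
  if (DRn < 0 || any(state < 0)) stop("muscle state and DRn must be >= 0")
  N <- params$N
  IL6R1m <- state[["IL6R1m"]]
  TC <- state[paste0("TC", seq_len(N))]
  IRS1m <- state[["IRS1m"]]
  dIL <- params$ks_IL6R1m * (1 + params$Smax_IL6R1m * DRn / (params$SC50_IL6R1m + DRn)) -
    params$kd_IL6R1m * IL6R1m
  upstream <- c(IL6R1m, TC[-N])
  dTC <- params$ke * (upstream - TC)
  inh <- (1 - DRn / (params$IC50_DRn + DRn)) *
    (1 - TC[[N]] / (params$IC50_IL6R1 + TC[[N]]))
  dIRS <- params$ks_m * inh - params$kd_IRS1m * IRS1m
  out <- c(dIL, dTC, dIRS)
  names(out) <- names(state)
  out
}

#' IRS-1 mRNA ratio
#'
#' Ratio of IRS-1 mRNA to its baseline, floored at a small positive value so
#' the power term `ratio^lambda1` in the systemic module stays finite.
#'
#' @param state Muscle state vector (or an `IRS1m` value).
#' @param baseline Baseline IRS-1 mRNA, `> 0`.
#' @param floor Lower clip, default 1e-6.
#' @return Dimensionless ratio.
#' @export
irs1_ratio <- function(state, baseline = 1, floor = 1e-6) {
  if (baseline <= 0) stop("IRS1m baseline must be > 0")
  x <- if (!is.null(names(state)) && "IRS1m" %in% names(state)) state[["IRS1m"]] else state
  pmax(x / baseline, floor)
}

#' Simulate the muscle cascade driven by a muscle DRn trace
#'
#' @param regimen A [dose_regimen()].
#' @param t_grid Output times (h).
#' @param drn_fn Optional function of time returning muscle DRn.
#' @param params Optional constants override.
#' @return `data.frame` with `time_h`, `IL6R1m_rel`, `TC1..TCN`, `IRS1m_rel`.
#' @export
simulate_muscle <- function(regimen, t_grid = NULL, drn_fn = NULL, params = NULL) {
  if (is.null(t_grid)) t_grid <- dense_grid(168)
  if (is.null(params)) params <- muscle_params()
  if (is.null(drn_fn)) {
    rec <- simulate_receptor("muscle", regimen, t_grid)
    drn_fn <- stats::splinefun(rec$time_h, rec$DRn, method = "natural")
  }
  rhs <- function(t, y, p) list(muscle_rhs(pmax(y, 0), max(drn_fn(t), 0), p))
  out <- deSolve::ode(
    y = muscle_init(params), times = .with_events(t_grid, regimen), func = rhs,
    parms = params, method = "lsoda", rtol = 1e-8, atol = 1e-10
  )
  df <- as.data.frame(out)
  names(df)[1] <- "time_h"
  names(df)[names(df) == "IL6R1m"] <- "IL6R1m_rel"
  names(df)[names(df) == "IRS1m"] <- "IRS1m_rel"
  df
}
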