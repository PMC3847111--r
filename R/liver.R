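#' Hepatic cAMP/PEPCK cascade parameters
#'
#' Study-keyed constants for the liver gluconeogenic cascade. The inhibition
#' constant of the nuclear complex on cAMP degradation and all baselines are
#' multiplexed by study: `"infusion"` arms use `IC50_cAMP = 433`, injection
#' arms `17.8`; baselines follow the same keying (`"iv_low"` covers the
#' saline-IV and 10 mg/kg arms). Zero-order synthesis rates are derived from
#' the baselines: `ks_C = kd_C * cAMP0`, `ks_Pm = kd_Pm * PEPCKm0`, and
#' `ks_P = kd_P * PEPCK0 / (lambda * PEPCKm0)`.
#'
#' @param study_key `"infusion"`, `"iv_low"` or `"injection"`.
#' @return Named list of liver-cascade constants.
#' @export
liver_params <- function(study_key = c("infusion", "injection", "iv_low")) {
  study_key <- match.arg(study_key)
  raw <- load_model_config()$liver_cascade
  p <- raw
  inj <- if (study_key == "infusion") "infusion" else "injection"
  p$IC50_cAMP <- raw$IC50_cAMP[[inj]]
  p$cAMP0 <- .pick(raw$cAMP0, study_key, "cAMP0")
  p$PEPCKm0 <- .pick(raw$PEPCKm0, study_key, "PEPCKm0")
  p$PEPCK0 <- raw$PEPCK0[[inj]]
  p$ks_C <- p$kd_C * p$cAMP0
  p$ks_Pm <- p$kd_Pm * p$PEPCKm0
  p$ks_P <- p$kd_P * p$PEPCK0 / (p$lambda * p$PEPCKm0)
  p
}

#' Baseline liver-cascade state
#' @param params Constants from [liver_params()].
#' @return Named state vector; the transduction biosignal `TC` starts at its
#'   drug-free fixed point 0.
#' @export
liver_init <- function(params) {
  c(cAMP = params$cAMP0, TC = 0, PEPCKm = params$PEPCKm0, PEPCK = params$PEPCK0)
}

#' Liver gluconeogenic cascade right-hand side
#'
#' The nuclear drug-receptor complex inhibits cAMP degradation, drives a
#' first-order transduction biosignal `TC`, and together with `TC` scales
#' PEPCK mRNA production and degradation; PEPCK activity is synthesized from
#' the amplified mRNA under Emax stimulation by the rise of cAMP above
#' baseline:
#' \deqn{dcAMP/dt = ks_C - kd_C (1 - DRn/(IC50_{cAMP} + DRn)) cAMP}
#' \deqn{dTC/dt = k_1 (DRn - TC)}
#' \deqn{dPEPCKm/dt = ks_{Pm} (1 + S_s^{Pm} DRn) - kd_{Pm} (1 + S_d^{Pm} TC) PEPCKm}
#' \deqn{dPEPCK/dt = ks_P \lambda PEPCKm (1 + S_{max}^P \Delta cAMP/(SC_{50} + \Delta cAMP)) - kd_P PEPCK}
#' with `dcAMP = max(cAMP - cAMP0, 0)` so the Emax term acts on the increase
#' of cAMP only.
#'
#' @param state Named vector `(cAMP, TC, PEPCKm, PEPCK)`, all `>= 0`.
#' @param DRn Liver nuclear drug-receptor complex (fmol/mg protein), `>= 0`.
#' @param params Constants from [liver_params()].
#' @return Named derivative vector.
#' @export
liver_rhs <- function(state, DRn, params) {
  if (DRn < 0 || any(state < 0)) stop("liver state and DRn must be >= 0")
  cAMP <- state[["cAMP"]]; TC <- state[["TC"]]
  PEPCKm <- state[["PEPCKm"]]; PEPCK <- state[["PEPCK"]]
  dcamp <- max(cAMP - params$cAMP0, 0)
  c(
    cAMP = params$ks_C - params$kd_C * (1 - DRn / (params$IC50_cAMP + DRn)) * cAMP,
    TC = params$k1 * (DRn - TC),
    PEPCKm = params$ks_Pm * (1 + params$Ss_Pm * DRn) -
      params$kd_Pm * (1 + params$Sd_Pm * TC) * PEPCKm,
    PEPCK = params$ks_P * params$lambda * PEPCKm *
      (1 + params$Smax_P * dcamp / (params$SC50_cAMP + dcamp)) -
      params$kd_P * PEPCK
  )
}

#' Simulate the hepatic cascade driven by a liver DRn trace
#'
#' @param regimen A [dose_regimen()].
#' @param t_grid Output times (h).
#' @param study_key Liver parameter multiplexing key; inferred from the
#'   regimen when `NULL`.
#' @param drn_fn Optional function of time returning liver DRn.
#' @param params Optional constants override.
#' @param rtol,atol Solver tolerances.
#' @return `data.frame` with `time_h`, `cAMP`, `TC`, `PEPCKm`, `PEPCK`.
#' @export
simulate_liver <- function(regimen, t_grid = NULL, study_key = NULL,
                           drn_fn = NULL, params = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  if (is.null(t_grid)) t_grid <- dense_grid(168)
  if (is.null(study_key)) study_key <- .liver_cascade_key(regimen)
  if (is.null(params)) params <- liver_params(study_key)
  if (is.null(drn_fn)) {
    rec <- simulate_receptor("liver", regimen, t_grid, rtol = rtol, atol = atol)
    drn_fn <- stats::splinefun(rec$time_h, rec$DRn, method = "natural")
  }
  rhs <- function(t, y, p) list(liver_rhs(pmax(y, 0), max(drn_fn(t), 0), p))
  out <- deSolve::ode(
    y = liver_init(params), times = .with_events(t_grid, regimen), func = rhs,
    parms = params, method = "lsoda", rtol = rtol, atol = atol
  )
  df <- as.data.frame(out)
  names(df)[1] <- "time_h"
  df
}

.liver_cascade_key <- function(regimen) {
  switch(regimen$route,
    sc_infusion = "infusion",
    iv_bolus = if (regimen$amount <= 10) "iv_low" else "injection",
    im_bolus = "injection"
  )
}
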