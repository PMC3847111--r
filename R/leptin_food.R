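#' Leptin dynamic parameters
#'
#' Constants for adipose leptin mRNA induction and plasma leptin turnover.
#' Baselines are study-specific (`"infusion"`, `"im50"`, `"im_control"`).
#' Zero-order synthesis rates are derived from the baselines so the drug-free
#' system is stationary: `ks_Lepm = kd_Lepm * Lepm0` and
#' `ks_Lep = kd_Lep * Lep0 / Lepm0`.
#'
#' @param study_key Baseline selector.
#' @return Named list of leptin constants.
#' @export
leptin_params <- function(study_key = "infusion") {
  raw <- load_model_config()$leptin
  p <- raw
  p$Lepm0 <- .pick(raw$Lepm0, study_key, "Lepm0")
  p$Lep0 <- .pick(raw$Lep0, study_key, "Lep0")
  p$ks_Lepm <- p$kd_Lepm * p$Lepm0
  p$ks_Lep <- p$kd_Lep * p$Lep0 / p$Lepm0
  p
}

#' Food-intake parameters
#'
#' Day-based rates are already converted to hours by [load_model_config()].
#' The first-order food loss constant is `kout_Food = kin_Food0 / Food_max`.
#'
#' @param group Chronic-infusion arm selecting the initial intake `Food0`
#'   (`"saline"`, `"0.03"`, ..., `"0.4"`).
#' @return Named list of food-intake constants (per-hour clock).
#' @export
food_params <- function(group = "saline") {
  raw <- load_model_config()$food
  p <- raw
  p$Food0 <- .pick(raw$Food0, group, "Food0")
  p
}

#' Leptin right-hand side
#'
#' Leptin mRNA production is the baseline synthesis rate scaled linearly by
#' the adipose nuclear drug-receptor complex,
#' \deqn{dLepm/dt = ks_{Lepm}(1 + S_{Lepm} DRn) - kd_{Lepm} Lepm}
#' and plasma leptin is produced in proportion to the mRNA,
#' \deqn{dLep/dt = ks_{Lep} Lepm - kd_{Lep} Lep.}
#'
#' @param state Named vector `(Lepm, Lep)`.
#' @param DRn Adipose nuclear drug-receptor complex (fmol/mg protein), `>= 0`.
#' @param params Constants from [leptin_params()].
#' @return Named derivative vector.
#' @export
leptin_rhs <- function(state, DRn, params) {
  if (DRn < 0) stop("DRn must be >= 0")
  c(
    Lepm = params$ks_Lepm * (1 + params$S_Lepm * DRn) - params$kd_Lepm * state[["Lepm"]],
    Lep = params$ks_Lep * state[["Lepm"]] - params$kd_Lep * state[["Lep"]]
  )
}

#' Time-varying food input rate
#'
#' Exponential decline from the initial to the steady-state input rate,
#' `kin_Food(t) = kin_FoodSS + (kin_Food0 - kin_FoodSS) * exp(-kd * t)`,
#' describing the stress-related control decline of intake.
#'
#' @param t Hours since study start.
#' @param params Constants from [food_params()].
#' @return Input rate in kcal/day per hour.
#' @export
kin_food <- function(t, params) {
  params$kin_FoodSS + (params$kin_Food0 - params$kin_FoodSS) * exp(-params$kd * t)
}

#' Food-intake right-hand side
#'
#' Indirect response model I: the drug-driven rise of plasma leptin above its
#' baseline inhibits the food input rate by the factor
#' `1 - dLep/(IC50_Lep + dLep)` with `dLep = max(Lep - Lep_ref, 0)`; a slow
#' feedback signal `FB` (initialized at 1) multiplies the input and relaxes
#' toward `Food0/Food`, so suppressed intake is slowly pushed back up
#' (tolerance),
#' \deqn{dFood/dt = kin_{Food}(t) (1 - \Delta Lep/(IC50 + \Delta Lep)) FB - kout_{Food} Food}
#' \deqn{dFB/dt = k_{FB} (Food^0/Food - FB).}
#'
#' Acting on the leptin excursion (rather than its absolute level) keeps the
#' control arms of every study consistent: with leptin at baseline the
#' control intake settles at `kin_FoodSS/kout_Food` regardless of the
#' study-specific leptin baseline.
#'
#' @param state Named vector `(Food, FB)`.
#' @param Lep Plasma leptin (pg/mL).
#' @param t Hours since study start.
#' @param params Constants from [food_params()]; `Lep_ref` (the baseline
#'   leptin of the driving study, 0 when absent) defines the excursion.
#' @param feedback Feedback-signal target function; the default implements
#'   `Food0/Food`. Kept injectable so the alternative placement of the
#'   feedback step can be examined without touching the solver.
#' @return Named derivative vector.
#' @export
food_rhs <- function(state, Lep, t, params,
                     feedback = function(Food, params) params$Food0 / max(Food, 1e-9)) {
  if (Lep < 0) stop("leptin must be >= 0")
  Food <- state[["Food"]]; FB <- state[["FB"]]
  dlep <- max(Lep - (params$Lep_ref %||% 0), 0)
  inhib <- 1 - dlep / (params$IC50_Lep + dlep)
  c(
    Food = kin_food(t, params) * inhib * FB - params$kout_Food * Food,
    FB = params$kFB * (feedback(Food, params) - FB)
  )
}

#' Simulate the coupled leptin / food-intake system
#'
#' Drives leptin transcription with an adipose nuclear drug-receptor complex
#' trace (simulated from the regimen when not supplied) and feeds plasma
#' leptin into the food-intake turnover model.
#'
#' @param regimen A [dose_regimen()].
#' @param t_grid Output times (h).
#' @param group Chronic-infusion arm for `Food0`.
#' @param study_key Leptin baseline selector.
#' @param drn_fn Optional function of time returning adipose DRn; defaults to
#'   a spline through [simulate_receptor()] output.
#' @param lp,fp Optional parameter overrides.
#' @return `data.frame` with `time_h`, `Lepm`, `Lep_pg_per_mL`,
#'   `Food_kcal_per_day`, `FB`.
#' @export
simulate_leptin_food <- function(regimen, t_grid = NULL, group = "saline",
                                 study_key = "infusion", drn_fn = NULL,
                                 lp = NULL, fp = NULL) {
  if (is.null(t_grid)) t_grid <- dense_grid(168)
  if (is.null(lp)) lp <- leptin_params(study_key)
  if (is.null(fp)) fp <- food_params(group)
  if (is.null(fp$Lep_ref)) fp$Lep_ref <- lp$Lep0
  if (is.null(drn_fn)) {
    rec <- simulate_receptor("adipose", regimen, t_grid)
    drn_fn <- stats::splinefun(rec$time_h, rec$DRn, method = "natural")
  }
  rhs <- function(t, y, p) {
    y <- pmax(y, 0)
    dl <- leptin_rhs(y[c("Lepm", "Lep")], max(drn_fn(t), 0), lp)
    df <- food_rhs(y[c("Food", "FB")], y[["Lep"]], t, fp)
    list(c(dl, df))
  }
  y0 <- c(Lepm = lp$Lepm0, Lep = lp$Lep0, Food = fp$Food0, FB = 1)
  out <- deSolve::ode(
    y = y0, times = .with_events(t_grid, regimen), func = rhs, parms = NULL,
    method = "lsoda", rtol = 1e-8, atol = 1e-10
  )
  df <- as.data.frame(out)
  data.frame(
    time_h = df$time, Lepm = df$Lepm, Lep_pg_per_mL = df$Lep,
    Food_kcal_per_day = df$Food, FB = df$FB
  )
}
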