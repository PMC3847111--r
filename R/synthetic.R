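#' Define a synthetic destructive-sampling design
#'
#' Wraps a [study_design()] with the sampling scheme of the emulated animal
#' experiment: each time point is measured in `n_animals_per_timepoint`
#' independent animals (destructive sampling), and each analyte carries its
#' own power-variance observation noise.
#'
#' @param design A [study_design()].
#' @param sampling_times Observation times (h). Food intake is always
#'   observed at 24-h marks regardless of this grid (daily weighing).
#' @param analytes Analyte names, see [analyte_trace()].
#' @param n_animals_per_timepoint Animals sacrificed per time point, `>= 1`.
#' @param noise A [variance_params()] shared by all analytes, or a named
#'   list per analyte.
#' @param seed Integer seed, recorded in the output.
#' @return A `synthetic_design`.
#' @export
synthetic_design <- function(design, sampling_times, analytes,
                             n_animals_per_timepoint = 4,
                             noise = variance_params(0.1, 2), seed = 1) {
  if (n_animals_per_timepoint < 1) stop("need at least one animal per time point")
  if (any(sampling_times < 0 | sampling_times > design$t_end)) {
    stop("sampling_times must lie in [0, t_end]")
  }
  structure(
    list(
      design = design, sampling_times = sort(unique(sampling_times)),
      analytes = analytes, n = as.integer(n_animals_per_timepoint),
      noise = noise, seed = as.integer(seed)
    ),
    class = "synthetic_design"
  )
}

#' Generate a synthetic observation set
#'
#' Simulates the noise-free model curves for the design, then draws `n`
#' independent Gaussian observations per (analyte, time) with variance
#' `sigma1^2 * Y^sigma2`, truncated at zero for these positive-valued
#' analytes (negative draws are redrawn). Food intake is sampled from the
#' state at daily marks only. The noise-free truth is returned alongside for
#' use as a test oracle.
#'
#' @param sdesign A [synthetic_design()].
#' @param overrides Parameter patches passed to [simulate_study()]; use these
#'   to generate data at non-default ("true") parameter values.
#' @param simulation Optional precomputed `mpl_simulation` to sample from
#'   (must match the design); avoids re-integration across noise replicates.
#' @return List with `observations` (an [observation_set()]), `truth`
#'   (`data.frame` analyte/time_h/value), `seed`, and `design`.
#' @export
generate_study <- function(sdesign, overrides = NULL, simulation = NULL) {
  if (!inherits(sdesign, "synthetic_design")) stop("need a synthetic_design")
  sim <- simulation %||%
    simulate_study(sdesign$design, overrides = overrides)
  obs_list <- list()
  truth_list <- list()
  set.seed(sdesign$seed)
  for (an in sdesign$analytes) {
    tr <- analyte_trace(sim, an)
    times <- if (an == "Food") {
      tm <- seq(24, sdesign$design$t_end, by = 24)
      tm[tm <= max(sdesign$sampling_times)]
    } else {
      sdesign$sampling_times
    }
    truth <- stats::approx(tr$time_h, tr$value, xout = times)$y
    truth_list[[an]] <- data.frame(analyte = an, time_h = times, value = truth)
    vp <- if (inherits(sdesign$noise, "variance_params")) sdesign$noise else sdesign$noise[[an]]
    sds <- sqrt(.power_variance(truth, vp))
    tt <- rep(times, each = sdesign$n)
    mu <- rep(truth, each = sdesign$n)
    ss <- rep(sds, each = sdesign$n)
    y <- stats::rnorm(length(mu), mu, ss)
    for (it in seq_len(50)) {
      neg <- y < 0
      if (!any(neg)) break
      y[neg] <- stats::rnorm(sum(neg), mu[neg], ss[neg])
    }
    y <- pmax(y, 0)
    obs_list[[an]] <- observation_set(
      analyte = an, time_h = tt, value = y,
      study = sdesign$design$study, group = sdesign$design$arm
    )
  }
  obs <- do.call(rbind, obs_list)
  rownames(obs) <- NULL
  class(obs) <- c("observation_set", "data.frame")
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL
  list(observations = obs, truth = truth, seed = sdesign$seed, design = sdesign)
}

#' Prediction function for the systemic stage with frozen drivers
#'
#' Builds a `fit_spec` predict function for the glucose/insulin/FFA
#' sub-system: the tissue-cascade drivers (PEPCK, cAMP, food, IRS-1 ratio,
#' adipose DRn) are taken from a reference simulation and splined, exactly
#' the piecewise strategy of freezing upstream time courses. Free parameters
#' may be any subset of the systemic constants.
#'
#' @param reference A `mpl_simulation` providing the driver traces.
#' @return Function `(pars, obs)` for [fit_spec()].
#' @export
systemic_stage_predict <- function(reference) {
  b <- reference$bundle
  design <- reference$design
  t <- reference$times
  sp <- function(v) stats::splinefun(t, v, method = "natural")
  fP <- sp(reference$states$PEPCK); fC <- sp(reference$states$cAMP)
  fF <- sp(reference$states$Food); fI <- sp(reference$states$IRS1m)
  fD <- sp(reference$states$aDRn)
  function(pars, obs) {
    p <- b$systemic
    for (nm in names(pars)) p[[nm]] <- pars[[nm]]
    rates <- steady_state_rates(p, list(Food = b$food$Food0), design$use_food)
    rhs <- function(tt, y, q) {
      drivers <- list(
        PEPCK = fP(tt), cAMP = fC(tt), Food = fF(tt),
        IRS1_ratio = irs1_ratio(fI(tt), b$muscle$IRS1m0), DRn = max(fD(tt), 0)
      )
      list(systemic_rhs(y, drivers, p, t = tt, rates = rates,
        use_food = design$use_food))
    }
    t_out <- sort(unique(c(0, obs$time_h)))
    out <- deSolve::ode(
      c(G = p$G0, I = p$I0, FFA = p$FFA0), t_out, rhs, NULL,
      method = "lsoda", rtol = 1e-6, atol = 1e-8
    )
    out <- as.data.frame(out)
    key <- c(G = "G", I = "I", FFA = "FFA")
    idx <- match(obs$time_h, out$time)
    vapply(seq_len(nrow(obs)), function(i) {
      out[[key[[obs$analyte[i]]]]][idx[i]]
    }, numeric(1))
  }
}

#' Prediction function for the leptin/food stage with a frozen DRn trace
#'
#' Integrates the coupled leptin mRNA / plasma leptin / food-intake system
#' driven by a fixed adipose DRn trace and returns predictions for any of
#' the analytes `Lepm`, `Lep`, `Food`. Free parameters may be leptin or food
#' constants; leptin synthesis rates are re-derived from the baselines.
#'
#' @param drn_fn Function of time returning the adipose nuclear complex.
#' @param group Food-intake arm, see [food_params()].
#' @param study_key Leptin baseline selector.
#' @return Function `(pars, obs)` for [fit_spec()].
#' @export
food_stage_predict <- function(drn_fn, group = "saline", study_key = "infusion") {
  lp0 <- leptin_params(study_key)
  fp0 <- food_params(group)
  fp0$Lep_ref <- lp0$Lep0
  function(pars, obs) {
    lp <- lp0; fp <- fp0
    for (nm in names(pars)) {
      if (nm %in% names(fp)) fp[[nm]] <- pars[[nm]] else lp[[nm]] <- pars[[nm]]
    }
    lp$ks_Lepm <- lp$kd_Lepm * lp$Lepm0
    lp$ks_Lep <- lp$kd_Lep * lp$Lep0 / lp$Lepm0
    rhs <- function(t, y, q) {
      y <- pmax(y, 0)
      dl <- leptin_rhs(y[c("Lepm", "Lep")], max(drn_fn(t), 0), lp)
      df <- food_rhs(y[c("Food", "FB")], y[["Lep"]], t, fp)
      list(c(dl, df))
    }
    t_out <- sort(unique(c(0, obs$time_h)))
    out <- as.data.frame(deSolve::ode(
      c(Lepm = lp$Lepm0, Lep = lp$Lep0, Food = fp$Food0, FB = 1),
      t_out, rhs, NULL, method = "lsoda", rtol = 1e-8, atol = 1e-10
    ))
    idx <- match(obs$time_h, out$time)
    vapply(seq_len(nrow(obs)), function(i) {
      out[[obs$analyte[i]]][idx[i]]
    }, numeric(1))
  }
}

#' Prediction function for the leptin stage with a frozen DRn trace
#'
#' @param drn_fn Function of time returning the adipose nuclear complex.
#' @param study_key Leptin baseline selector, see [leptin_params()].
#' @return Function `(pars, obs)` for [fit_spec()]; free parameters may be
#'   any of the leptin constants (synthesis rates are re-derived from the
#'   baselines so the drug-free system stays stationary at any candidate).
#' @export
leptin_stage_predict <- function(drn_fn, study_key = "im50") {
  base <- leptin_params(study_key)
  function(pars, obs) {
    p <- base
    for (nm in names(pars)) p[[nm]] <- pars[[nm]]
    p$ks_Lepm <- p$kd_Lepm * p$Lepm0
    p$ks_Lep <- p$kd_Lep * p$Lep0 / p$Lepm0
    rhs <- function(t, y, q) list(leptin_rhs(pmax(y, 0), max(drn_fn(t), 0), p))
    t_out <- sort(unique(c(0, obs$time_h)))
    out <- as.data.frame(deSolve::ode(
      c(Lepm = p$Lepm0, Lep = p$Lep0), t_out, rhs, NULL,
      method = "lsoda", rtol = 1e-8, atol = 1e-10
    ))
    key <- c(Lepm = "Lepm", Lep = "Lep")
    idx <- match(obs$time_h, out$time)
    vapply(seq_len(nrow(obs)), function(i) {
      out[[key[[obs$analyte[i]]]]][idx[i]]
    }, numeric(1))
  }
}
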