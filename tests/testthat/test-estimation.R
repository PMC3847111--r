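test_that("power-variance NLL matches brute-force density evaluation exactly", {
  set.seed(11)
  y <- c(1.2, 1.9, 4.4, 0.8, 2.2)
  pred <- c(1.0, 2.0, 4.0, 1.0, 2.0)
  for (vp in list(variance_params(1, 1), variance_params(0.3, 2),
                  variance_params(2, 0))) {
    brute <- -sum(stats::dnorm(y, pred, sqrt(vp$sigma1^2 * pred^vp$sigma2),
      log = TRUE))
    expect_equal(nll_power(y, pred, vp), brute, tolerance = 1e-12)
  }
})

test_that("hand-worked NLL example and constant-variance reduction hold", {
  # perfect fit, sigma1 = 1, sigma2 = 1: NLL = (3/2) log(2*pi) + 0.5 log(8)
  expect_equal(
    nll_power(c(1, 2, 4), c(1, 2, 4), variance_params(1, 1)),
    1.5 * log(2 * pi) + 0.5 * log(8),
    tolerance = 1e-12
  )
  # sigma2 = 0 reduces to constant-variance least squares
  y <- c(1, 3, 2); pred <- c(1.5, 2.5, 2.5); s1 <- 0.7
  expect_equal(
    nll_power(y, pred, variance_params(s1, 0)),
    (3 / 2) * log(2 * pi * s1^2) + sum((y - pred)^2) / (2 * s1^2),
    tolerance = 1e-12
  )
})

test_that("non-finite predictions give a penalty, not a crash", {
  expect_equal(nll_power(c(1, 2), c(NaN, 1), variance_params(1, 0)), 1e10)
  spec <- fit_spec(function(pars, obs) stop("boom"), free = c(a = 1))
  obs <- observation_set("x", c(1, 2), c(1, 2))
  expect_equal(negative_log_likelihood(c(a = 1), obs, spec, variance_params(1, 0)),
    1e10)
})

test_that("zero-noise leptin data recover the reported parameters to <1%", {
  drn <- adipose_im50_drn_fn()
  pred_fn <- leptin_stage_predict(drn, "im50")
  times <- c(1, 2, 4, 6, 8, 12, 18, 24, 36, 48, 72)
  obs0 <- observation_set(rep(c("Lepm", "Lep"), each = length(times)),
    rep(times, 2), 1)
  truth <- pred_fn(list(), obs0)
  obs <- observation_set(obs0$analyte, obs0$time_h, truth)
  spec <- fit_spec(pred_fn,
    free = c(kd_Lepm = 0.02, S_Lepm = 0.3),
    lower = c(1e-4, 1e-4), upper = c(1, 10))
  fit <- fit_stage(obs, spec, variance_params(1, 0), seed = 1, n_starts = 2)
  expect_lt(abs(fit$estimates[["kd_Lepm"]] - 0.0427) / 0.0427, 0.01)
  expect_lt(abs(fit$estimates[["S_Lepm"]] - 0.0989) / 0.0989, 0.01)
  expect_true(all(is.finite(fit$cv_pct)))
})

test_that("perfect-fit parameters minimize the NLL over a local grid", {
  drn <- adipose_im50_drn_fn()
  pred_fn <- leptin_stage_predict(drn, "im50")
  times <- c(2, 6, 12, 24, 48)
  obs0 <- observation_set(rep("Lepm", length(times)), times, 1)
  truth <- pred_fn(list(), obs0)
  obs <- observation_set(obs0$analyte, obs0$time_h, truth)
  spec <- fit_spec(pred_fn, free = c(S_Lepm = 0.0989))
  vp <- variance_params(1, 0)
  nll_at <- function(s) negative_log_likelihood(c(S_Lepm = s), obs, spec, vp)
  grid <- seq(0.05, 0.15, by = 0.01)
  vals <- vapply(grid, nll_at, numeric(1))
  # the grid point nearest the generating value wins
  expect_lt(abs(grid[which.min(vals)] - 0.0989), 0.011)
})

test_that("an empty free set returns the fixed-model likelihood only", {
  obs <- observation_set("x", c(1, 2, 3), c(2, 4, 6))
  spec <- fit_spec(function(pars, obs) pars$a * obs$time_h,
    free = numeric(0), fixed = list(a = 2))
  fit <- fit_stage(obs, spec, variance_params(1, 0))
  expect_length(fit$estimates, 0)
  expect_equal(fit$nll, nll_power(obs$value, 2 * obs$time_h, variance_params(1, 0)))
})

test_that("free and fixed parameter sets must be disjoint", {
  expect_error(
    fit_spec(function(pars, obs) 0, free = c(a = 1), fixed = list(a = 2)),
    "overlap"
  )
})

test_that("AIC prefers the model with a truly present effect", {
  drn <- adipose_im50_drn_fn()
  pred_fn <- leptin_stage_predict(drn, "im50")
  times <- c(2, 6, 12, 24, 48, 72)
  obs0 <- observation_set(rep("Lepm", length(times)), times, 1)
  truth <- pred_fn(list(), obs0) # generated with S_Lepm = 0.0989 > 0
  set.seed(5)
  obs <- observation_set(obs0$analyte, obs0$time_h,
    truth * (1 + stats::rnorm(length(truth), 0, 0.03)))
  vp <- variance_params(0.03, 2)
  with_effect <- fit_stage(obs,
    fit_spec(pred_fn, free = c(kd_Lepm = 0.04, S_Lepm = 0.05),
      lower = c(1e-4, 0), upper = c(1, 10)),
    vp, seed = 2, n_starts = 2)
  without_effect <- fit_stage(obs,
    fit_spec(pred_fn, free = c(kd_Lepm = 0.04),
      lower = 1e-4, upper = 1, fixed = list(S_Lepm = 0)),
    vp, seed = 2, n_starts = 2)
  expect_lt(with_effect$aic, without_effect$aic)
})

test_that("piecewise workflow: ordering, imports, and cycle detection", {
  obs <- observation_set(
    rep(c("u", "w"), each = 4), rep(1:4, 2),
    c(2 * (1:4), 3 + 2 * (1:4))
  )
  # stage A fits the slope on analyte u; stage B reuses it for analyte w
  spec_a <- fit_spec(function(pars, obs) pars$slope * obs$time_h,
    free = c(slope = 1), lower = 0, upper = 10, analytes = "u")
  spec_b <- fit_spec(function(pars, obs) pars$offset + pars$slope * obs$time_h,
    free = c(offset = 0), lower = -10, upper = 10,
    fixed = list(slope = NA), analytes = "w")
  plan <- list(
    a = list(spec = spec_a, var = variance_params(1, 0)),
    b = list(spec = spec_b, var = variance_params(1, 0),
      depends = "a", imports = c(slope = "a:slope"))
  )
  res <- run_piecewise_workflow(obs, plan, seed = 1, n_starts = 2)
  expect_equal(res$fits$a$estimates[["slope"]], 2, tolerance = 1e-4)
  expect_equal(res$fits$b$estimates[["offset"]], 3, tolerance = 1e-4)
  expect_equal(res$manifest$source, "a:slope")

  # single-stage plan is identical to fit_stage
  solo <- run_piecewise_workflow(obs, plan["a"], seed = 1, n_starts = 2)
  direct <- fit_stage(obs, spec_a, variance_params(1, 0), seed = 1, n_starts = 2)
  expect_equal(solo$fits$a$estimates, direct$estimates)

  # permuting two independent stages leaves results identical
  plan2 <- list(
    a = plan$a,
    c = list(spec = fit_spec(function(pars, obs) pars$k + 0 * obs$time_h,
      free = c(k = 1), lower = -10, upper = 20, analytes = "w"),
      var = variance_params(1, 0))
  )
  r12 <- run_piecewise_workflow(obs, plan2, seed = 1, n_starts = 2)
  r21 <- run_piecewise_workflow(obs, plan2[c("c", "a")], seed = 1, n_starts = 2)
  expect_equal(r12$fits$a$estimates, r21$fits$a$estimates)
  expect_equal(r12$fits$c$estimates, r21$fits$c$estimates)

  # cyclic plans are rejected
  bad <- list(
    a = list(spec = spec_a, var = variance_params(1, 0), depends = "b"),
    b = list(spec = spec_a, var = variance_params(1, 0), depends = "a")
  )
  expect_error(run_piecewise_workflow(obs, bad), "cyclic")
})

test_that("downstream estimates stabilize as upstream noise vanishes", {
  drn <- adipose_im50_drn_fn()
  lep_pred <- leptin_stage_predict(drn, "im50")
  food_pred <- food_stage_predict(drn, group = "saline", study_key = "im50")
  times <- c(4, 8, 12, 24, 48, 72)
  lep_obs0 <- observation_set(rep("Lepm", 6), times, 1)
  lep_truth <- lep_pred(list(), lep_obs0)
  food_times <- c(24, 48, 72)
  food_obs0 <- observation_set(rep("Food", 3), food_times, 1)
  food_truth <- food_pred(list(), food_obs0)

  run_with_noise <- function(cv, seed) {
    set.seed(seed)
    lep_obs <- observation_set("Lepm", times,
      lep_truth * (1 + stats::rnorm(6, 0, cv)))
    obs <- rbind(lep_obs, observation_set("Food", food_times, food_truth))
    class(obs) <- c("observation_set", "data.frame")
    plan <- list(
      leptin = list(
        spec = fit_spec(lep_pred, free = c(S_Lepm = 0.05),
          lower = 1e-4, upper = 5, analytes = "Lepm"),
        var = variance_params(1, 0)
      ),
      food = list(
        spec = fit_spec(food_pred, free = c(IC50_Lep = 20000),
          lower = 100, upper = 1e6, analytes = "Food"),
        var = variance_params(1, 0),
        depends = "leptin", imports = c(S_Lepm = "leptin:S_Lepm")
      )
    )
    run_piecewise_workflow(obs, plan, seed = 1, n_starts = 1)
  }
  noisy <- run_with_noise(0.05, 31)
  clean <- run_with_noise(0, 31)
  # with exact upstream data, the downstream stage recovers the true constant
  expect_equal(clean$fits$food$estimates[["IC50_Lep"]], 11550, tolerance = 0.01)
  err_clean <- abs(clean$fits$food$estimates[["IC50_Lep"]] - 11550)
  err_noisy <- abs(noisy$fits$food$estimates[["IC50_Lep"]] - 11550)
  expect_lt(err_clean, err_noisy + 1e-6)
})
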