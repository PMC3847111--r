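#' Variance-model parameters
#'
#' Power-of-the-mean observation variance `V = sigma1^2 * Y^sigma2`, where
#' `Y` is the model prediction. `sigma2 = 0` recovers constant variance,
#' `sigma2 = 2` a constant coefficient of variation `sigma1`.
#'
#' @param sigma1 Scale, `> 0`.
#' @param sigma2 Power exponent (any real).
#' @return A `variance_params` list.
#' @export
variance_params <- function(sigma1 = 0.1, sigma2 = 2) {
  if (sigma1 <= 0) stop("sigma1 must be > 0")
  structure(list(sigma1 = sigma1, sigma2 = sigma2), class = "variance_params")
}

# per-point variance with a floor for non-positive predictions
.power_variance <- function(pred, vp, eps = 1e-6) {
  bad <- pred <= 0
  if (any(bad) && vp$sigma2 != 0) {
    warning("non-positive predictions; variance floored at sigma1^2 * eps^sigma2")
  }
  vp$sigma1^2 * pmax(pred, eps)^vp$sigma2
}

#' Gaussian negative log-likelihood under the power variance model
#'
#' \deqn{-\log L = \sum_i \tfrac12 \log(2\pi V_i) + (y_i - Y_i)^2/(2 V_i),
#'   \quad V_i = \sigma_1^2 Y_i^{\sigma_2}.}
#'
#' @param y Observations.
#' @param pred Model predictions `Y`, aligned with `y`.
#' @param vp A [variance_params()].
#' @return Scalar negative log-likelihood; a large penalty (`1e10`) if any
#'   prediction is non-finite (so optimizers back away instead of crashing).
#' @export
nll_power <- function(y, pred, vp) {
  if (any(!is.finite(pred))) {
    return(1e10)
  }
  V <- .power_variance(pred, vp)
  sum(0.5 * log(2 * pi * V) + (y - pred)^2 / (2 * V))
}

#' Build an observation set
#'
#' Tidy container for pooled destructive-sampling measurements; replicate
#' rows at a time point are independent animals.
#'
#' @param analyte,time_h,value,study,group Vectors of equal length (or
#'   scalars recycled).
#' @return `data.frame` with class `observation_set`.
#' @export
observation_set <- function(analyte, time_h, value, study = "synthetic",
                            group = "1") {
  df <- data.frame(
    analyte = analyte, time_h = time_h, value = value,
    study = study, group = group, stringsAsFactors = FALSE
  )
  if (any(df$time_h < 0)) stop("negative observation times")
  class(df) <- c("observation_set", "data.frame")
  df
}

#' Specify a fitting stage
#'
#' @param predict Function `(pars, obs)` returning predictions aligned with
#'   the rows of `obs`; `pars` is the full named vector (free values merged
#'   over `fixed`).
#' @param free Named numeric vector of initial values for the free
#'   parameters.
#' @param lower,upper Bounds, recycled to `length(free)`.
#' @param fixed Named list/vector of fixed parameters.
#' @param analytes Analytes entering the likelihood (default: all in `obs`).
#' @return A `fit_spec`.
#' @export
fit_spec <- function(predict, free, lower = -Inf, upper = Inf,
                     fixed = list(), analytes = NULL) {
  if (length(free) && is.null(names(free))) stop("free parameters must be named")
  if (length(intersect(names(free), names(fixed)))) {
    stop("free and fixed parameter sets overlap")
  }
  structure(
    list(
      predict = predict, free = free,
      lower = rep_len(lower, length(free)), upper = rep_len(upper, length(free)),
      fixed = fixed, analytes = analytes
    ),
    class = "fit_spec"
  )
}

#' Negative log-likelihood of a parameter vector for a fitting stage
#'
#' Evaluates the model at `theta` (merged over the spec's fixed parameters)
#' and sums the power-variance Gaussian likelihood per analyte, each analyte
#' with its own `(sigma1, sigma2)` pair when `var` is a named list.
#'
#' @param theta Named values for the spec's free parameters.
#' @param obs An [observation_set()].
#' @param spec A [fit_spec()].
#' @param var A [variance_params()] or a named list of them keyed by analyte.
#' @return Scalar NLL (penalty value on simulation failure, never an error).
#' @export
negative_log_likelihood <- function(theta, obs, spec, var) {
  if (!is.null(spec$analytes)) obs <- obs[obs$analyte %in% spec$analytes, ]
  pars <- c(as.list(spec$fixed), as.list(theta))
  pred <- tryCatch(spec$predict(pars, obs), error = function(e) NULL)
  if (is.null(pred) || length(pred) != nrow(obs)) {
    return(1e10)
  }
  total <- 0
  for (an in unique(obs$analyte)) {
    i <- obs$analyte == an
    vp <- if (inherits(var, "variance_params")) var else var[[an]]
    if (is.null(vp)) stop("no variance parameters for analyte ", an)
    total <- total + nll_power(obs$value[i], pred[i], vp)
  }
  total
}

#' Maximum-likelihood fit of one stage
#'
#' Bounded quasi-Newton optimization (`L-BFGS-B`) from `n_starts` seeded
#' starting points (the spec's initial values plus uniform draws inside the
#' bounds). Reports estimates, asymptotic CV% from the observed-information
#' matrix, the NLL, AIC (`2*NLL + 2k`), convergence diagnostics, and the
#' per-start trace. With an empty free set the fixed model is evaluated and
#' only the NLL/AIC are returned.
#'
#' @param obs An [observation_set()].
#' @param spec A [fit_spec()].
#' @param var Variance parameters (see [negative_log_likelihood()]).
#' @param seed Integer seed for the multi-start draws.
#' @param n_starts Number of optimization starts.
#' @return A `stage_fit` list.
#' @export
fit_stage <- function(obs, spec, var, seed = 1, n_starts = 8) {
  k <- length(spec$free)
  if (k == 0) {
    nll <- negative_log_likelihood(numeric(0), obs, spec, var)
    return(structure(
      list(estimates = numeric(0), cv_pct = numeric(0), nll = nll,
        aic = 2 * nll, convergence = 0L, starts = NULL, fixed = spec$fixed),
      class = "stage_fit"
    ))
  }
  obj <- function(th) {
    names(th) <- names(spec$free)
    negative_log_likelihood(th, obs, spec, var)
  }
  lo <- spec$lower; hi <- spec$upper
  set.seed(seed)
  starts <- matrix(NA_real_, n_starts, k)
  starts[1, ] <- unlist(spec$free)
  if (n_starts > 1) {
    slo <- ifelse(is.finite(lo), lo, unlist(spec$free) / 10)
    shi <- ifelse(is.finite(hi), hi, unlist(spec$free) * 10)
    for (j in seq_len(k)) {
      starts[-1, j] <- stats::runif(n_starts - 1, slo[j], shi[j])
    }
  }
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    runs[[s]] <- tryCatch(
      stats::optim(starts[s, ], obj, method = "L-BFGS-B", lower = lo, upper = hi,
        control = list(
          maxit = 500, factr = 1e8,
          parscale = pmax(abs(starts[s, ]), 1e-8)
        )),
      error = function(e) list(value = Inf, convergence = 99L, par = starts[s, ])
    )
  }
  values <- vapply(runs, function(r) r$value, numeric(1))
  conv <- vapply(runs, function(r) as.integer(r$convergence), integer(1))
  if (all(!is.finite(values))) {
    stop("no optimization start converged; per-start values: ",
      paste(signif(values, 4), collapse = ", "))
  }
  best <- runs[[which.min(values)]]
  est <- best$par
  names(est) <- names(spec$free)
  cv <- rep(NA_real_, k)
  names(cv) <- names(spec$free)
  hess <- tryCatch(stats::optimHess(est, obj), error = function(e) NULL)
  if (!is.null(hess)) {
    cov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov)) {
      se <- suppressWarnings(sqrt(diag(cov)))
      cv <- 100 * se / abs(est)
    }
  }
  structure(
    list(
      estimates = est, cv_pct = cv, nll = best$value,
      aic = 2 * best$value + 2 * k, convergence = best$convergence,
      starts = data.frame(start = seq_len(n_starts), nll = values, convergence = conv),
      fixed = spec$fixed
    ),
    class = "stage_fit"
  )
}

#' @export
print.stage_fit <- function(x, ...) {
  cat("<stage_fit> NLL =", format(x$nll), " AIC =", format(x$aic), "\n")
  if (length(x$estimates)) {
    print(data.frame(estimate = x$estimates, cv_pct = x$cv_pct))
  }
  invisible(x)
}

#' Run a staged (piecewise) estimation workflow
#'
#' Executes fitting stages in dependency order, freezing each stage's
#' estimates as fixed parameters of downstream stages — the strategy used to
#' make the full meta-model tractable: receptor dynamics are fitted first,
#' then the adipose cascade, then food intake, and finally the systemic
#' glucose/insulin/FFA parameters with all upstream time courses fixed.
#'
#' @param obs An [observation_set()] shared by all stages (each stage filters
#'   by its analytes).
#' @param stage_plan Named list; each element has `spec` (a [fit_spec()]),
#'   `var`, optional `depends` (character vector of stage names), and
#'   optional `imports`: a named character vector mapping this stage's fixed
#'   parameter names to `"stage:param"` sources.
#' @param seed,n_starts Passed to [fit_stage()].
#' @return List with `fits` (per stage), and `manifest` — the provenance
#'   table of every imported parameter.
#' @export
run_piecewise_workflow <- function(obs, stage_plan, seed = 1, n_starts = 8) {
  order <- .toposort(lapply(stage_plan, function(s) s$depends %||% character(0)))
  fits <- list()
  manifest <- data.frame(
    stage = character(0), param = character(0),
    value = numeric(0), source = character(0)
  )
  for (nm in order) {
    st <- stage_plan[[nm]]
    spec <- st$spec
    for (tgt in names(st$imports %||% character(0))) {
      src <- strsplit(st$imports[[tgt]], ":", fixed = TRUE)[[1]]
      val <- fits[[src[1]]]$estimates[[src[2]]]
      if (is.null(val)) stop("stage '", nm, "' imports unknown ", st$imports[[tgt]])
      spec$fixed[[tgt]] <- val
      manifest <- rbind(manifest, data.frame(
        stage = nm, param = tgt, value = val, source = st$imports[[tgt]]
      ))
    }
    fits[[nm]] <- fit_stage(obs, spec, st$var, seed = seed, n_starts = n_starts)
  }
  list(fits = fits, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# topological sort of a named dependency list; cycles are an error
.toposort <- function(deps) {
  remaining <- names(deps)
  done <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(n) {
      all(deps[[n]] %in% done)
    }, logical(1))]
    if (!length(ready)) {
      stop("cyclic stage plan involving: ", paste(remaining, collapse = ", "))
    }
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  done
}
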