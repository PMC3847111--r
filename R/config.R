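#' Molecular weight of methylprednisolone
#'
#' Used to convert plasma concentrations from mg/L to nM for receptor binding
#' (the association rate constant `kon` is expressed in 1/nM/h). The value can
#' be overridden in [to_nanomolar()].
#'
#' @format Scalar, g/mol.
#' @export
MPL_MW <- 374.47

# package-local cache for the parsed parameter configuration
.mplgluc_env <- new.env(parent = emptyenv())

#' Load the packaged model parameter configuration
#'
#' Reads the YAML file shipped under `extdata/parameters.yaml` (or a
#' user-supplied file with the same layout) holding the fixed pharmacokinetic
#' and pharmacodynamic parameter tables: PK constants for the IV/infusion and
#' IM routes, glucocorticoid receptor dynamics per tissue, leptin/food-intake
#' parameters, the hepatic cAMP/PEPCK cascade, the muscle IL6R1/IRS-1 cascade
#' and the systemic glucose-insulin-FFA constants with per-study baselines.
#' Day-based food-intake rates are converted to hours here so that every
#' coupled ODE shares one clock.
#'
#' @param path Path to a YAML configuration; defaults to the packaged file.
#' @param refresh Re-read the packaged file even if cached.
#' @return Nested list of parameter tables.
#' @export
load_model_config <- function(path = NULL, refresh = FALSE) {
  if (is.null(path)) {
    if (!refresh && !is.null(.mplgluc_env$config)) {
      return(.mplgluc_env$config)
    }
    path <- system.file("extdata", "parameters.yaml", package = "mplgluc")
    if (path == "") {
      # during development (pkgload) inst/ may still be on the source path
      path <- system.file("inst", "extdata", "parameters.yaml", package = "mplgluc")
    }
    cfg <- yaml::read_yaml(path)
    cfg$food <- .food_params_to_hours(cfg$food)
    .mplgluc_env$config <- cfg
    return(cfg)
  }
  cfg <- yaml::read_yaml(path)
  cfg$food <- .food_params_to_hours(cfg$food)
  cfg
}

# converts the day-based food parameters once, keeping the printed values
.food_params_to_hours <- function(food) {
  if (!is.null(food[["kin_Food0"]])) {
    return(food) # already converted
  }
  food$kin_Food0 <- food$kin_Food0_per_day / 24   # kcal/day per h
  food$kin_FoodSS <- food$kin_FoodSS_per_day / 24
  food$kFB <- food$kFB_per_day / 24
  food$kd <- food$kd_per_day / 24
  food$kout_Food <- food$kin_Food0_per_day / food$Food_max / 24  # 1/h
  food
}

# small helper: pick a keyed value from a scalar-or-list YAML entry
.pick <- function(x, key, what = "parameter") {
  if (!is.list(x)) {
    return(x)
  }
  if (!is.null(x[[key]])) {
    return(x[[key]])
  }
  if (!is.null(x$default)) {
    return(x$default)
  }
  stop("no value keyed '", key, "' for ", what, call. = FALSE)
}
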