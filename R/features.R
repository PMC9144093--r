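# Classification features: population-predicted / observed concentration
# ratios on an hourly grid, with sparse observations imputed forward to the
# unobserved hours.

#' Observation-imputation map for a sampling scenario
#'
#' Prediction hours run 1-12 for every scenario, but observations exist only
#' at the scenario's sampling times.  Each prediction hour is assigned the
#' observation whose value divides the model prediction at that hour:
#' `trough` maps all hours to the 12 h sample; `peak_trough` maps hours 1-6
#' to the 2 h sample and 7-12 to the 12 h sample; `peak_mid_trough` maps
#' 1-4 to 2 h, 5-8 to 5 h and 9-12 to 12 h; `every_hour` maps each hour to
#' itself.
#'
#' @param scenario A [sampling_scenario()] or scenario name.
#' @return Integer vector of length 12: `map[t]` is the observation hour
#'   used at prediction hour `t`.
#' @export
imputation_map <- function(scenario) {
  name <- if (inherits(scenario, "sampling_scenario")) scenario$name else scenario
  switch(name,
    trough = rep(12L, 12),
    peak_trough = c(rep(2L, 6), rep(12L, 6)),
    peak_mid_trough = c(rep(2L, 4), rep(5L, 4), rep(12L, 4)),
    every_hour = 1:12,
    stop("unknown scenario: ", name)
  )
}

#' A-priori population concentration predictions for every candidate model
#'
#' Concentrations under each model's typical values (no random effects, no
#' residual error) for each patient at the hourly prediction grid.
#'
#' @param models List of [pk_model()] objects.
#' @param cov Covariate `data.frame`.
#' @param reg A [regimen()].
#' @param times Prediction times (h); the hourly grid by default.
#' @return Named list (one element per model) of patient x time matrices.
#' @export
predict_population_profiles <- function(models, cov, reg, times = 1:12) {
  if (inherits(models, "pk_model")) models <- list(models)
  out <- lapply(models, function(m) {
    concentration_profile(typical_values(m, cov), reg, times)
  })
  names(out) <- vapply(models, function(m) m$name, character(1))
  out
}

#' Build the classifier feature matrix
#'
#' For each candidate model m and prediction hour t, feature
#' `(m, t) = C_PRED[m, t] / C_OBS[impute(t)]`: the model's a-priori
#' prediction divided by the (imputed) observed concentration.  With M
#' candidate models this yields 12 x M columns per patient, ordered
#' model-major (all 12 hours of model 1, then model 2, ...).
#'
#' @param cohort A [generate_cohort()] result (supplies observed profiles,
#'   covariates, scenario and labels).
#' @param models Candidate models to predict with; defaults to the cohort's
#'   generating models (internal validation).  For external cohorts pass
#'   the internal candidate registry here.
#' @param log_ratio If `TRUE`, features are natural-log ratios instead of
#'   raw ratios.
#' @return Object of class `feature_matrix`: `x` (numeric matrix with
#'   stable column names `<model>.t<hour>`), `label` (factor; levels are the
#'   candidate-model names, entries `NA` for labels outside the candidate
#'   set), `scenario`, `model_names`.
#' @export
build_features <- function(cohort, models = NULL, log_ratio = FALSE) {
  stopifnot(inherits(cohort, "virtual_cohort"))
  if (is.null(models)) models <- cohort$models
  if (inherits(models, "pk_model")) models <- list(models)
  map <- imputation_map(cohort$scenario)
  obs_times <- cohort$scenario$times
  idx <- match(map, obs_times)
  if (anyNA(idx)) {
    stop("scenario/profile mismatch: observation missing at hour(s) ",
         paste(unique(map[is.na(idx)]), collapse = ", "))
  }
  obs_imp <- cohort$observed[, idx, drop = FALSE] # n x 12
  cpred <- predict_population_profiles(models, cohort$covariates,
                                       cohort$regimen, times = 1:12)
  blocks <- lapply(cpred, function(p) p / obs_imp)
  x <- do.call(cbind, blocks)
  model_names <- names(cpred)
  colnames(x) <- as.vector(vapply(model_names,
    function(nm) sprintf("%s.t%02d", nm, 1:12), character(12)))
  if (log_ratio) x <- log(x)
  if (any(!is.finite(x))) stop("non-finite feature values (observed floor violated?)")
  label <- factor(as.character(cohort$label), levels = model_names)
  structure(list(x = x, label = label, scenario = cohort$scenario,
                 model_names = model_names, log_ratio = log_ratio),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d features (%d models), scenario %s/%s\n",
              nrow(x$x), ncol(x$x), length(x$model_names),
              x$scenario$name, x$scenario$dosing))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' Plain CSV with one header row of feature names plus a final `label`
#' column; round-trips losslessly up to numeric text precision.
#'
#' @param fm A [build_features()] result.
#' @param path File path.
#' @return `read_features` returns a list with `x` and `label` (scenario
#'   metadata is not stored in the CSV).
#' @export
write_features <- function(fm, path) {
  df <- as.data.frame(fm$x)
  df$label <- as.character(fm$label)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("feature CSV must have a 'label' column")
  lab <- factor(df$label)
  df$label <- NULL
  list(x = as.matrix(df), label = lab)
}
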