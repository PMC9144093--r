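# Exposure prediction by model selection / averaging and the error metrics
# used to score each method against the true AUC.

#' AUC chosen by the classifier (model selection)
#'
#' Returns the per-model AUC of the highest-probability model; ties are
#' broken by the lowest model index.
#'
#' @param prob Probability matrix (patients x models) or vector.
#' @param auc Matching AUC matrix (patients x models) or vector, mg.h/L.
#' @return Numeric vector of selected AUCs.
#' @export
ml_selection_auc <- function(prob, auc) {
  prob <- rbind(prob); auc <- rbind(auc)
  stopifnot(all(dim(prob) == dim(auc)))
  sel <- max.col(prob, ties.method = "first")
  unname(auc[cbind(seq_len(nrow(auc)), sel)])
}

#' Probability-weighted average AUC
#'
#' `sum_m p_m * AUC_m` per patient: the classifier's class probabilities
#' used as model-averaging weights.
#'
#' @inheritParams ml_selection_auc
#' @return Numeric vector of weighted AUCs.
#' @export
ml_weighted_auc <- function(prob, auc) {
  prob <- rbind(prob); auc <- rbind(auc)
  stopifnot(all(dim(prob) == dim(auc)))
  if (any(abs(rowSums(prob) - 1) > 1e-6)) stop("probability rows must sum to 1")
  unname(rowSums(prob * auc))
}

#' Oracle (perfect-selection) AUC
#'
#' The AUC estimated under each patient's true generating model: the upper
#' bound a classifier-driven method can aim for.  Defined only for internal
#' cohorts, where the generating models are among the estimation candidates.
#'
#' @param label Factor/character of generating-model names.
#' @param auc AUC matrix with model-name columns.
#' @return Numeric vector.
#' @export
perfect_selection_auc <- function(label, auc) {
  auc <- rbind(auc)
  j <- match(as.character(label), colnames(auc))
  if (anyNA(j)) {
    stop("perfect selection is undefined: generating model(s) ",
         paste(unique(as.character(label)[is.na(j)]), collapse = ", "),
         " are not among the estimation candidates (external cohort)")
  }
  unname(auc[cbind(seq_len(nrow(auc)), j)])
}

#' OFV-based selection / weighted-average AUC
#'
#' Converts each patient's per-model objective-function values to softmax
#' weights ([ofv_weights()]); `mode = "select"` returns the AUC of the
#' highest-weight (lowest-OFV) model, `mode = "weight"` the weighted
#' average.
#'
#' @param ofv OFV matrix (patients x models) or vector.
#' @param auc Matching AUC matrix.
#' @param mode `"select"` or `"weight"`.
#' @return Numeric vector.
#' @export
ofv_method_auc <- function(ofv, auc, mode = c("select", "weight")) {
  mode <- match.arg(mode)
  ofv <- rbind(ofv); auc <- rbind(auc)
  stopifnot(all(dim(ofv) == dim(auc)))
  w <- t(apply(ofv, 1, ofv_weights))
  if (nrow(ofv) == 1) w <- rbind(as.vector(w))
  if (mode == "select") {
    unname(auc[cbind(seq_len(nrow(auc)), max.col(w, ties.method = "first"))])
  } else {
    unname(rowSums(w * auc))
  }
}

#' Mean percent error
#'
#' `MPE = mean((predicted - true) / true) * 100` (%): signed relative bias.
#'
#' @param predicted,true Numeric vectors of equal length; `true` strictly
#'   positive.
#' @return Scalar, percent.
#' @export
mpe <- function(predicted, true) {
  if (length(predicted) != length(true)) stop("length mismatch")
  if (any(true <= 0)) stop("true AUC must be strictly positive")
  mean((predicted - true) / true) * 100
}

#' Relative root mean squared error
#'
#' `rRMSE = sqrt(mean(((predicted - true) / true)^2)) * 100` (%): the root
#' of the patient-mean squared relative error.
#'
#' @inheritParams mpe
#' @return Scalar, percent.
#' @export
rrmse <- function(predicted, true) {
  if (length(predicted) != length(true)) stop("length mismatch")
  if (any(true <= 0)) stop("true AUC must be strictly positive")
  sqrt(mean(((predicted - true) / true)^2)) * 100
}

#' Score every AUC-prediction method on a validation cohort
#'
#' Builds the per-method predicted AUCs (each single model, perfect
#' selection on internal cohorts, classifier selection and weighting, the
#' non-weighted average, and OFV selection/weighting) and scores each with
#' [mpe()] and [rrmse()] against the true AUC.
#'
#' @param cohort Validation [generate_cohort()] result.
#' @param fits [map_fit_cohort()] result for the candidate models.
#' @param prob Classifier probability matrix over the candidate models
#'   (columns ordered as `fits$auc`), or `NULL` to skip the ML methods.
#' @param internal If `TRUE`, include perfect selection (requires the
#'   generating models to be the candidates).
#' @return List: `table` (`data.frame` of method, MPE, rRMSE, N) and
#'   `predictions` (patients x methods matrix of predicted AUCs).
#' @export
evaluate_methods <- function(cohort, fits, prob = NULL, internal = TRUE) {
  auc <- fits$auc
  truth <- cohort$true_auc
  preds <- list()
  for (m in colnames(auc)) preds[[m]] <- auc[, m]
  if (internal) preds[["perfect_selection"]] <- perfect_selection_auc(cohort$label, auc)
  if (!is.null(prob)) {
    if (!identical(colnames(prob), colnames(auc))) {
      prob <- prob[, colnames(auc), drop = FALSE]
    }
    preds[["ml_selection"]] <- ml_selection_auc(prob, auc)
    preds[["ml_weighted"]] <- ml_weighted_auc(prob, auc)
  }
  preds[["nonweighted_average"]] <- rowMeans(auc)
  preds[["ofv_selection"]] <- ofv_method_auc(fits$ofv, auc, "select")
  preds[["ofv_weighted"]] <- ofv_method_auc(fits$ofv, auc, "weight")
  tab <- data.frame(
    method = names(preds),
    mpe = vapply(preds, mpe, numeric(1), true = truth),
    rrmse = vapply(preds, rrmse, numeric(1), true = truth),
    n = length(truth), row.names = NULL)
  list(table = tab, predictions = do.call(cbind, preds))
}

#' Run the full simulation study over a scenario grid
#'
#' For every dosing state x sampling scenario: simulate a training cohort
#' from the candidate models, build ratio features, train the classifier,
#' then simulate a paired validation cohort (and optionally an external
#' cohort from a disjoint model set), MAP-fit every patient under every
#' candidate model, predict the AUC by every method, and score MPE / rRMSE.
#'
#' @param models Candidate (internal) models: generators for training and
#'   internal validation, and the estimation priors everywhere.
#' @param dem A [demographic_model()] (shared by all cohorts).
#' @param scenarios Character vector of sampling-scenario names.
#' @param dosing Character vector of dosing states.
#' @param n_train,n_valid Patients per model for the training and
#'   validation cohorts.
#' @param external_models Optional disjoint model list generating an
#'   external validation cohort of `n_valid` patients per external model.
#' @param algorithm,params Classifier algorithm and hyperparameters (see
#'   [train_classifier()]).
#' @param fit_map If `FALSE`, skip MAP fitting and TDM scoring (classifier
#'   accuracy only).
#' @param window AUC evaluation window (h after first dose; one dosing
#'   interval at steady state).
#' @param seed Integer seed; each scenario derives its own substream.
#' @return Object of class `tdm_report`: `accuracy` (`data.frame` of
#'   scenario, dosing, accuracy, n) and `tdm` (`data.frame` of cohort,
#'   scenario, dosing, method, MPE, rRMSE, N); `reports` holds the per-run
#'   [classification_metrics()] objects.
#' @export
run_scenario <- function(models, dem = demographic_model(),
                         scenarios = c("trough", "peak_trough", "peak_mid_trough", "every_hour"),
                         dosing = c("single_dose", "steady_state"),
                         n_train = 1000, n_valid = 200,
                         external_models = NULL,
                         algorithm = "gradient_boosting", params = list(),
                         fit_map = TRUE, window = c(12, 24), seed = 1) {
  acc_rows <- list(); tdm_rows <- list(); reports <- list()
  run_id <- 0L
  for (dos in dosing) {
    for (sc in scenarios) {
      run_id <- run_id + 1L
      scen <- sampling_scenario(sc, dos)
      s_train <- child_seed(seed, 101L, run_id)
      s_valid <- child_seed(seed, 202L, run_id)
      s_ext <- child_seed(seed, 303L, run_id)
      train <- generate_cohort(models, dem, n_train, scen, seed = s_train,
                               window = window)
      fm_train <- build_features(train)
      clf <- train_classifier(fm_train, algorithm, params,
                              seed = child_seed(seed, 404L, run_id))
      valid <- generate_cohort(models, dem, n_valid, scen, seed = s_valid,
                               window = window)
      fm_valid <- build_features(valid)
      pred <- predict_class(clf, fm_valid)
      rep <- classification_metrics(fm_valid$label, pred)
      key <- sprintf("%s.%s", dos, sc)
      reports[[key]] <- rep
      acc_rows[[key]] <- data.frame(scenario = sc, dosing = dos,
                                    accuracy = rep$accuracy,
                                    n = nrow(fm_valid$x))
      if (fit_map) {
        prob <- predict_probabilities(clf, fm_valid)
        fits <- map_fit_cohort(valid, models, window = window)
        ev <- evaluate_methods(valid, fits, prob, internal = TRUE)
        tdm_rows[[paste0(key, ".internal")]] <-
          cbind(cohort = "internal", scenario = sc, dosing = dos, ev$table)
        if (!is.null(external_models)) {
          ext <- generate_cohort(external_models, dem, n_valid, scen,
                                 seed = s_ext, window = window)
          fm_ext <- build_features(ext, models)
          prob_ext <- predict_probabilities(clf, fm_ext)
          fits_ext <- map_fit_cohort(ext, models, window = window)
          ev_ext <- evaluate_methods(ext, fits_ext, prob_ext, internal = FALSE)
          tdm_rows[[paste0(key, ".external")]] <-
            cbind(cohort = "external", scenario = sc, dosing = dos, ev_ext$table)
        }
      }
    }
  }
  structure(list(accuracy = do.call(rbind, c(acc_rows, list(make.row.names = FALSE))),
                 tdm = if (length(tdm_rows))
                   do.call(rbind, c(tdm_rows, list(make.row.names = FALSE))),
                 reports = reports, seed = seed),
            class = "tdm_report")
}

#' @export
print.tdm_report <- function(x, ...) {
  cat("<tdm_report>\nClassifier accuracy:\n")
  print(x$accuracy, digits = 4)
  if (!is.null(x$tdm)) {
    cat("\nTDM performance (MPE / rRMSE, %):\n")
    print(x$tdm, digits = 4)
  }
  invisible(x)
}
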