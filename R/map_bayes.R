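# Maximum a posteriori (empirical Bayes) estimation of individual PK
# parameters under one candidate model, and the objective-function-value
# (OFV) machinery used for model averaging.

# -2 log joint density (up to an additive constant):
#   OFV(eta) = sum_j [ (y_j - f_j)^2 / g_j^2 + log g_j^2 ] + eta' Omega^-1 eta
# with f_j the model-predicted concentration and residual variance
# g_j^2 = add^2 + (prop * f_j)^2 evaluated at the model prediction.

#' MAP estimate of one patient's random effects under one model
#'
#' Minimises the standard MAP objective (data likelihood with combined
#' additive + proportional residual variance, plus the log-normal prior on
#' the random effects) by quasi-Newton search started at the prior mode
#' `eta = 0`, with jittered restarts on non-convergence.
#'
#' @param model A [pk_model()] with a non-null, invertible `omega`.
#' @param cov One-row covariate `data.frame` for the patient.
#' @param reg The dosing [regimen()].
#' @param times Observation times (h).
#' @param dv Observed concentrations (mg/L) at `times`.
#' @param restarts Maximum jittered restarts on non-convergence.
#' @return Object of class `map_result`: `eta` (named), `params`
#'   (individual `CL`, `V1`, `Q`, `V2`), `ofv` (the minimised objective),
#'   `converged`, `n_obs`.
#' @export
map_estimate <- function(model, cov, reg, times, dv, restarts = 5) {
  stopifnot(inherits(model, "pk_model"), length(times) >= 1,
            length(times) == length(dv))
  if (is.null(model$omega)) stop("model has no random effects to estimate")
  Oinv <- tryCatch(solve(model$omega), error = function(e) {
    stop(sprintf("model '%s': omega is singular", model$name))
  })
  tv <- typical_values(model, cov[1, , drop = FALSE])
  eta_names <- rownames(model$omega)
  k <- length(eta_names)
  add2 <- model$residual$add^2
  prop <- model$residual$prop
  tvv <- as.numeric(tv[1, PK_PARAMS]); names(tvv) <- PK_PARAMS

  pre <- .precompute_events(reg, times)
  obj <- function(eta) {
    # the kinetics argument is clamped (|eta| = 20 is an e^20-fold deviation,
    # far beyond any plausible mode) to keep exp() away from under/overflow
    # during line searches, but the prior quadratic stays on the raw eta so
    # the objective keeps growing outside the clamp and the search is pulled
    # back rather than stranded on a flat region
    eta_k <- pmax(pmin(eta, 20), -20)
    p <- tvv
    p[eta_names] <- p[eta_names] * exp(eta_k)
    f <- .conc_fast(p[["CL"]], p[["V1"]], p[["Q"]], p[["V2"]], pre)
    g2 <- pmax(add2 + (prop * f)^2, 1e-12)
    val <- sum((dv - f)^2 / g2 + log(g2)) + drop(eta %*% Oinv %*% eta)
    if (!is.finite(val)) 1e10 else val
  }

  best <- NULL
  eta0 <- rep(0, k)
  for (attempt in 0:restarts) {
    start <- if (attempt == 0) eta0 else eta0 + stats::rnorm(k, 0, 0.3)
    fit <- tryCatch(
      stats::optim(start, obj, method = "BFGS",
                   control = list(reltol = 1e-10, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) break
  }
  if (is.null(best)) stop("MAP optimisation failed for model ", model$name)
  # the optimum can never be worse than the prior mode we started from
  if (best$value > obj(eta0)) {
    best <- list(par = eta0, value = obj(eta0), convergence = 0L)
  }
  eta <- pmax(pmin(best$par, 20), -20)
  names(eta) <- eta_names
  p <- tvv
  p[eta_names] <- p[eta_names] * exp(eta)
  structure(list(eta = eta,
                 params = as.data.frame(as.list(p)),
                 ofv = best$value,
                 converged = best$convergence == 0,
                 n_obs = length(dv)),
            class = "map_result")
}

#' @export
print.map_result <- function(x, ...) {
  cat(sprintf("<map_result> ofv %.4f (%sconverged, %d obs)\n  eta: %s\n",
              x$ofv, if (x$converged) "" else "NOT ", x$n_obs,
              paste(sprintf("%s=%.3f", names(x$eta), x$eta), collapse = ", ")))
  invisible(x)
}

#' Softmax model weights from objective-function values
#'
#' `w_m = exp(-OFV_m / 2) / sum_m exp(-OFV_m / 2)`, computed after shifting
#' by the minimum OFV so extreme values neither overflow nor underflow all
#' at once.  Adding a constant to every OFV leaves the weights unchanged.
#'
#' @param ofvs Numeric vector of finite OFVs (one per candidate model).
#' @return Numeric weights, non-negative, summing to 1.
#' @export
ofv_weights <- function(ofvs) {
  if (length(ofvs) == 0) stop("empty OFV vector")
  if (any(!is.finite(ofvs))) stop("OFVs must be finite")
  w <- exp(-0.5 * (ofvs - min(ofvs)))
  w / sum(w)
}

#' Fit every patient of a cohort under every candidate model
#'
#' The batch driver behind the TDM evaluation: one MAP fit per patient x
#' model, returning the OFV matrix and the per-model AUC predictions over
#' the evaluation window.
#'
#' @param cohort A [generate_cohort()] result.
#' @param models Candidate models used as estimation priors (defaults to
#'   the cohort's generating models).
#' @param window AUC window (h); defaults to the cohort's.
#' @return List: `ofv` and `auc` (patient x model matrices with model-name
#'   columns), `converged` (logical matrix), `window`.
#' @export
map_fit_cohort <- function(cohort, models = NULL, window = NULL) {
  stopifnot(inherits(cohort, "virtual_cohort"))
  if (is.null(models)) models <- cohort$models
  if (inherits(models, "pk_model")) models <- list(models)
  if (is.null(window)) window <- cohort$window
  n <- nrow(cohort$covariates)
  M <- length(models)
  model_names <- vapply(models, function(m) m$name, character(1))
  ofv <- matrix(NA_real_, n, M, dimnames = list(NULL, model_names))
  auc <- matrix(NA_real_, n, M, dimnames = list(NULL, model_names))
  conv <- matrix(NA, n, M, dimnames = list(NULL, model_names))
  times <- cohort$scenario$times
  for (mi in seq_len(M)) {
    for (i in seq_len(n)) {
      r <- map_estimate(models[[mi]], cohort$covariates[i, , drop = FALSE],
                        cohort$regimen, times, cohort$observed[i, ])
      ofv[i, mi] <- r$ofv
      auc[i, mi] <- auc_interval(r$params, cohort$regimen, window[1], window[2])
      conv[i, mi] <- r$converged
    }
  }
  list(ofv = ofv, auc = auc, converged = conv, window = window)
}

#' Batch MAP estimation over a NONMEM-style dataset
#'
#' Fits every subject in the dataset under every candidate model and
#' returns a long-format table.
#'
#' @param data A NONMEM-style `data.frame` as read by [read_dataset()].
#' @param models List of candidate [pk_model()]s.
#' @return `data.frame` with one row per subject x model: `ID`, `model`,
#'   the individual `CL`, `V1`, `Q`, `V2`, `OFV`, `converged`, `n_obs`.
#' @export
map_fit_dataset <- function(data, models) {
  if (inherits(models, "pk_model")) models <- list(models)
  subjects <- split_dataset(data)
  rows <- list()
  for (s in subjects) {
    for (m in models) {
      r <- map_estimate(m, s$covariates, s$regimen, s$times, s$dv)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(ID = s$id, model = m$name),
        r$params, OFV = r$ofv, converged = r$converged, n_obs = r$n_obs)
    }
  }
  do.call(rbind, rows)
}
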