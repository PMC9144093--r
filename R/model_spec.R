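# Candidate population-PK model specifications.
#
# A model is four typical-value expressions (CL, V1, Q, V2) over a restricted
# covariate vocabulary, a log-normal inter-individual variance matrix over a
# subset of those parameters, and a combined additive + proportional residual
# error model.

PK_PARAMS <- c("CL", "V1", "Q", "V2")

# Covariate names an expression may reference; anything else is rejected at
# load time so that typos surface before a 10^5-patient simulation.
COVARIATE_VOCAB <- c(
  "age", "sexf", "height", "weight", "scr",
  "crcl", "mdrd", "ckdepi",
  "rrt", "crrt", "hd", "burn"
)

ALLOWED_FUNS <- c(
  "+", "-", "*", "/", "^", "(", "exp", "log", "sqrt",
  "ifelse", "pmin", "pmax", "<", ">", "<=", ">=", "=="
)

validate_expr <- function(e, extra_covariates = character(), where = "expression") {
  vars <- all.vars(e)
  funs <- setdiff(all.names(e), vars)
  bad_fun <- setdiff(funs, ALLOWED_FUNS)
  if (length(bad_fun)) {
    stop(sprintf("%s uses disallowed function(s): %s", where,
                 paste(bad_fun, collapse = ", ")))
  }
  vocab <- c(COVARIATE_VOCAB, extra_covariates)
  bad_var <- setdiff(vars, vocab)
  if (length(bad_var)) {
    stop(sprintf("%s references unknown covariate(s): %s", where,
                 paste(bad_var, collapse = ", ")))
  }
  invisible(e)
}

#' Define a candidate population-PK model
#'
#' A two-compartment intravenous-infusion model: typical values of clearance
#' `CL` (L/h), central volume `V1` (L), inter-compartmental clearance `Q`
#' (L/h) and peripheral volume `V2` (L) given as arithmetic expressions over
#' the covariate vocabulary (`age`, `sexf`, `height`, `weight`, `scr`,
#' `crcl`, `mdrd`, `ckdepi` plus discrete flags such as `crrt`); a symmetric
#' positive semi-definite variance matrix `omega` of log-scale random effects
#' on a named subset of the parameters; and a residual error model with
#' additive (mg/L) and proportional (fraction) standard deviations.
#'
#' @param name Model name (used as the class label).
#' @param CL,V1,Q,V2 Typical-value expressions: a number, a string, or a
#'   one-sided formula, e.g. `CL = ~ 3.5 * (crcl / 100)`.
#' @param omega Variance-covariance matrix of the log-normal random effects.
#'   Must carry `dimnames` naming the parameters that receive a random effect
#'   (a subset of `CL`, `V1`, `Q`, `V2`).  A named numeric vector is accepted
#'   as a diagonal matrix.  May be `NULL` (no inter-individual variability).
#' @param residual List with elements `add` and `prop`; at least one must be
#'   strictly positive unless `allow_zero_residual = TRUE` (used for
#'   noise-free constructions).
#' @param label Integer class index used by classifiers (defaults are
#'   assigned by registry loaders).
#' @param extra_covariates Additional covariate names (beyond the built-in
#'   vocabulary) the expressions may reference.
#' @param allow_zero_residual Permit `add = prop = 0`.
#' @return An object of class `pk_model`.
#' @export
#' @examples
#' m <- pk_model("toy",
#'   CL = ~ 3.5 * (crcl / 100), V1 = ~ 0.5 * weight, Q = 6, V2 = 60,
#'   omega = c(CL = 0.09, V1 = 0.04), residual = list(add = 1, prop = 0.2))
pk_model <- function(name, CL, V1, Q, V2, omega = NULL,
                     residual = list(add = 0, prop = 0.2),
                     label = NA_integer_,
                     extra_covariates = character(),
                     allow_zero_residual = FALSE) {
  as_expr <- function(x, nm) {
    e <- if (inherits(x, "formula")) x[[2L]]
    else if (is.character(x)) str2lang(x)
    else if (is.numeric(x)) x
    else if (is.language(x)) x
    else stop(sprintf("typical value '%s' must be numeric, string or formula", nm))
    validate_expr(e, extra_covariates, where = sprintf("model '%s', parameter %s", name, nm))
    e
  }
  pars <- list(CL = as_expr(CL, "CL"), V1 = as_expr(V1, "V1"),
               Q = as_expr(Q, "Q"), V2 = as_expr(V2, "V2"))

  if (!is.null(omega)) {
    if (is.vector(omega) && !is.matrix(omega)) {
      if (is.null(names(omega))) stop("diagonal omega must be a named vector")
      om <- diag(as.numeric(omega), nrow = length(omega))
      dimnames(om) <- list(names(omega), names(omega))
      omega <- om
    }
    if (is.null(rownames(omega))) stop("omega must have parameter dimnames")
    if (!all(rownames(omega) %in% PK_PARAMS)) {
      stop("omega names must be among ", paste(PK_PARAMS, collapse = ", "))
    }
    if (!isSymmetric(unname(omega), tol = 1e-10)) stop("omega must be symmetric")
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-10 * max(abs(ev), 1))) {
      stop(sprintf("model '%s': omega is not positive semi-definite", name))
    }
  }

  residual <- list(add = as.numeric(residual$add %||% 0),
                   prop = as.numeric(residual$prop %||% 0))
  if (residual$add < 0 || residual$prop < 0) stop("residual sds must be non-negative")
  if (!allow_zero_residual && residual$add == 0 && residual$prop == 0) {
    stop(sprintf("model '%s': at least one residual component must be positive", name))
  }

  structure(
    list(name = as.character(name), parameters = pars, omega = omega,
         residual = residual, label = as.integer(label),
         extra_covariates = extra_covariates),
    class = "pk_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pk_model <- function(x, ...) {
  cat(sprintf("<pk_model> %s\n", x$name))
  for (p in PK_PARAMS) {
    cat(sprintf("  %-3s = %s\n", p, deparse(x$parameters[[p]])))
  }
  eta <- if (is.null(x$omega)) "none" else paste(rownames(x$omega), collapse = ", ")
  cat(sprintf("  IIV on: %s; residual add = %g mg/L, prop = %g\n",
              eta, x$residual$add, x$residual$prop))
  invisible(x)
}

#' Typical (population) PK parameter values for a set of patients
#'
#' Evaluates the model's covariate functions for each patient, with no random
#' effects applied (the a-priori population prediction).
#'
#' @param model A [pk_model()].
#' @param cov Covariate `data.frame` (one row per patient).
#' @return A `data.frame` with columns `CL`, `V1`, `Q`, `V2` (L/h, L, L/h, L).
#' @export
typical_values <- function(model, cov) {
  stopifnot(inherits(model, "pk_model"), is.data.frame(cov))
  n <- nrow(cov)
  need <- unique(unlist(lapply(model$parameters, all.vars)))
  miss <- setdiff(need, names(cov))
  if (length(miss)) {
    stop(sprintf("model '%s' requires missing covariate(s): %s",
                 model$name, paste(miss, collapse = ", ")))
  }
  env <- list2env(as.list(cov[need]), parent = baseenv())
  out <- lapply(model$parameters, function(e) rep_len(eval(e, env), n))
  out <- as.data.frame(out)
  if (any(!is.finite(as.matrix(out))) || any(as.matrix(out) < 0) ||
      any(out$CL <= 0) || any(out$V1 <= 0)) {
    stop(sprintf("model '%s' produced non-positive or non-finite typical values", model$name))
  }
  out
}

#' Individual PK parameters from typical values and random effects
#'
#' Applies log-normal random effects: `parameter = typical * exp(eta)` for
#' each parameter named in `eta`'s columns; parameters without a random
#' effect keep their typical value.
#'
#' @param tv Typical-value `data.frame` from [typical_values()].
#' @param eta Matrix of log-scale deviations (one row per patient, columns
#'   named after PK parameters), or `NULL` for none.
#' @return A `data.frame` of individual `CL`, `V1`, `Q`, `V2`.
#' @export
individual_parameters <- function(tv, eta = NULL) {
  out <- tv
  if (!is.null(eta)) {
    eta <- as.matrix(eta)
    for (p in colnames(eta)) out[[p]] <- tv[[p]] * exp(eta[, p])
  }
  out
}
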