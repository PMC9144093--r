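# Virtual-patient generation: correlated demographics and labelled cohorts.

#' Demographic distribution model
#'
#' Continuous covariates (age, height, weight, serum creatinine) are drawn
#' from a truncated multivariate normal; sex is assigned deterministically to
#' the configured ratio; discrete flags are independent Bernoulli.
#'
#' Defaults are the adult hospital population simulated throughout this
#' package: age 50.2 (17.1) years, height 165.1 (8.7) cm, weight 65.1 (10.2)
#' kg, serum creatinine 0.8 (0.2) mg/dL, 1:1 sex ratio.  The covariate
#' correlation matrix defaults to identity; supply any positive
#' semi-definite matrix to impose correlation.
#'
#' @param means,sds Named numeric vectors over `age`, `height`, `weight`,
#'   `scr`.
#' @param corr 4x4 correlation matrix (unit diagonal, PSD), variable order
#'   `age`, `height`, `weight`, `scr`.
#' @param sex_ratio Proportion of male patients in `[0, 1]`.
#' @param lower,upper Truncation bounds (out-of-bound draws are resampled,
#'   not clipped).  Defaults: mean +/- 4 sd with floors age >= 18 (adult
#'   populations), height >= 100, weight >= 30, scr >= 0.2.
#' @param flag_prob Named vector of Bernoulli prevalences for discrete
#'   flags, e.g. `c(crrt = 0.15)`.
#' @return Object of class `demographic_model`.
#' @export
demographic_model <- function(means = c(age = 50.2, height = 165.1, weight = 65.1, scr = 0.8),
                              sds = c(age = 17.1, height = 8.7, weight = 10.2, scr = 0.2),
                              corr = diag(4),
                              sex_ratio = 0.5,
                              lower = NULL, upper = NULL,
                              flag_prob = NULL) {
  vars <- c("age", "height", "weight", "scr")
  means <- means[vars]; sds <- sds[vars]
  if (any(is.na(means)) || any(is.na(sds))) stop("means/sds must cover age, height, weight, scr")
  if (any(sds < 0)) stop("sds must be non-negative")
  corr <- as.matrix(corr)
  if (!all(dim(corr) == 4)) stop("corr must be 4x4")
  if (!isSymmetric(unname(corr), tol = 1e-10) || any(abs(diag(corr) - 1) > 1e-10)) {
    stop("corr must be symmetric with unit diagonal")
  }
  if (any(eigen(corr, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
    stop("corr must be positive semi-definite")
  }
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0, 1]")
  floors <- c(age = 18, height = 100, weight = 30, scr = 0.2)
  if (is.null(lower)) lower <- pmax(means - 4 * sds, floors)
  if (is.null(upper)) upper <- means + 4 * sds
  lower <- lower[vars]; upper <- upper[vars]
  if (any(lower > upper)) stop("lower bounds must not exceed upper bounds")
  if (!is.null(flag_prob) && (any(flag_prob < 0) || any(flag_prob > 1))) {
    stop("flag probabilities must be in [0, 1]")
  }
  structure(list(means = means, sds = sds, corr = corr, sex_ratio = sex_ratio,
                 lower = lower, upper = upper, flag_prob = flag_prob),
            class = "demographic_model")
}

#' Draw virtual-patient demographics
#'
#' Samples `n` covariate rows from the demographic model: multivariate
#' normal with the configured correlation, resampled until inside the
#' truncation bounds; sex interleaved to force the exact configured ratio;
#' flags Bernoulli; renal markers derived.
#'
#' @param dem A [demographic_model()].
#' @param n Number of patients.
#' @param seed Integer seed (required: cohorts must be reproducible).
#' @return Covariate `data.frame` (see [covariate_table()]) with an `id`
#'   column.
#' @export
generate_demographics <- function(dem, n, seed) {
  stopifnot(inherits(dem, "demographic_model"), n >= 1)
  vars <- c("age", "height", "weight", "scr")
  D <- diag(dem$sds)
  Sigma <- D %*% dem$corr %*% D
  # chol of a PSD (possibly singular, e.g. zero-sd) covariance
  L <- tryCatch(chol(Sigma), error = function(e) {
    ev <- eigen(Sigma, symmetric = TRUE)
    t(ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 4) %*% t(ev$vectors))
  })
  nf <- length(dem$flag_prob)
  out <- matrix(NA_real_, n, 4, dimnames = list(NULL, vars))
  fl <- matrix(0L, n, nf)
  # one substream per patient (rejection sampling to the bounds happens
  # inside the substream), so enlarging a cohort never perturbs earlier
  # patients
  for (i in seq_len(n)) {
    set.seed(child_seed(seed, 0L, i))
    repeat {
      x <- drop(stats::rnorm(4) %*% L) + dem$means
      if (all(x >= dem$lower & x <= dem$upper)) break
    }
    out[i, ] <- x
    if (nf > 0) fl[i, ] <- stats::rbinom(nf, 1L, dem$flag_prob)
  }
  # deterministic interleave hits the configured sex ratio exactly
  n_male <- cumsum(rep(dem$sex_ratio, n))
  sex <- ifelse(diff(c(0, floor(n_male + 1e-9))) >= 1, "male", "female")
  flags <- list()
  for (j in seq_len(nf)) flags[[names(dem$flag_prob)[j]]] <- fl[, j]
  cov <- covariate_table(age = out[, "age"], sex = sex, height = out[, "height"],
                         weight = out[, "weight"], scr = out[, "scr"], flags = flags)
  cov <- cbind(id = seq_len(n), cov)
  cov
}

#' Blood-sampling scenario
#'
#' The four sparse-sampling designs evaluated by the pipeline, within a
#' 12-hour dosing interval:
#' `trough` samples at 12 h; `peak_trough` at 2 and 12 h; `peak_mid_trough`
#' at 2, 5 and 12 h; `every_hour` at 1-12 h.  Each is combined with either a
#' single dose or steady-state dosing.
#'
#' @param name One of `"trough"`, `"peak_trough"`, `"peak_mid_trough"`,
#'   `"every_hour"`.
#' @param dosing `"single_dose"` or `"steady_state"`.
#' @return Object of class `sampling_scenario` with fields `name`, `times`,
#'   `dosing`.
#' @export
sampling_scenario <- function(name = c("trough", "peak_trough", "peak_mid_trough", "every_hour"),
                              dosing = c("single_dose", "steady_state")) {
  name <- match.arg(name)
  dosing <- match.arg(dosing)
  times <- switch(name,
    trough = 12,
    peak_trough = c(2, 12),
    peak_mid_trough = c(2, 5, 12),
    every_hour = 1:12
  )
  structure(list(name = name, times = times, dosing = dosing),
            class = "sampling_scenario")
}

#' Regimen implied by a sampling scenario
#'
#' 1000 mg infused over 1 h every 12 h.  The `single_dose` state samples
#' during the first dosing interval (hours 1-12 after the first dose) while
#' dosing continues, so the 12-24 h evaluation window spans the second
#' interval and contains the second dose; the `steady_state` state samples
#' within an interval of the established periodic profile.
#'
#' @param scenario A [sampling_scenario()].
#' @param amt,dur,tau Dose amount (mg), infusion duration (h), interval (h).
#' @return A [regimen()].
#' @export
scenario_regimen <- function(scenario, amt = 1000, dur = 1, tau = 12) {
  if (scenario$dosing == "steady_state") {
    regimen(doses = data.frame(time = 0, amt = amt, dur = dur), tau = tau,
            steady_state = TRUE)
  } else {
    # first and second dose are all that reach the 0-24 h horizon
    regimen(doses = data.frame(time = c(0, tau), amt = amt, dur = dur),
            tau = tau, steady_state = FALSE)
  }
}

# Per-patient RNG substream: a fixed mixing of (cohort seed, label, patient),
# so enlarging a cohort never perturbs earlier patients.
child_seed <- function(seed, label, i) {
  s <- (as.double(seed) * 48271 + as.double(label) * 16807 + as.double(i) * 69621)
  as.integer(s %% 2147483587) + 1L
}

#' Generate a labelled virtual cohort
#'
#' Draws one set of demographics and pushes it through every candidate model
#' (the paired design: covariates are identical across labels).  For each
#' patient x generating model: log-normal random effects from the model's
#' omega, true concentrations at the scenario's sampling times, observed
#' concentrations with the model's residual error, and the true AUC over the
#' evaluation window.
#'
#' @param models List of [pk_model()] objects (the generating models).
#' @param dem A [demographic_model()].
#' @param n_per_model Patients per generating model.
#' @param scenario A [sampling_scenario()].
#' @param seed Integer seed.
#' @param window AUC evaluation window in hours after the first dose.
#' @param obs_floor Lower bound for observed concentrations (mg/L).
#' @return Object of class `virtual_cohort`: `covariates` (stacked, with
#'   global `id`), `label` (factor of generating model names), `params`
#'   (true individual parameters), `true` and `observed` concentration
#'   matrices (columns = scenario times), `true_auc`, plus the `scenario`,
#'   `regimen`, `models` and `seed` used.
#' @export
generate_cohort <- function(models, dem, n_per_model, scenario, seed,
                            window = c(12, 24), obs_floor = 0.01) {
  stopifnot(inherits(scenario, "sampling_scenario"))
  if (inherits(models, "pk_model")) models <- list(models)
  model_names <- vapply(models, function(m) m$name, character(1))
  if (anyDuplicated(model_names)) stop("model names must be unique")
  reg <- scenario_regimen(scenario)
  base_cov <- generate_demographics(dem, n_per_model, seed)
  times <- scenario$times

  cov_all <- list(); par_all <- list(); true_all <- list(); obs_all <- list()
  auc_all <- list(); lab_all <- list()
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    tv <- typical_values(m, base_cov)
    k <- if (is.null(m$omega)) 0L else nrow(m$omega)
    eta <- NULL
    noise <- matrix(0, n_per_model, length(times))
    if (k > 0) {
      eta <- matrix(0, n_per_model, k, dimnames = list(NULL, rownames(m$omega)))
    }
    Lo <- if (k > 0) {
      tryCatch(chol(m$omega), error = function(e) {
        ev <- eigen(m$omega, symmetric = TRUE)
        t(ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors))
      })
    }
    for (i in seq_len(n_per_model)) {
      set.seed(child_seed(seed, mi, i))
      if (k > 0) eta[i, ] <- drop(stats::rnorm(k) %*% Lo)
      noise[i, ] <- stats::rnorm(length(times))
    }
    ip <- individual_parameters(tv, eta)
    true <- concentration_profile(ip, reg, times)
    sd <- sqrt(m$residual$add^2 + (m$residual$prop * true)^2)
    obs <- pmax(true + noise * sd, obs_floor)
    cov_all[[mi]] <- base_cov
    par_all[[mi]] <- ip
    true_all[[mi]] <- true
    obs_all[[mi]] <- obs
    auc_all[[mi]] <- auc_interval(ip, reg, window[1], window[2])
    lab_all[[mi]] <- rep(m$name, n_per_model)
  }
  covariates <- do.call(rbind, cov_all)
  covariates$id <- seq_len(nrow(covariates))
  structure(list(
    covariates = covariates,
    label = factor(unlist(lab_all), levels = model_names),
    params = do.call(rbind, par_all),
    true = do.call(rbind, true_all),
    observed = do.call(rbind, obs_all),
    true_auc = unlist(auc_all),
    scenario = scenario, regimen = reg, models = models,
    window = window, seed = seed
  ), class = "virtual_cohort")
}

#' @export
print.virtual_cohort <- function(x, ...) {
  cat(sprintf("<virtual_cohort> %d patients, %d models, scenario %s/%s\n",
              nrow(x$covariates), length(x$models), x$scenario$name,
              x$scenario$dosing))
  invisible(x)
}

#' True exposure of a cohort's patients
#'
#' Recomputes the AUC over a window from each patient's true individual
#' parameters (the reference value every prediction method is scored
#' against).
#'
#' @param cohort A [generate_cohort()] result.
#' @param window AUC window (h); defaults to the cohort's own.
#' @return Numeric vector of AUCs (mg.h/L).
#' @export
true_auc <- function(cohort, window = NULL) {
  stopifnot(inherits(cohort, "virtual_cohort"))
  if (is.null(window)) window <- cohort$window
  auc_interval(cohort$params, cohort$regimen, window[1], window[2])
}
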