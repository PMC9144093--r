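# Configuration and data interchange: YAML model specs and the NONMEM-style
# patient dataset CSV that links simulation, estimation and classification.

#' Load PK model specifications from YAML
#'
#' Each YAML file defines one candidate model:
#' ```yaml
#' name: toy_fast
#' label: 1
#' parameters:
#'   CL: "3.5 * (crcl / 100)"
#'   V1: "0.5 * weight"
#'   Q: "6.0"
#'   V2: "60"
#' omega:            # lower triangle, row-wise, over `names`
#'   names: [CL, V1]
#'   values: [0.09, 0.0, 0.04]
#' residual: {add: 1.0, prop: 0.2}
#' ```
#' Expressions are restricted to arithmetic, `exp`/`log`/`sqrt`, comparisons
#' and `ifelse` over the covariate vocabulary; unknown names and non-PSD
#' omegas are rejected at load with the offending field.  Every model is
#' probe-evaluated on a reference patient so broken covariate functions fail
#' here, not mid-simulation.
#'
#' @param path A directory (all `*.yaml`/`*.yml` files, sorted) or a
#'   character vector of files.
#' @return List of [pk_model()] objects; labels default to file order.
#' @export
load_model_specs <- function(path) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    sort(list.files(path, pattern = "\\.ya?ml$", full.names = TRUE))
  } else path
  if (!length(files)) stop("no model-spec files found at ", path)
  models <- vector("list", length(files))
  for (i in seq_along(files)) {
    spec <- tryCatch(yaml::read_yaml(files[i]), error = function(e) {
      stop(sprintf("%s: cannot parse YAML (%s)", files[i], conditionMessage(e)))
    })
    for (field in c("name", "parameters")) {
      if (is.null(spec[[field]])) stop(sprintf("%s: missing field '%s'", files[i], field))
    }
    for (p in PK_PARAMS) {
      if (is.null(spec$parameters[[p]])) {
        stop(sprintf("%s: missing parameter expression '%s'", files[i], p))
      }
    }
    omega <- NULL
    if (!is.null(spec$omega)) {
      nm <- spec$omega$names
      vals <- as.numeric(spec$omega$values)
      k <- length(nm)
      if (length(vals) != k * (k + 1) / 2) {
        stop(sprintf("%s: omega needs %d lower-triangle values for %d names",
                     files[i], k * (k + 1) / 2, k))
      }
      omega <- matrix(0, k, k, dimnames = list(nm, nm))
      omega[upper.tri(omega, diag = TRUE)] <- vals # row-wise lower = col-wise upper
      omega <- omega + t(omega) - diag(diag(omega), k)
    }
    m <- tryCatch(
      pk_model(spec$name,
               CL = as.character(spec$parameters$CL),
               V1 = as.character(spec$parameters$V1),
               Q = as.character(spec$parameters$Q),
               V2 = as.character(spec$parameters$V2),
               omega = omega,
               residual = spec$residual %||% list(add = 0, prop = 0.2),
               label = spec$label %||% i),
      error = function(e) stop(sprintf("%s: %s", files[i], conditionMessage(e))))
    # probe evaluation: a reference adult with all flags at 0
    probe <- covariate_table(age = 50, sex = "male", height = 170, weight = 70,
                             scr = 0.9,
                             flags = list(rrt = 0, crrt = 0, hd = 0, burn = 0))
    tryCatch(typical_values(m, probe), error = function(e) {
      stop(sprintf("%s: probe evaluation failed: %s", files[i], conditionMessage(e)))
    })
    models[[i]] <- m
  }
  names(models) <- vapply(models, function(m) m$name, character(1))
  models
}

#' Bundled candidate-model registries
#'
#' `internal_models()` returns the nine bundled two-compartment vancomycin
#' models used as classifier labels and estimation priors;
#' `external_models()` returns the four bundled models for special
#' populations (renal replacement therapy, hemodialysis, burns, ICU) used
#' only to generate external validation cohorts.  All thirteen are
#' synthetic: vancomycin-like parameterisations spanning published adult
#' ranges, shipped as editable YAML under `inst/extdata/models/`.
#'
#' @return List of [pk_model()] objects.
#' @export
internal_models <- function() {
  load_model_specs(system.file("extdata", "models", "internal", package = "tdmsel"))
}

#' @rdname internal_models
#' @export
external_models <- function() {
  load_model_specs(system.file("extdata", "models", "external", package = "tdmsel"))
}

NONMEM_COLS <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "MDV")

#' Export a cohort as a NONMEM-style dataset
#'
#' One dosing record (`EVID = 1`, `RATE = AMT / duration`) per dose and one
#' observation record (`EVID = 0`, `MDV = 0`) per sample, with covariate
#' columns appended.  Steady-state regimens carry `SS = 1` and `II = tau`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param path Optional CSV path; when given, the table is also written.
#' @return The dataset `data.frame` (invisibly when `path` is given).
#' @export
write_dataset <- function(cohort, path = NULL) {
  stopifnot(inherits(cohort, "virtual_cohort"))
  reg <- cohort$regimen
  times <- cohort$scenario$times
  covcols <- setdiff(names(cohort$covariates), "id")
  rows <- list()
  for (i in seq_len(nrow(cohort$covariates))) {
    dose <- data.frame(ID = i, TIME = reg$doses$time, EVID = 1L,
                       AMT = reg$doses$amt, RATE = reg$doses$amt / reg$doses$dur,
                       DV = NA_real_, MDV = 1L,
                       SS = as.integer(reg$steady_state),
                       II = if (reg$steady_state) reg$tau else 0)
    obs <- data.frame(ID = i, TIME = times, EVID = 0L, AMT = 0, RATE = 0,
                      DV = cohort$observed[i, ], MDV = 0L, SS = 0L, II = 0)
    rec <- rbind(dose, obs)
    rec <- cbind(rec, cohort$covariates[rep(i, nrow(rec)), covcols, drop = FALSE])
    rows[[i]] <- rec
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = ".")
    return(invisible(df))
  }
  df
}

#' Read and validate a NONMEM-style dataset
#'
#' Requires columns `ID, TIME, EVID, AMT, RATE, DV, MDV`; `.` is read as
#' missing; dosing records must carry a positive `RATE`.  Unknown columns
#' are preserved.
#'
#' @param path CSV path or a `data.frame` to validate in place.
#' @return Validated `data.frame`.
#' @export
read_dataset <- function(path) {
  df <- if (is.data.frame(path)) path
  else utils::read.csv(path, na.strings = c("NA", "."), check.names = FALSE)
  miss <- setdiff(NONMEM_COLS, names(df))
  if (length(miss)) stop("dataset is missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  doses <- df$EVID == 1
  if (any(doses & (is.na(df$RATE) | df$RATE <= 0))) {
    stop("dosing records (EVID=1) must have a positive RATE (infusion)")
  }
  if (any(df$EVID == 0 & df$MDV == 0 & is.na(df$DV))) {
    stop("observation records with MDV=0 must carry DV")
  }
  df
}

#' Split a dataset into per-subject estimation inputs
#'
#' Observation rows with `MDV = 1` are retained in the file contract but
#' excluded from estimation.
#'
#' @param data A [read_dataset()] result.
#' @return List (one element per subject) with `id`, `covariates` (one-row
#'   `data.frame`), `regimen`, `times`, `dv`.
#' @export
split_dataset <- function(data) {
  data <- read_dataset(data)
  lapply(split(data, data$ID), function(d) {
    dose <- d[d$EVID == 1, , drop = FALSE]
    obs <- d[d$EVID == 0 & d$MDV == 0, , drop = FALSE]
    ss <- "SS" %in% names(d) && any(dose$SS == 1, na.rm = TRUE)
    reg <- regimen(doses = data.frame(time = dose$TIME, amt = dose$AMT,
                                      dur = dose$AMT / dose$RATE),
                   tau = if (ss) dose$II[dose$SS == 1][1] else 12,
                   steady_state = ss)
    covcols <- intersect(c("age", "sex", "sexf", "height", "weight", "scr",
                           "crcl", "mdrd", "ckdepi", "rrt", "crrt", "hd", "burn"),
                         names(d))
    list(id = d$ID[1], covariates = d[1, covcols, drop = FALSE],
         regimen = reg, times = obs$TIME, dv = obs$DV)
  })
}
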