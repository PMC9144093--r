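#' Construct a covariate table
#'
#' Builds the per-patient covariate table used throughout the package: one row
#' per patient, with demographic fields, optional discrete flags (renal
#' replacement therapy, burns, ...) and the derived renal-function markers.
#'
#' @param age Age in years (strictly positive).
#' @param sex Character vector, `"male"` or `"female"`.
#' @param height Height in cm.
#' @param weight Total body weight in kg.
#' @param scr Serum creatinine in mg/dL.
#' @param flags Named list of 0/1 vectors for discrete covariates
#'   (e.g. `list(crrt = c(0, 1))`); recycled to the number of patients.
#'
#' @return A `data.frame` with columns `age`, `sex`, `sexf` (1 for female),
#'   `height`, `weight`, `scr`, any flag columns, and the derived markers
#'   `crcl` (Cockcroft-Gault, mL/min), `mdrd` and `ckdepi`
#'   (mL/min/1.73 m^2).
#' @export
#' @examples
#' covariate_table(age = 50, sex = "male", height = 170, weight = 65, scr = 0.8)
covariate_table <- function(age, sex, height, weight, scr, flags = list()) {
  n <- max(length(age), length(sex), length(height), length(weight), length(scr))
  df <- data.frame(
    age = rep_len(as.numeric(age), n),
    sex = rep_len(as.character(sex), n),
    height = rep_len(as.numeric(height), n),
    weight = rep_len(as.numeric(weight), n),
    scr = rep_len(as.numeric(scr), n),
    stringsAsFactors = FALSE
  )
  bad <- !df$sex %in% c("male", "female")
  if (any(bad)) stop("sex must be 'male' or 'female'")
  for (v in c("age", "height", "weight", "scr")) {
    if (any(!is.finite(df[[v]]) | df[[v]] <= 0)) {
      stop(sprintf("covariate '%s' must be finite and strictly positive", v))
    }
  }
  df$sexf <- as.numeric(df$sex == "female")
  for (nm in names(flags)) {
    fl <- rep_len(as.numeric(flags[[nm]]), n)
    if (any(!fl %in% c(0, 1))) stop(sprintf("flag '%s' must be 0/1", nm))
    df[[nm]] <- fl
  }
  compute_renal_markers(df)
}

#' Derive renal-function markers
#'
#' Fills (or refreshes) the three renal markers used as PK-model covariates:
#' Cockcroft-Gault creatinine clearance (`crcl`, mL/min), the four-variable
#' IDMS-traceable MDRD estimate (`mdrd`) and the 2009 CKD-EPI creatinine
#' equation (`ckdepi`), both in mL/min/1.73 m^2.  Race terms are omitted.
#'
#' @param cov A covariate `data.frame` as built by [covariate_table()] (the
#'   columns `age`, `sex`, `weight`, `scr` must be present and valid).
#' @return The input with `crcl`, `mdrd` and `ckdepi` columns (re)computed;
#'   all other columns are untouched.
#' @export
compute_renal_markers <- function(cov) {
  stopifnot(is.data.frame(cov))
  need <- c("age", "sex", "weight", "scr")
  miss <- setdiff(need, names(cov))
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(cov$scr) | cov$scr <= 0)) {
    stop("serum creatinine must be finite and strictly positive")
  }
  female <- cov$sex == "female"

  crcl <- (140 - cov$age) * cov$weight / (72 * cov$scr)
  crcl[female] <- 0.85 * crcl[female]

  mdrd <- 175 * cov$scr^-1.154 * cov$age^-0.203
  mdrd[female] <- 0.742 * mdrd[female]

  kappa <- ifelse(female, 0.7, 0.9)
  a <- ifelse(female, -0.329, -0.411)
  r <- cov$scr / kappa
  ckdepi <- 141 * pmin(r, 1)^a * pmax(r, 1)^-1.209 * 0.993^cov$age
  ckdepi[female] <- 1.018 * ckdepi[female]

  cov$crcl <- pmax(crcl, 0)
  cov$mdrd <- pmax(mdrd, 0)
  cov$ckdepi <- pmax(ckdepi, 0)
  cov
}
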