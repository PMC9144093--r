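# Deterministic toy fixtures: three well-separated vancomycin-like models
# and a small labelled cohort, used across the test suite and examples.

#' Build the toy fixture set
#'
#' Three two-compartment toy models with well-separated clearances (fast /
#' intermediate / slow elimination, different covariate structures), a
#' 30-patient cohort (10 per model, every-hour single-dose sampling) and its
#' feature matrix.  Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param n_per_model Patients per model in the toy cohort.
#' @param scenario A [sampling_scenario()] for the cohort.
#' @return List: `models`, `dem` (the demographic model used), `cohort`,
#'   `features`.
#' @export
make_fixtures <- function(seed = 42, n_per_model = 10,
                          scenario = sampling_scenario("every_hour", "single_dose")) {
  models <- toy_models()
  dem <- demographic_model()
  cohort <- generate_cohort(models, dem, n_per_model, scenario, seed = seed)
  list(models = models, dem = dem, cohort = cohort,
       features = build_features(cohort))
}

#' @rdname make_fixtures
#' @export
toy_models <- function() {
  list(
    pk_model("toy_fast",
             CL = ~ 6.5 * (crcl / 100), V1 = ~ 0.35 * weight, Q = 8, V2 = 35,
             omega = c(CL = 0.06, V1 = 0.04),
             residual = list(add = 0.5, prop = 0.15), label = 1L),
    pk_model("toy_mid",
             CL = ~ 3.2 * (crcl / 100)^0.75, V1 = ~ 0.55 * weight, Q = 6, V2 = 55,
             omega = c(CL = 0.08, V1 = 0.05),
             residual = list(add = 1.0, prop = 0.2), label = 2L),
    pk_model("toy_slow",
             CL = ~ 1.3 + 0.004 * crcl, V1 = 45, Q = 4, V2 = 80,
             omega = c(CL = 0.05, V1 = 0.06),
             residual = list(add = 0.8, prop = 0.18), label = 3L)
  )
}
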