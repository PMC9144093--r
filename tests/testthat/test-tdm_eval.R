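test_that("selection and averaging rules follow their definitions", {
  expect_equal(ml_selection_auc(c(0.1, 0.7, 0.2), c(100, 200, 300)), 200)
  # exact tie: lowest model index wins
  expect_equal(ml_selection_auc(c(0.5, 0.5), c(100, 200)), 100)
  expect_equal(ml_weighted_auc(c(0.25, 0.75), c(100, 200)), 175)
  # one-hot weights make the two ML methods agree
  expect_equal(ml_weighted_auc(c(0, 1, 0), c(100, 200, 300)),
               ml_selection_auc(c(0, 1, 0), c(100, 200, 300)))
  # uniform probabilities reduce to the arithmetic mean
  expect_equal(ml_weighted_auc(rep(1 / 3, 3), c(100, 200, 300)), 200)
  expect_error(ml_weighted_auc(c(0.3, 0.3), c(100, 200)), "sum to 1")
})

test_that("OFV-based methods select and weight by the softmax weights", {
  aucs <- matrix(c(100, 200), 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(ofv_method_auc(c(0, 2), aucs, "weight"),
               0.7310585786 * 100 + 0.2689414214 * 200, tolerance = 1e-9)
  expect_equal(ofv_method_auc(c(0, 2), aucs, "select"), 100)
  expect_equal(ofv_method_auc(c(5, 5), aucs, "weight"), 150)
  # extreme OFV gap: both modes give the best model's AUC
  expect_equal(ofv_method_auc(c(0, 1000), aucs, "weight"), 100, tolerance = 1e-6)
  expect_equal(ofv_method_auc(c(0, 1000), aucs, "select"), 100)
})

test_that("perfect selection picks the generating model and rejects external labels", {
  aucs <- matrix(1:6, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(perfect_selection_auc(c("c", "a"), aucs), c(5, 2))
  expect_error(perfect_selection_auc(c("a", "zz"), aucs), "external")
})

test_that("error metrics match their formulas and an independent recomputation", {
  expect_equal(mpe(c(100, 100), c(100, 100)), 0)
  expect_equal(mpe(c(110, 90), c(100, 100)), 0)
  expect_equal(mpe(c(110, 110), c(100, 100)), 10)
  expect_equal(rrmse(c(100, 100), c(100, 100)), 0)
  expect_equal(rrmse(c(110, 90), c(100, 100)), 10)
  # single patient: rRMSE equals |MPE|
  expect_equal(rrmse(95, 100), abs(mpe(95, 100)))
  # against a one-line independent recomputation on random vectors
  set.seed(5)
  p <- runif(50, 50, 400); t <- runif(50, 50, 400)
  expect_equal(mpe(p, t), sum((p - t) / t) / 50 * 100, tolerance = 1e-12)
  expect_equal(rrmse(p, t), sqrt(sum(((p - t) / t)^2) / 50) * 100, tolerance = 1e-12)
  expect_error(mpe(c(1, 2), c(1, 0)), "positive")
  expect_error(rrmse(1, c(1, 2)), "mismatch")
})

test_that("averaged AUCs stay in the convex hull; selections return a vertex", {
  set.seed(8)
  n <- 40; M <- 5
  auc <- matrix(runif(n * M, 50, 400), n, M,
                dimnames = list(NULL, paste0("m", 1:M)))
  prob <- matrix(rexp(n * M), n, M)
  prob <- prob / rowSums(prob)
  ofv <- matrix(runif(n * M, 20, 60), n, M)
  w_avg <- ml_weighted_auc(prob, auc)
  o_avg <- ofv_method_auc(ofv, auc, "weight")
  lo <- apply(auc, 1, min); hi <- apply(auc, 1, max)
  expect_true(all(w_avg >= lo - 1e-9 & w_avg <= hi + 1e-9))
  expect_true(all(o_avg >= lo - 1e-9 & o_avg <= hi + 1e-9))
  sel <- ml_selection_auc(prob, auc)
  expect_true(all(vapply(seq_len(n), function(i) sel[i] %in% auc[i, ], logical(1))))
})

test_that("evaluate_methods assembles the full method table", {
  scen <- sampling_scenario("peak_trough", "single_dose")
  co <- generate_cohort(fx$models, fx$dem, 12, scen, seed = 23)
  fits <- map_fit_cohort(co)
  clf <- train_classifier(fx$features, "decision_tree", seed = 1)
  prob <- predict_probabilities(clf, build_features(co))
  ev <- evaluate_methods(co, fits, prob, internal = TRUE)
  expect_setequal(ev$table$method,
                  c("toy_fast", "toy_mid", "toy_slow", "perfect_selection",
                    "ml_selection", "ml_weighted", "nonweighted_average",
                    "ofv_selection", "ofv_weighted"))
  expect_true(all(ev$table$rrmse >= 0))
  expect_true(all(ev$table$n == 36))
  # external mode drops perfect selection
  ev_ext <- evaluate_methods(co, fits, prob, internal = FALSE)
  expect_false("perfect_selection" %in% ev_ext$table$method)
})

test_that("noiseless patients fit with their generating model give exact AUC", {
  scen <- sampling_scenario("every_hour", "single_dose")
  co <- generate_cohort(noiseless_models, fx$dem, 6, scen, seed = 29)
  # estimation priors keep the IIV but use an additive-only residual: with
  # proportional error the log-variance term of the OFV shifts the mode
  # away from eta = 0 even for exact data
  priors <- lapply(fx$models, function(m) {
    m$residual <- list(add = 1, prop = 0)
    m
  })
  fits <- map_fit_cohort(co, priors)
  perf <- perfect_selection_auc(co$label, fits$auc)
  expect_equal(perf, co$true_auc, tolerance = 1e-3, ignore_attr = TRUE)
  expect_lt(abs(mpe(perf, co$true_auc)), 0.05)
  expect_lt(rrmse(perf, co$true_auc), 0.05)
})

test_that("run_scenario produces the accuracy and TDM report structure", {
  report <- run_scenario(fx$models, fx$dem,
                         scenarios = c("trough", "every_hour"),
                         dosing = "single_dose",
                         n_train = 80, n_valid = 30,
                         params = list(nrounds = 40),
                         fit_map = TRUE, seed = 3)
  expect_s3_class(report, "tdm_report")
  expect_equal(nrow(report$accuracy), 2)
  expect_true(all(report$accuracy$accuracy >= 0 & report$accuracy$accuracy <= 1))
  tdm <- report$tdm
  expect_setequal(unique(tdm$scenario), c("trough", "every_hour"))
  expect_true(all(c("perfect_selection", "ml_weighted", "ofv_weighted") %in% tdm$method))
  expect_true(all(tdm$n == 90))
})
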