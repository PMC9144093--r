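# Separable two-model toy problem: clearances differ 10-fold, so every-hour
# ratio features identify the generating model almost perfectly.
separable_fixture <- local({
  m1 <- pk_model("sep_fast", CL = 9, V1 = 30, Q = 6, V2 = 50,
                 omega = c(CL = 0.02), residual = list(add = 0.2, prop = 0.05),
                 label = 1L)
  m2 <- pk_model("sep_slow", CL = 0.9, V1 = 30, Q = 6, V2 = 50,
                 omega = c(CL = 0.02), residual = list(add = 0.2, prop = 0.05),
                 label = 2L)
  scen <- sampling_scenario("every_hour", "single_dose")
  train <- generate_cohort(list(m1, m2), demographic_model(), 120, scen, seed = 21)
  test <- generate_cohort(list(m1, m2), demographic_model(), 60, scen, seed = 22)
  list(models = list(m1, m2), fm_train = build_features(train),
       fm_test = build_features(test))
})

test_that("tuning returns the best grid point with first-row tie-breaking", {
  fm <- separable_fixture$fm_train
  cfg1 <- classifier_config("decision_tree", grid = data.frame(cp = 0.01),
                            folds = 3, tune_fraction = 1, seed = 1)
  expect_equal(tune_hyperparameters(fm, cfg1)$best$cp, 0.01)
  # an inert duplicated grid point ties; the first listed must win
  cfg2 <- classifier_config("decision_tree", grid = data.frame(cp = c(0.01, 0.01)),
                            folds = 3, tune_fraction = 1, seed = 1)
  res <- tune_hyperparameters(fm, cfg2)
  expect_equal(res$results$cv_mlogloss[1], res$results$cv_mlogloss[2])
  expect_identical(res$best, as.list(res$results[1, "cp", drop = FALSE]))
})

test_that("tuned CV log-loss beats the uniform baseline on separable data", {
  fm <- separable_fixture$fm_train
  cfg <- classifier_config("gradient_boosting",
                           grid = data.frame(max_depth = 3, eta = 0.3, nrounds = 50),
                           folds = 3, tune_fraction = 1, seed = 2)
  res <- tune_hyperparameters(fm, cfg)
  expect_lt(min(res$results$cv_mlogloss), log(2))
})

test_that("classifiers separate well-separated models and are deterministic", {
  for (algo in c("gradient_boosting", "random_forest", "decision_tree")) {
    clf <- train_classifier(separable_fixture$fm_train, algo,
                            params = list(nrounds = 50), seed = 4)
    rep <- classification_metrics(separable_fixture$fm_test$label,
                                  predict_class(clf, separable_fixture$fm_test))
    expect_gt(rep$accuracy, 0.95)
    # probabilities: rows sum to 1, duplicated rows agree
    p <- predict_probabilities(clf, separable_fixture$fm_test)
    expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-6)
    dup <- predict_probabilities(clf, separable_fixture$fm_test$x[c(1, 1, 5), ])
    expect_equal(dup[1, ], dup[2, ])
    # refit with the same seed reproduces predictions exactly
    clf2 <- train_classifier(separable_fixture$fm_train, algo,
                             params = list(nrounds = 50), seed = 4)
    expect_equal(predict_probabilities(clf2, separable_fixture$fm_test), p)
  }
})

test_that("indistinguishable classes yield chance accuracy", {
  m <- separable_fixture$models[[1]]
  m_twin <- m; m_twin$name <- "sep_fast_twin"
  scen <- sampling_scenario("every_hour", "single_dose")
  train <- generate_cohort(list(m, m_twin), demographic_model(), 100, scen, seed = 31)
  test <- generate_cohort(list(m, m_twin), demographic_model(), 100, scen, seed = 32)
  clf <- train_classifier(build_features(train), "gradient_boosting",
                          list(nrounds = 40), seed = 1)
  rep <- classification_metrics(build_features(test)$label,
                                predict_class(clf, build_features(test)))
  expect_lt(abs(rep$accuracy - 0.5), 0.12)
})

test_that("prediction refuses mismatched feature columns", {
  clf <- train_classifier(separable_fixture$fm_train, "decision_tree", seed = 1)
  x <- separable_fixture$fm_test$x
  colnames(x)[1] <- "bogus"
  expect_error(predict_probabilities(clf, x), "manifest")
  expect_error(predict_probabilities(clf, x[, rev(colnames(x))]), "manifest")
})

test_that("classification metrics match the hand-counted confusion matrix", {
  truth <- factor(c("A", "A", "B", "B"))
  pred <- factor(c("A", "B", "B", "B"), levels = c("A", "B"))
  rep <- classification_metrics(truth, pred)
  expect_equal(rep$accuracy, 0.75)
  b <- rep$per_class[rep$per_class$class == "B", ]
  expect_equal(b$precision, 2 / 3)
  expect_equal(b$recall, 1)
  expect_equal(b$f1, 0.8)
  # perfect predictions
  perf <- classification_metrics(truth, truth)
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$per_class$f1, c(1, 1))
  # constant predictor on balanced classes scores 1/M
  const <- classification_metrics(factor(rep(c("A", "B"), 10)),
                                  factor(rep("A", 20), levels = c("A", "B")))
  expect_equal(const$accuracy, 0.5)
  # accuracy reconciles with the matrix trace
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
  expect_error(classification_metrics(truth, c("A", "B", "C", "A")), "unseen")
})

test_that("metrics agree with caret's independent confusion matrix", {
  skip_if_not_installed("caret")
  set.seed(77)
  truth <- factor(sample(c("a", "b", "c"), 200, replace = TRUE))
  pred <- factor(sample(c("a", "b", "c"), 200, replace = TRUE), levels = levels(truth))
  ours <- classification_metrics(truth, pred)
  cc <- caret::confusionMatrix(pred, truth)
  expect_equal(unname(ours$accuracy), unname(cc$overall["Accuracy"]))
  expect_equal(unname(ours$per_class$recall),
               unname(cc$byClass[, "Sensitivity"]))
  expect_equal(unname(ours$per_class$precision),
               unname(cc$byClass[, "Pos Pred Value"]))
})
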