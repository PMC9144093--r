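# Multiclass classifiers over the concentration-ratio features: decision
# tree (rpart), random forest (ranger) and gradient boosting (xgboost), with
# repeated stratified cross-validated grid search scored by multiclass
# log-loss.

#' Default hyperparameter grids
#'
#' Small, documented grids; override freely via [classifier_config()].
#' Gradient boosting: `max_depth` {3, 6, 9}, `eta` {0.1, 0.3}, `nrounds`
#' {100, 300}, `subsample` {0.8, 1}.  Random forest: `num.trees` {250, 500},
#' `mtry_rule` {`sqrt`, `third`} (square root of p or p/3 features per
#' split).  Decision tree: complexity penalty `cp` {0.01, 0.001}.
#'
#' @param algorithm One of `"gradient_boosting"`, `"random_forest"`,
#'   `"decision_tree"`.
#' @return A `data.frame`, one row per grid point.
#' @export
default_grid <- function(algorithm) {
  switch(algorithm,
    gradient_boosting = expand.grid(max_depth = c(3, 6, 9), eta = c(0.1, 0.3),
                                    nrounds = c(100, 300), subsample = c(0.8, 1),
                                    KEEP.OUT.ATTRS = FALSE),
    random_forest = expand.grid(num.trees = c(250, 500),
                                mtry_rule = c("sqrt", "third"),
                                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    decision_tree = data.frame(cp = c(0.01, 0.001)),
    stop("unknown algorithm: ", algorithm)
  )
}

#' Classifier training configuration
#'
#' @param algorithm `"decision_tree"`, `"random_forest"` or
#'   `"gradient_boosting"`.
#' @param grid Hyperparameter grid (`data.frame`, one row per candidate);
#'   defaults to [default_grid()].
#' @param folds Cross-validation folds (>= 2).
#' @param repeats Repetitions of the k-fold split.
#' @param tune_fraction Fraction of the data subsampled for tuning.
#' @param split Train fraction of the tuning subsample (the rest is held
#'   out from cross-validation).
#' @param seed Integer seed for subsampling and fold assignment.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(algorithm = c("gradient_boosting", "random_forest", "decision_tree"),
                              grid = NULL, folds = 10, repeats = 1,
                              tune_fraction = 0.1, split = 0.7, seed = 1) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- default_grid(algorithm)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1, folds >= 2, repeats >= 1,
            tune_fraction > 0, tune_fraction <= 1, split > 0, split < 1)
  structure(list(algorithm = algorithm, grid = grid, folds = as.integer(folds),
                 repeats = as.integer(repeats), tune_fraction = tune_fraction,
                 split = split, seed = as.integer(seed)),
            class = "classifier_config")
}

# Multiclass log-loss of a probability matrix against true factor labels.
mlogloss <- function(prob, truth) {
  i <- cbind(seq_along(truth), as.integer(truth))
  -mean(log(pmax(prob[i], 1e-15)))
}

# Stratified index sample: about `fraction` of each class.
stratified_sample <- function(label, fraction) {
  idx <- unlist(lapply(split(seq_along(label), label), function(ix) {
    k <- max(1L, round(length(ix) * fraction))
    sample(ix, k)
  }), use.names = FALSE)
  sort(idx)
}

# Stratified fold assignment (every class spread over all folds).
stratified_folds <- function(label, k) {
  fold <- integer(length(label))
  for (ix in split(seq_along(label), label)) {
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  if (any(vapply(split(label, fold), function(l) length(unique(l)), 1L) <
          length(levels(label)))) {
    stop("a class is absent from a fold; reduce folds or enlarge the sample")
  }
  fold
}

#' Tune hyperparameters by repeated stratified cross-validation
#'
#' Subsamples `tune_fraction` of the data (stratified), splits it into a
#' train/held-out pair (`split` / `1 - split`, stratified), and evaluates
#' every grid row by repeated stratified k-fold cross-validation on the
#' train part, scored by mean multiclass log-loss.  Ties are broken by grid
#' order (first listed wins).
#'
#' @param fm A [build_features()] result.
#' @param config A [classifier_config()].
#' @return List: `best` (grid row as a list), `results` (grid with a
#'   `cv_mlogloss` column), `holdout` (indices of the untouched 30% of the
#'   tuning subsample, relative to `fm`).
#' @export
tune_hyperparameters <- function(fm, config) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "classifier_config"))
  if (anyNA(fm$label)) stop("tuning requires labelled rows only")
  set.seed(config$seed)
  sub <- stratified_sample(fm$label, config$tune_fraction)
  x <- fm$x[sub, , drop = FALSE]
  y <- droplevels(fm$label[sub])
  tr <- stratified_sample(y, config$split)
  xt <- x[tr, , drop = FALSE]; yt <- droplevels(y[tr])
  scores <- numeric(nrow(config$grid))
  for (g in seq_len(nrow(config$grid))) {
    pars <- as.list(config$grid[g, , drop = FALSE])
    ll <- c()
    for (r in seq_len(config$repeats)) {
      set.seed(config$seed + 1000L * r + g)
      fold <- stratified_folds(yt, config$folds)
      for (k in seq_len(config$folds)) {
        fit <- fit_algorithm(config$algorithm, xt[fold != k, , drop = FALSE],
                             yt[fold != k], pars, seed = config$seed + k)
        p <- predict_algorithm(fit, xt[fold == k, , drop = FALSE])
        ll <- c(ll, mlogloss(p, yt[fold == k]))
      }
    }
    scores[g] <- mean(ll)
  }
  best <- which.min(scores) # ties: first grid row
  results <- config$grid
  results$cv_mlogloss <- scores
  list(best = as.list(config$grid[best, , drop = FALSE]),
       results = results,
       holdout = sub[setdiff(seq_along(y), tr)])
}

# Internal: dispatch to the underlying learner. `x` a numeric matrix, `y` a
# factor with >= 2 levels.
fit_algorithm <- function(algorithm, x, y, pars, seed = 1) {
  K <- length(levels(y))
  if (algorithm == "gradient_boosting") {
    set.seed(seed)
    dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
    fit <- xgboost::xgb.train(
      params = list(objective = "multi:softprob", eval_metric = "mlogloss",
                    num_class = K,
                    max_depth = as.integer(pars$max_depth %||% 6),
                    eta = pars$eta %||% 0.3,
                    subsample = pars$subsample %||% 1,
                    nthread = 1, seed = seed),
      data = dtrain, nrounds = as.integer(pars$nrounds %||% 100), verbose = 0)
    list(algorithm = algorithm, fit = fit)
  } else if (algorithm == "random_forest") {
    p <- ncol(x)
    mtry <- if (!is.null(pars$mtry)) as.integer(pars$mtry)
            else if (identical(pars$mtry_rule, "third")) max(1L, floor(p / 3))
            else max(1L, floor(sqrt(p)))
    df <- as.data.frame(x, check.names = FALSE)
    fit <- ranger::ranger(x = df, y = y, probability = TRUE,
                          num.trees = as.integer(pars$num.trees %||% 500),
                          mtry = mtry, seed = seed, num.threads = 1,
                          verbose = FALSE)
    list(algorithm = algorithm, fit = fit)
  } else if (algorithm == "decision_tree") {
    df <- as.data.frame(x)
    names(df) <- paste0("f", seq_len(ncol(x))) # rpart needs syntactic names
    df$.label <- y
    set.seed(seed)
    fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                        control = rpart::rpart.control(cp = pars$cp %||% 0.01,
                                                       xval = 0))
    list(algorithm = algorithm, fit = fit, classes = levels(y))
  } else stop("unknown algorithm: ", algorithm)
}

predict_algorithm <- function(fit, x) {
  if (fit$algorithm == "gradient_boosting") {
    p <- predict(fit$fit, xgboost::xgb.DMatrix(x))
    if (is.null(dim(p))) p <- matrix(p, nrow = nrow(x), byrow = TRUE)
    p
  } else if (fit$algorithm == "random_forest") {
    predict(fit$fit, data = as.data.frame(x, check.names = FALSE),
            num.threads = 1)$predictions
  } else {
    df <- as.data.frame(x)
    names(df) <- paste0("f", seq_len(ncol(x)))
    predict(fit$fit, newdata = df, type = "prob")
  }
}

#' Train a model-selection classifier
#'
#' Fits the chosen algorithm on the full labelled feature matrix and wraps
#' it with its feature-name manifest and class labels; prediction refuses
#' feature matrices whose columns do not match exactly (no silent
#' reordering).
#'
#' @param fm A [build_features()] result with complete labels.
#' @param algorithm See [classifier_config()].
#' @param params Hyperparameters (a list / one-row grid); defaults per
#'   algorithm: gradient boosting `max_depth` 6, `eta` 0.3, `nrounds` 100;
#'   random forest `num.trees` 500, `mtry` sqrt(p); tree `cp` 0.01.
#' @param seed Integer seed (training is deterministic given the seed).
#' @return Object of class `tdm_classifier`.
#' @export
train_classifier <- function(fm, algorithm = "gradient_boosting",
                             params = list(), seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (anyNA(fm$label)) stop("training labels contain NA")
  fit <- fit_algorithm(algorithm, fm$x, fm$label, params, seed = seed)
  structure(list(algorithm = algorithm, fit = fit,
                 classes = levels(fm$label), features = colnames(fm$x),
                 params = params, seed = seed),
            class = "tdm_classifier")
}

#' @export
print.tdm_classifier <- function(x, ...) {
  cat(sprintf("<tdm_classifier> %s, %d classes, %d features\n",
              x$algorithm, length(x$classes), length(x$features)))
  invisible(x)
}

#' Predict class-membership probabilities
#'
#' @param clf A [train_classifier()] result.
#' @param fm A `feature_matrix` (or bare numeric matrix with matching column
#'   names).
#' @return Matrix of probabilities (rows sum to 1), columns named by model.
#' @export
predict_probabilities <- function(clf, fm) {
  stopifnot(inherits(clf, "tdm_classifier"))
  x <- if (inherits(fm, "feature_matrix")) fm$x else fm
  if (!identical(colnames(x), clf$features)) {
    stop("feature columns do not match the classifier's training manifest")
  }
  p <- predict_algorithm(clf$fit, x)
  colnames(p) <- clf$classes
  p / rowSums(p)
}

#' Hard class predictions
#'
#' Argmax of [predict_probabilities()]; ties go to the lowest model index.
#'
#' @inheritParams predict_probabilities
#' @return Factor of predicted model names with the classifier's levels.
#' @export
predict_class <- function(clf, fm) {
  p <- predict_probabilities(clf, fm)
  factor(clf$classes[max.col(p, ties.method = "first")], levels = clf$classes)
}

#' Confusion matrix and derived classification metrics
#'
#' Accuracy plus one-vs-rest precision, recall and F1 per class, all derived
#' from the confusion matrix (`accuracy = trace / total`).
#'
#' @param truth,predicted Factors (or vectors) of equal length; every
#'   predicted value must be a known class of `truth`.
#' @return Object of class `classifier_report`: `confusion` (truth in rows),
#'   `accuracy`, `per_class` data.frame with `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  truth <- as.factor(truth)
  if (any(!as.character(predicted) %in% levels(truth))) {
    stop("predicted contains label(s) unseen in truth")
  }
  predicted <- factor(as.character(predicted), levels = levels(truth))
  cm <- table(truth = truth, predicted = predicted)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  structure(list(confusion = cm, accuracy = acc,
                 per_class = data.frame(class = levels(truth), precision = precision,
                                        recall = recall, f1 = f1,
                                        row.names = NULL)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> accuracy %.4f (n = %d)\n",
              x$accuracy, sum(x$confusion)))
  print(x$confusion)
  print(x$per_class, digits = 4)
  invisible(x)
}
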