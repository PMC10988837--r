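# Sample-size rule, stratified splitting, five classifier backends with a
# seeded random-search tuner, stratified 10-fold CV, and confusion-matrix
# evaluation with the ROA class positive.

MODEL_NAMES <- c("knn", "svm", "rf", "adaboost", "xgboost")

#' Minimal cohort size for a feature count
#'
#' Applies the sample-size rule used for planning: the training set must
#' hold at least `train_multiple` subjects per input feature, and the
#' cohort is split train:test = `train_test_ratio`:1 (train share taken as
#' `floor(n * ratio / (ratio + 1))`). Returns the smallest total n
#' satisfying both, i.e. `ceiling(train_multiple * n_features *
#' (ratio + 1) / ratio)`.
#'
#' @param n_features Number of model input features (>= 1).
#' @param train_multiple Training subjects required per feature.
#' @param train_test_ratio Train-to-test ratio.
#' @return Smallest admissible total cohort size (integer).
#' @examples
#' minimum_sample_size(4)  # 54
#' @export
minimum_sample_size <- function(n_features, train_multiple = 10,
                                train_test_ratio = 3) {
  if (!is.numeric(n_features) || n_features < 1) {
    stopf("n_features must be >= 1")
  }
  r <- train_test_ratio
  as.integer(ceiling(train_multiple * n_features * (r + 1) / r))
}

#' Stratified train/test split
#'
#' Assigns `round(fraction * class size)` subjects of each class (rounding
#' half away from zero) to the training set at random under `seed`; the
#' remainder form the test set.
#'
#' @param labels Binary class labels of the cohort, in cohort order.
#' @param fraction Training fraction (default 0.75). `fraction = 1` yields
#'   an empty test set with a warning.
#' @param seed Integer seed.
#' @return A `split_plan` list: integer vectors `train` and `test`
#'   (positions in `labels`), `fraction`, `seed`, and the per-class train
#'   counts `strata`.
#' @export
stratified_split <- function(labels, fraction = 0.75, seed = 1L) {
  f <- factor(labels)
  if (nlevels(f) != 2) stopf("labels must contain exactly 2 classes")
  if (any(table(f) < 2)) stopf("each class needs >= 2 subjects")
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0,1]")
  if (fraction == 1) warning("fraction = 1: test set is empty")
  train <- integer(0)
  strata <- integer(0)
  with_seed(seed, {
    for (lv in levels(f)) {
      idx <- which(f == lv)
      n_tr <- as.integer(round_half_away(fraction * length(idx)))
      train <- c(train, sort(sample(idx, n_tr)))
      strata[lv] <- n_tr
    }
  })
  train <- sort(train)
  structure(list(train = train, test = setdiff(seq_along(f), train),
                 fraction = fraction, seed = seed, strata = strata),
            class = "split_plan")
}

# Stratified k-fold assignment; returns list of test-index vectors. Fold
# sizes differ by at most one and class ratios are preserved within one
# subject per class. Consumes RNG (callers wrap in with_seed).
make_folds <- function(y, k = 10L) {
  folds <- vector("list", k)
  offset <- 0L
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    # continue fold assignment across classes so total fold sizes differ by
    # at most one while each class stays balanced within one subject
    grp <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
    for (fold in seq_len(k)) {
      folds[[fold]] <- c(folds[[fold]], idx[grp == fold])
    }
  }
  folds
}

# numeric model matrix: gender becomes an indicator, everything else must
# already be numeric
encode_features <- function(df) {
  df <- as.data.frame(df)
  if ("gender" %in% colnames(df)) {
    df$gender <- as.numeric(df$gender %in% c("male", "M", 1))
  }
  for (nm in colnames(df)) {
    if (!is.numeric(df[[nm]])) {
      stopf("feature '%s' is not numeric and has no encoding", nm)
    }
  }
  as.matrix(df)
}

default_hyperparameters <- function(model, p) {
  switch(model,
    knn = list(k = 5L),
    svm = list(kernel = "radial", cost = 1, gamma = 1 / max(p, 1)),
    rf = list(ntree = 300L, mtry = max(1L, floor(sqrt(p))), nodesize = 1L),
    adaboost = list(n_rounds = 100L, learning_rate = 0.5, max_depth = 1L),
    xgboost = list(nrounds = 150L, max_depth = 3L, eta = 0.1, subsample = 1),
    stopf("unknown model '%s'; supported: %s", model,
          paste(MODEL_NAMES, collapse = ", "))
  )
}

# one random draw from the model's declared search space (consumes RNG)
sample_hyperparameters <- function(model, p) {
  switch(model,
    knn = list(k = sample(seq(1L, 15L, by = 2L), 1)),
    svm = list(kernel = sample(c("radial", "linear"), 1),
               cost = 10^stats::runif(1, -2, 2),
               gamma = 10^stats::runif(1, -3, 1)),
    rf = list(ntree = sample(c(100L, 200L, 300L, 400L, 500L), 1),
              mtry = sample(seq_len(max(1L, p)), 1),
              nodesize = sample(c(1L, 2L, 3L, 5L), 1)),
    adaboost = list(n_rounds = sample(c(50L, 100L, 150L, 200L), 1),
                    learning_rate = stats::runif(1, 0.1, 1),
                    max_depth = sample(1:2, 1)),
    xgboost = list(nrounds = sample(c(50L, 100L, 150L, 200L, 300L), 1),
                   max_depth = sample(2:6, 1),
                   eta = 10^stats::runif(1, -2, -0.3),
                   subsample = stats::runif(1, 0.6, 1)),
    stopf("unknown model '%s'; supported: %s", model,
          paste(MODEL_NAMES, collapse = ", "))
  )
}

# Discrete AdaBoost (SAMME) over shallow rpart trees.
fit_adaboost <- function(X, y, n_rounds, learning_rate, max_depth) {
  df <- data.frame(X, .y = y)
  n <- nrow(df)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    tree <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                         control = rpart::rpart.control(
                           maxdepth = max_depth, cp = 0, minsplit = 2,
                           xval = 0))
    pred <- predict(tree, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- learning_rate * log((1 - err) / err)
    learners[[length(learners) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err < 1e-9) break
  }
  list(learners = learners, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(fit, X) {
  df <- as.data.frame(X)
  if (!length(fit$learners)) {
    return(factor(rep(fit$levels[1], nrow(df)), levels = fit$levels))
  }
  score <- matrix(0, nrow(df), length(fit$levels))
  for (m in seq_along(fit$learners)) {
    pred <- predict(fit$learners[[m]], df, type = "class")
    score[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      score[cbind(seq_len(nrow(df)), as.integer(pred))] + fit$alphas[m]
  }
  factor(fit$levels[max.col(score, ties.method = "first")],
         levels = fit$levels)
}

# Fit one backend. X: numeric matrix; y: 2-level factor. KNN and SVM see
# train-standardised features; tree ensembles consume them raw.
fit_model <- function(model, X, y, hp) {
  if (!model %in% MODEL_NAMES) {
    stopf("unknown model '%s'; supported: %s", model,
          paste(MODEL_NAMES, collapse = ", "))
  }
  scaler <- NULL
  if (model %in% c("knn", "svm")) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    scaler <- list(center = ctr, scale = scl)
    X <- scale(X, ctr, scl)
  }
  fit <- switch(model,
    knn = list(X = X, y = y, k = hp$k),
    svm = e1071::svm(X, y, kernel = hp$kernel, cost = hp$cost,
                     gamma = hp$gamma, scale = FALSE),
    rf = randomForest::randomForest(X, y, ntree = hp$ntree, mtry = hp$mtry,
                                    nodesize = hp$nodesize),
    adaboost = fit_adaboost(X, y, hp$n_rounds, hp$learning_rate,
                            hp$max_depth),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                    eta = hp$eta, subsample = hp$subsample, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L),
      nrounds = hp$nrounds, verbose = 0)
  )
  structure(list(model = model, fit = fit, hp = hp, scaler = scaler,
                 levels = levels(y), features = colnames(X)),
            class = "insole_model")
}

predict_model <- function(object, X) {
  if (!is.null(object$features) && !is.null(colnames(X))) {
    if (!identical(colnames(X), object$features)) {
      if (!all(object$features %in% colnames(X))) {
        stopf("test features do not match training features")
      }
      X <- X[, object$features, drop = FALSE]
    }
  }
  if (!is.null(object$scaler)) {
    X <- scale(X, object$scaler$center, object$scaler$scale)
  }
  lv <- object$levels
  switch(object$model,
    knn = class::knn(object$fit$X, X, object$fit$y, k = object$fit$k),
    svm = predict(object$fit, X),
    rf = predict(object$fit, X),
    adaboost = predict_adaboost(object$fit, X),
    xgboost = factor(
      lv[(predict(object$fit, xgboost::xgb.DMatrix(X)) > 0.5) + 1L],
      levels = lv)
  )
}

#' Train one classifier with seeded hyperparameter tuning
#'
#' Seeded random search over the backend's declared hyperparameter space:
#' each of `budget` trials draws a candidate configuration and scores it by
#' mean stratified 10-fold CV accuracy on the training set; the best trial
#' (ties to the earliest) is refit on the full training set. With
#' `budget = 0` the documented per-model defaults are used directly.
#'
#' @param model One of `"knn"`, `"svm"`, `"rf"`, `"adaboost"`, `"xgboost"`.
#' @param features Training feature table (or numeric matrix).
#' @param labels Training labels (2 classes; >= `cv_folds` subjects per
#'   class recommended for stratified CV).
#' @param budget Number of random-search trials (default 50).
#' @param cv_folds CV folds used for scoring.
#' @param seed Integer seed fixing folds, trial draws and model randomness.
#' @return A `tuned_model` list: the fitted `model` object,
#'   `hyperparameters`, `cv_accuracy`, `cv_f1`, `trials` tibble, `seed`.
#' @export
train_and_tune <- function(model, features, labels, budget = 50L,
                           cv_folds = 10L, seed = 1L) {
  if (!model %in% MODEL_NAMES) {
    stopf("unknown model '%s'; supported: %s", model,
          paste(MODEL_NAMES, collapse = ", "))
  }
  X <- encode_features(features)
  y <- factor(labels)
  p <- ncol(X)
  folds <- with_seed(derive_seed(seed, 77), make_folds(y, cv_folds))
  score_hp <- function(hp, trial) {
    accs <- f1s <- numeric(length(folds))
    for (fold in seq_along(folds)) {
      test_idx <- folds[[fold]]
      ytr <- droplevels(y[-test_idx])
      if (nlevels(ytr) < 2) stopf("training fold with a single class")
      fit <- with_seed(derive_seed(seed, trial, fold),
        fit_model(model, X[-test_idx, , drop = FALSE], y[-test_idx], hp))
      pred <- predict_model(fit, X[test_idx, , drop = FALSE])
      cm <- confusion_counts(pred, y[test_idx])
      accs[fold] <- (cm["TP"] + cm["TN"]) / sum(cm)
      f1s[fold] <- f1_from_counts(cm)
    }
    c(accuracy = mean(accs), f1 = mean(f1s))
  }
  trials <- list()
  if (budget > 0) {
    hps <- with_seed(derive_seed(seed, 55), {
      lapply(seq_len(budget), function(i) sample_hyperparameters(model, p))
    })
  } else {
    hps <- list(default_hyperparameters(model, p))
  }
  scores <- t(vapply(seq_along(hps),
                     function(i) score_hp(hps[[i]], i), numeric(2)))
  best <- which.max(scores[, "accuracy"])
  final <- with_seed(derive_seed(seed, 999),
    fit_model(model, X, y, hps[[best]]))
  structure(list(
    model = final,
    model_name = model,
    hyperparameters = hps[[best]],
    cv_accuracy = scores[best, "accuracy"],
    cv_f1 = scores[best, "f1"],
    trials = tibble::tibble(
      trial = seq_along(hps),
      accuracy = scores[, "accuracy"],
      f1 = scores[, "f1"]
    ),
    seed = seed
  ), class = "tuned_model")
}

# confusion counts with the positive class = ROA = the level "1" (or the
# second factor level)
positive_level <- function(lv) if ("1" %in% lv) "1" else lv[length(lv)]

confusion_counts <- function(pred, truth) {
  lv <- levels(factor(truth))
  pos <- positive_level(lv)
  pred <- factor(pred, levels = lv)
  c(TP = sum(pred == pos & truth == pos),
    FP = sum(pred == pos & truth != pos),
    FN = sum(pred != pos & truth == pos),
    TN = sum(pred != pos & truth != pos))
}

f1_from_counts <- function(cm) {
  denom <- 2 * cm[["TP"]] + cm[["FP"]] + cm[["FN"]]
  if (denom == 0) return(0)
  2 * cm[["TP"]] / denom
}

#' Evaluate a fitted model on a test set
#'
#' Builds the test confusion matrix with the ROA class positive and derives
#' accuracy `(TP + TN) / n` and the positive-class F1 score
#' `2 TP / (2 TP + FP + FN)`.
#'
#' @param tuned A [train_and_tune()] result (or an internal fitted model).
#' @param features Test feature table.
#' @param labels Test labels (non-empty, both classes present).
#' @return A `model_report` list: `model`, `hyperparameters`,
#'   `cv_accuracy`, `cv_f1`, `confusion` (named TP/FP/FN/TN),
#'   `test_accuracy`, `test_f1`.
#' @export
evaluate_model <- function(tuned, features, labels) {
  if (!length(labels)) stopf("test set is empty")
  fit <- if (inherits(tuned, "tuned_model")) tuned$model else tuned
  X <- encode_features(features)
  pred <- predict_model(fit, X)
  cm <- confusion_counts(pred, factor(labels, levels = fit$levels))
  structure(list(
    model = fit$model,
    hyperparameters = if (inherits(tuned, "tuned_model")) {
      tuned$hyperparameters
    } else {
      fit$hp
    },
    cv_accuracy = if (inherits(tuned, "tuned_model")) tuned$cv_accuracy else NA_real_,
    cv_f1 = if (inherits(tuned, "tuned_model")) tuned$cv_f1 else NA_real_,
    confusion = cm,
    test_accuracy = (cm[["TP"]] + cm[["TN"]]) / sum(cm),
    test_f1 = f1_from_counts(cm)
  ), class = "model_report")
}
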