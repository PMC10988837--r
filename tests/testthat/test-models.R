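# Sample-size rule, stratified splitting, classifier backends, tuning and
# confusion-matrix metrics.

test_that("minimum sample size matches a brute-force search over the rule", {
  brute <- function(f, mult = 10, ratio = 3) {
    n <- 1L
    repeat {
      if (floor(n * ratio / (ratio + 1)) >= mult * f) return(n)
      n <- n + 1L
    }
  }
  for (f in c(1:8, 12, 21)) {
    expect_equal(minimum_sample_size(f), brute(f), info = paste("f =", f))
  }
  expect_equal(minimum_sample_size(4), 54L)
  expect_equal(minimum_sample_size(1), 14L)
  expect_error(minimum_sample_size(0))
})

test_that("stratified split reproduces the published cohort partition", {
  labels <- rep(c(0, 1), c(49, 43))
  for (seed in c(1, 7, 123)) {
    sp <- stratified_split(labels, 0.75, seed = seed)
    expect_length(sp$train, 69)
    expect_length(sp$test, 23)
    expect_equal(sum(labels[sp$train] == 0), 37)
    expect_equal(sum(labels[sp$train] == 1), 32)
    expect_equal(sum(labels[sp$test] == 0), 12)
    expect_equal(sum(labels[sp$test] == 1), 11)
    expect_length(intersect(sp$train, sp$test), 0)
  }
  expect_identical(stratified_split(labels, seed = 4),
                   stratified_split(labels, seed = 4))
  expect_warning(sp1 <- stratified_split(labels, 1, seed = 1), "empty")
  expect_length(sp1$test, 0)
  expect_error(stratified_split(rep(1, 10)), "2 classes")
})

test_that("stratified folds are balanced in size and class ratio", {
  y <- factor(rep(c(0, 1), c(37, 32)))
  folds <- insolegait:::with_seed(1, insolegait:::make_folds(y, 10))
  sizes <- lengths(folds)
  expect_equal(sum(sizes), 69)
  expect_lte(max(sizes) - min(sizes), 1)
  pos <- vapply(folds, function(idx) sum(y[idx] == "1"), numeric(1))
  expect_lte(max(pos) - min(pos), 1)
})

test_that("confusion-matrix identities hold across random matrices", {
  set.seed(99)
  for (i in 1:50) {
    cm <- c(TP = sample(0:20, 1), FP = sample(0:20, 1),
            FN = sample(0:20, 1), TN = sample(0:20, 1))
    if (sum(cm) == 0) next
    truth <- factor(c(rep(1, cm["TP"]), rep(0, cm["FP"]),
                      rep(1, cm["FN"]), rep(0, cm["TN"])), levels = c(0, 1))
    pred <- factor(c(rep(1, cm["TP"]), rep(1, cm["FP"]),
                     rep(0, cm["FN"]), rep(0, cm["TN"])), levels = c(0, 1))
    got <- insolegait:::confusion_counts(pred, truth)
    expect_equal(got, cm)
    acc <- (cm[["TP"]] + cm[["TN"]]) / sum(cm)
    expect_equal((got[["TP"]] + got[["TN"]]) / sum(got), acc)
    f1 <- insolegait:::f1_from_counts(got)
    denom <- 2 * cm[["TP"]] + cm[["FP"]] + cm[["FN"]]
    expect_equal(f1, if (denom == 0) 0 else 2 * cm[["TP"]] / denom)
  }
})

test_that("evaluation reports perfect and all-positive predictors correctly", {
  X_test <- matrix(seq_len(46), ncol = 2)
  colnames(X_test) <- c("a", "b")
  y_test <- rep(c(0, 1), c(12, 11))
  # 1-NN trained on the test points themselves predicts perfectly
  fit <- insolegait:::fit_model("knn", X_test, factor(y_test), list(k = 1))
  rep_perfect <- evaluate_model(fit, X_test, y_test)
  expect_equal(rep_perfect$test_accuracy, 1)
  expect_equal(rep_perfect$test_f1, 1)
  # 1-NN trained on a single positive subject predicts all-positive
  fit_pos <- insolegait:::fit_model(
    "knn", matrix(c(0, 0), 1, 2, dimnames = list(NULL, c("a", "b"))),
    factor("1", levels = c("0", "1")), list(k = 1))
  rep_pos <- evaluate_model(fit_pos, X_test, y_test)
  expect_equal(rep_pos$test_accuracy, 11 / 23)
  expect_equal(rep_pos$test_f1, 22 / 34)
  expect_equal(unname(rep_pos$confusion),
               c(11, 12, 0, 0))
  expect_error(evaluate_model(fit, X_test, numeric(0)), "empty")
})

test_that("all five backends learn a linearly separable problem", {
  n <- 60
  labels <- factor(rep(0:1, each = n / 2))
  X <- withr::with_seed(11, cbind(
    x1 = as.numeric(labels == "1") * 4 + rnorm(n, 0, 0.4),
    x2 = rnorm(n)
  ))
  df <- tibble::as_tibble(as.data.frame(X))
  for (m in c("knn", "svm", "rf", "adaboost", "xgboost")) {
    tuned <- train_and_tune(m, df, labels, budget = 0L, seed = 3)
    expect_gte(tuned$cv_accuracy, 0.95)
  }
  expect_error(train_and_tune("mlp", df, labels), "knn, svm, rf")
})

test_that("tuning is seeded, deterministic and budget-0 uses defaults", {
  n <- 40
  labels <- factor(rep(0:1, each = n / 2))
  df <- withr::with_seed(12, tibble::tibble(
    x1 = as.numeric(labels == "1") * 2 + rnorm(n),
    x2 = rnorm(n)
  ))
  t1 <- train_and_tune("svm", df, labels, budget = 4L, seed = 7)
  t2 <- train_and_tune("svm", df, labels, budget = 4L, seed = 7)
  expect_identical(t1$hyperparameters, t2$hyperparameters)
  expect_equal(nrow(t1$trials), 4)
  t0 <- train_and_tune("rf", df, labels, budget = 0L, seed = 7)
  expect_equal(t0$hyperparameters,
               insolegait:::default_hyperparameters("rf", 2))
})

test_that("null features yield chance-level held-out accuracy", {
  n <- 92
  labels <- rep(0:1, c(49, 43))
  df <- withr::with_seed(13,
    tibble::as_tibble(as.data.frame(matrix(rnorm(n * 6), n))))
  sp <- stratified_split(labels, 0.75, seed = 2)
  tuned <- train_and_tune("rf", df[sp$train, ], labels[sp$train],
                          budget = 0L, seed = 2)
  rep_null <- evaluate_model(tuned, df[sp$test, ], labels[sp$test])
  # majority rate 12/23 plus three binomial SDs
  expect_lte(rep_null$test_accuracy, 12 / 23 + 3 * sqrt(0.52 * 0.48 / 23))
})
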