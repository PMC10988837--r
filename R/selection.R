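# Filter-then-wrapper feature selection: Shapiro-Wilk-routed two-sample
# tests at alpha = 0.05 over all 215 candidates (210 plantar + 5
# physiological), then a seeded forward wrapper over the p-value ordering
# scored by cross-validated classifier accuracy.

#' Normality-routed two-sample test for one feature
#'
#' Routes by Shapiro-Wilk normality within each group: if both groups look
#' normal (Shapiro-Wilk p >= 0.05 in each) an independent two-sample t-test
#' (pooled variance) is used, otherwise a Mann-Whitney U test with tie
#' correction. A feature constant in both groups is flagged degenerate and
#' never kept. No multiple-testing correction is applied; features are kept
#' at raw p < alpha.
#'
#' @param values Numeric vector of feature values.
#' @param labels Binary group labels (coerced to factor; both groups need
#'   >= 3 observations).
#' @param alpha Significance threshold (default 0.05).
#' @return List: `test` (`"t-test"`, `"mann-whitney"` or `"degenerate"`),
#'   `statistic`, `p_value`, `shapiro_p` (length 2), `kept`.
#' @export
route_and_test <- function(values, labels, alpha = 0.05) {
  f <- factor(labels)
  if (nlevels(f) != 2) stopf("labels must have exactly 2 levels")
  g1 <- values[f == levels(f)[1]]
  g2 <- values[f == levels(f)[2]]
  if (length(g1) < 3 || length(g2) < 3) {
    stopf("both groups need >= 3 observations")
  }
  if (stats::sd(values) == 0) {
    return(list(test = "degenerate", statistic = NA_real_, p_value = NA_real_,
                shapiro_p = c(NA_real_, NA_real_), kept = FALSE))
  }
  shp <- vapply(list(g1, g2), function(g) {
    tryCatch(stats::shapiro.test(g)$p.value, error = function(e) 0)
  }, numeric(1))
  if (all(shp >= 0.05)) {
    ht <- stats::t.test(g1, g2, var.equal = TRUE)
    test <- "t-test"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(g1, g2, exact = FALSE, correct = TRUE)
    )
    test <- "mann-whitney"
  }
  list(test = test, statistic = unname(ht$statistic),
       p_value = ht$p.value, shapiro_p = shp,
       kept = is.finite(ht$p.value) && ht$p.value < alpha)
}

#' Univariate filter over the whole feature table
#'
#' Applies [route_and_test()] to every plantar and physiological feature
#' column. Gender, being categorical, is tested with a 2 x 2 contingency
#' test instead (Pearson chi-square, or Fisher's exact test when any
#' expected count is below 5).
#'
#' @param features Feature table (one row per subject), e.g. from
#'   [cohort_feature_table()].
#' @param labels Binary labels; defaults to the table's `label` column.
#' @param alpha Significance threshold.
#' @return A `filter_result` tibble sorted by ascending p-value: `feature`,
#'   `test`, `statistic`, `p_value`, `shapiro_p1`, `shapiro_p2`, `kept`,
#'   with `alpha` as an attribute.
#' @export
filter_features <- function(features, labels = features$label, alpha = 0.05) {
  f <- factor(labels)
  if (nlevels(f) != 2) stopf("labels must contain both classes")
  if (min(table(f)) < 2) stopf("each class needs >= 2 subjects")
  candidates <- intersect(c(feature_registry(), physio_feature_names()),
                          colnames(features))
  rows <- lapply(candidates, function(nm) {
    v <- features[[nm]]
    if (nm == "gender" || !is.numeric(v)) {
      tab <- table(factor(v), f)
      res <- if (nrow(tab) < 2) {
        list(test = "degenerate", statistic = NA_real_, p_value = NA_real_,
             shapiro_p = c(NA_real_, NA_real_), kept = FALSE)
      } else {
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        ht <- if (any(expected < 5)) {
          stats::fisher.test(tab)
        } else {
          stats::chisq.test(tab, correct = FALSE)
        }
        list(test = if (any(expected < 5)) "fisher" else "chi-square",
             statistic = unname(ht$statistic %||% NA_real_),
             p_value = ht$p.value, shapiro_p = c(NA_real_, NA_real_),
             kept = ht$p.value < alpha)
      }
      res
    } else {
      route_and_test(v, f, alpha)
    }
  })
  out <- tibble::tibble(
    feature = candidates,
    test = vapply(rows, `[[`, character(1), "test"),
    statistic = vapply(rows, `[[`, numeric(1), "statistic"),
    p_value = vapply(rows, `[[`, numeric(1), "p_value"),
    shapiro_p1 = vapply(rows, function(r) r$shapiro_p[1], numeric(1)),
    shapiro_p2 = vapply(rows, function(r) r$shapiro_p[2], numeric(1)),
    kept = vapply(rows, `[[`, logical(1), "kept")
  )
  out <- out[order(out$p_value), ]
  attr(out, "alpha") <- alpha
  class(out) <- c("filter_result", class(out))
  out
}

#' Forward wrapper search over the filter ordering
#'
#' Sequential forward evaluation over prefixes of the filter's ascending
#' p-value ordering: for each k in 1..`k_max` the classifier is trained on
#' the first k kept features and scored by seeded stratified 10-fold
#' cross-validated accuracy (averaged over `cv_repeats` repetitions to
#' stabilise the selection); the chosen k maximises mean CV accuracy, with
#' ties broken towards the smallest k.
#'
#' @param filter_result A [filter_features()] result (or a character vector
#'   of ordered feature names).
#' @param features Feature table.
#' @param labels Binary labels; defaults to the table's `label` column.
#' @param model Classifier backend used for scoring (see
#'   [train_and_tune()]); default `"rf"`.
#' @param k_max Largest prefix evaluated; defaults to all kept features,
#'   capped at 15.
#' @param cv_folds,cv_repeats Cross-validation folds and repetitions.
#' @param seed Integer seed fixing folds and model randomness.
#' @return A `wrapper_trace` list: `trace` tibble (`k`, `feature`,
#'   `cv_accuracy`, `cv_accuracy_sd`), `chosen_k`, `chosen_features`,
#'   `model`, `seed`.
#' @export
wrapper_select <- function(filter_result, features, labels = features$label,
                           model = "rf", k_max = NULL, cv_folds = 10L,
                           cv_repeats = 3L, seed = 1L) {
  ordered <- if (is.character(filter_result)) {
    filter_result
  } else {
    filter_result$feature[filter_result$kept]
  }
  if (!length(ordered)) stopf("no kept features to search over")
  if (is.null(k_max)) k_max <- min(length(ordered), 15L)
  if (k_max > length(ordered)) {
    stopf("k_max (%d) exceeds number of kept features (%d)",
          k_max, length(ordered))
  }
  y <- factor(labels)
  X <- encode_features(features[, ordered[seq_len(k_max)], drop = FALSE])
  # canonical subject ordering (by label, then feature values) makes the
  # fold assignment -- and hence the chosen subset -- invariant to how the
  # cohort rows happen to be ordered
  canon <- do.call(order, c(list(as.integer(y)),
                            unname(as.list(as.data.frame(X)))))
  X <- X[canon, , drop = FALSE]
  y <- y[canon]
  folds <- with_seed(derive_seed(seed, 101), {
    lapply(seq_len(cv_repeats), function(r) make_folds(y, cv_folds))
  })
  acc <- matrix(NA_real_, nrow = k_max, ncol = cv_repeats * cv_folds)
  for (k in seq_len(k_max)) {
    Xk <- X[, seq_len(k), drop = FALSE]
    col <- 0L
    for (r in seq_len(cv_repeats)) {
      for (fold in seq_len(cv_folds)) {
        col <- col + 1L
        test_idx <- folds[[r]][[fold]]
        ytr <- y[-test_idx]
        if (nlevels(droplevels(ytr)) < 2) {
          stopf("training fold with a single class; re-stratify")
        }
        fit <- with_seed(derive_seed(seed, k, r, fold),
          fit_model(model, Xk[-test_idx, , drop = FALSE], ytr,
                    default_hyperparameters(model, ncol(Xk))))
        pred <- predict_model(fit, Xk[test_idx, , drop = FALSE])
        acc[k, col] <- mean(pred == y[test_idx])
      }
    }
  }
  mean_acc <- rowMeans(acc)
  chosen_k <- which.max(mean_acc)  # which.max returns the first (smallest) max
  out <- list(
    trace = tibble::tibble(
      k = seq_len(k_max),
      feature = ordered[seq_len(k_max)],
      cv_accuracy = mean_acc,
      cv_accuracy_sd = apply(acc, 1, stats::sd)
    ),
    chosen_k = chosen_k,
    chosen_features = ordered[seq_len(chosen_k)],
    model = model,
    seed = seed
  )
  class(out) <- "wrapper_trace"
  out
}
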