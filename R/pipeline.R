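# End-to-end driver: simulate (or ingest) -> segment -> extract -> filter
# -> wrapper -> train and evaluate the five classifiers, with all stage
# artifacts written to a run directory and a config snapshot embedded in
# the summary report.

#' Pipeline configuration
#'
#' Groups every stage default behind one validated object. Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param cohort List: `n_non_roa`, `n_roa`.
#' @param sim A [gait_sim_config()].
#' @param preprocessing List: `contact_threshold`, `min_stance_s`,
#'   `max_stance_s`, `n_discard_per_end`, `n_required`, `peak_prominence`,
#'   `valley_depth`.
#' @param selection List: `alpha`, `model`, `k_max` (NULL = all kept,
#'   capped at 15), `cv_folds`, `cv_repeats`.
#' @param modeling List: `train_fraction`, `models`, `budget`, `cv_folds`.
#' @param seed Global seed; every stage derives its stream from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = list(n_non_roa = 49, n_roa = 43),
                            sim = gait_sim_config(),
                            preprocessing = list(),
                            selection = list(),
                            modeling = list(),
                            seed = 1L) {
  fill <- function(given, defaults, what) {
    extra <- setdiff(names(given), names(defaults))
    if (length(extra)) {
      stopf("unknown %s config key(s): %s", what,
            paste(extra, collapse = ", "))
    }
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    cohort = fill(cohort, list(n_non_roa = 49, n_roa = 43), "cohort"),
    sim = sim,
    preprocessing = fill(preprocessing, list(
      contact_threshold = 0.05, min_stance_s = 0.3, max_stance_s = 2.0,
      n_discard_per_end = 2L, n_required = 60L,
      peak_prominence = 0.3, valley_depth = 0.9), "preprocessing"),
    selection = fill(selection, list(
      alpha = 0.05, model = "rf", k_max = NULL,
      cv_folds = 10L, cv_repeats = 3L), "selection"),
    modeling = fill(modeling, list(
      train_fraction = 0.75, models = MODEL_NAMES, budget = 20L,
      cv_folds = 10L), "modeling"),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg$sim)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Simulates a labelled cohort (or takes one supplied through `cohort`),
#' preprocesses every recording into 60 valid cycles per foot, extracts the
#' 210-feature table, filters features at `alpha`, runs the forward wrapper
#' search, splits the cohort stratified by label, trains the requested
#' classifier backends on the chosen feature subset and evaluates them on
#' the held-out test set. Fully reproducible from `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built cohort (list of `profile` +
#'   `recording`); when `NULL` one is simulated from the config.
#' @param out_dir Optional directory; when given, stage artifacts
#'   (`features.csv`, `filter.csv`, `wrapper_trace.csv`, `report.json`)
#'   are written there.
#' @return A `pipeline_result` list: `features`, `filter`, `wrapper`,
#'   `split`, `reports` (per model), and `summary` (kept features, chosen
#'   subset, split sizes, per-model train/test metrics, config snapshot).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stopf("config must be a pipeline_config()")
  }
  seed <- config$seed
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$cohort$n_non_roa, config$cohort$n_roa,
                              config$sim, seed = derive_seed(seed, 1))
  }
  pp <- config$preprocessing
  features <- cohort_feature_table(
    cohort, n_required = pp$n_required,
    contact_threshold = pp$contact_threshold,
    min_stance_s = pp$min_stance_s, max_stance_s = pp$max_stance_s,
    n_discard_per_end = pp$n_discard_per_end,
    peak_prominence = pp$peak_prominence, valley_depth = pp$valley_depth
  )
  sel <- config$selection
  filt <- filter_features(features, alpha = sel$alpha)
  wrap <- wrapper_select(filt, features, model = sel$model,
                         k_max = sel$k_max, cv_folds = sel$cv_folds,
                         cv_repeats = sel$cv_repeats,
                         seed = derive_seed(seed, 2))
  mdl <- config$modeling
  split <- stratified_split(features$label, mdl$train_fraction,
                            seed = derive_seed(seed, 3))
  sub <- features[, wrap$chosen_features, drop = FALSE]
  reports <- lapply(mdl$models, function(m) {
    tuned <- train_and_tune(m, sub[split$train, , drop = FALSE],
                            features$label[split$train],
                            budget = mdl$budget, cv_folds = mdl$cv_folds,
                            seed = derive_seed(seed, 4, match(m, MODEL_NAMES)))
    evaluate_model(tuned, sub[split$test, , drop = FALSE],
                   features$label[split$test])
  })
  names(reports) <- mdl$models
  summary <- list(
    n_subjects = nrow(features),
    n_train = length(split$train),
    n_test = length(split$test),
    train_by_class = as.list(split$strata),
    kept_features = filt$feature[filt$kept],
    chosen_features = wrap$chosen_features,
    chosen_k = wrap$chosen_k,
    models = lapply(reports, function(r) {
      list(cv_accuracy = r$cv_accuracy, cv_f1 = r$cv_f1,
           test_accuracy = r$test_accuracy, test_f1 = r$test_f1,
           confusion = as.list(r$confusion),
           hyperparameters = r$hyperparameters)
    }),
    config = config_snapshot(config)
  )
  out <- list(features = features, filter = filt, wrapper = wrap,
              split = split, reports = reports, summary = summary)
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features, file.path(out_dir, "features.csv"))
    utils::write.csv(as.data.frame(filt), file.path(out_dir, "filter.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(wrap$trace),
                     file.path(out_dir, "wrapper_trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

# plain-list snapshot of the config (JSON-serialisable)
config_snapshot <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      lapply(unclass(x), strip)
    } else if (is.null(x)) {
      NULL
    } else if (!is.null(names(x)) && length(x) > 1) {
      as.list(x)
    } else {
      x
    }
  }
  strip(config)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("insole gait pipeline result\n")
  cat(sprintf("  subjects: %d (train %d / test %d)\n",
              s$n_subjects, s$n_train, s$n_test))
  cat(sprintf("  features kept by filter: %d\n", length(s$kept_features)))
  cat(sprintf("  wrapper-chosen subset (k = %d): %s\n", s$chosen_k,
              paste(s$chosen_features, collapse = ", ")))
  for (m in names(s$models)) {
    r <- s$models[[m]]
    cat(sprintf("  %-8s cv acc %.3f | test acc %.3f | test F1 %.3f\n",
                m, r$cv_accuracy, r$test_accuracy, r$test_f1))
  }
  invisible(x)
}
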