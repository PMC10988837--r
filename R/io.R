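# Plain-text interchange formats: long-form recording CSV with a JSON
# sidecar, candidate-cycle tables, and the wide feature table in frozen
# registry order. Numeric values are written with 17 significant digits so
# write/read round-trips reproduce doubles exactly.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, format = "g", digits = 17)
  }, character(1))
  out
}

write_csv_exact <- function(df, path) {
  out <- df
  for (nm in colnames(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
}

#' Write a pressure recording to CSV + JSON sidecar
#'
#' The CSV is long-form with columns `subject_id`, `foot`, `time_s`,
#' `s1`..`s8` (kPa); the JSON sidecar stores the sampling rate, per-foot
#' pass boundaries, the subject profile and label, and the sensor layouts.
#'
#' @param recording A `pressure_recording`.
#' @param stem Output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
write_recording <- function(recording, stem) {
  rows <- lapply(c("left", "right"), function(foot) {
    p <- recording[[foot]]
    df <- as.data.frame(p)
    colnames(df) <- paste0("s", 1:8)
    cbind(
      data.frame(
        subject_id = recording$profile$subject_id %||% NA_character_,
        foot = foot,
        time_s = (seq_len(nrow(p)) - 1) / recording$fs
      ),
      df
    )
  })
  write_csv_exact(do.call(rbind, rows), paste0(stem, ".csv"))
  side <- list(
    fs = recording$fs,
    pass_bounds = lapply(recording$pass_bounds, function(b) {
      lapply(seq_len(nrow(b)), function(i) as.integer(b[i, ]))
    }),
    profile = recording$profile,
    label = recording$profile$label %||% NA_integer_,
    layout = list(left = as.data.frame(sensor_layout("left")),
                  right = as.data.frame(sensor_layout("right")))
  )
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' Read a pressure recording written by [write_recording()]
#'
#' @param stem Path stem (expects `<stem>.csv` and `<stem>.json`).
#' @return A `pressure_recording`.
#' @export
read_recording <- function(stem) {
  df <- utils::read.csv(paste0(stem, ".csv"), stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  feet <- lapply(c("left", "right"), function(foot) {
    sub <- df[df$foot == foot, paste0("s", 1:8), drop = FALSE]
    m <- as.matrix(sub)
    dimnames(m) <- NULL
    m
  })
  names(feet) <- c("left", "right")
  # read_json with simplifyVector gives either a matrix or a list per foot
  pb <- lapply(side$pass_bounds, function(b) {
    if (is.matrix(b)) b else do.call(rbind, lapply(b, as.integer))
  })
  out <- list(
    left = feet$left, right = feet$right,
    fs = side$fs,
    pass_bounds = pb,
    profile = side$profile,
    ground_truth = NULL
  )
  class(out) <- "pressure_recording"
  out
}

#' Write / read the candidate-cycle table
#'
#' One row per detected stance candidate: `foot`, `pass`, `cycle_index`,
#' `start`, `end`, `valid`, `reason`, `retained`.
#'
#' @param table The `table` element of [preprocess_recording()].
#' @param path CSV path.
#' @return `path` invisibly; `read_cycles()` returns the data frame.
#' @export
write_cycles <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cycles
#' @export
read_cycles <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the wide per-subject feature table
#'
#' Columns are `subject_id`, the 210 registry features in frozen order,
#' the physiological features and `label`. The writer refuses tables whose
#' feature columns deviate from the registry; numeric values round-trip
#' exactly.
#'
#' @param features Tibble from [cohort_feature_table()].
#' @param path CSV path.
#' @return `path` invisibly; `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(features, path) {
  expected <- c("subject_id", feature_registry(), physio_feature_names(),
                "label")
  if (!identical(colnames(features), expected)) {
    stopf("feature table columns do not match the frozen registry order")
  }
  write_csv_exact(as.data.frame(features), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  expected <- c("subject_id", feature_registry(), physio_feature_names(),
                "label")
  if (!identical(colnames(df), expected)) {
    stopf("file does not contain a registry-ordered feature table")
  }
  for (nm in c(feature_registry(), "age", "height", "weight", "bmi")) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  tibble::as_tibble(df)
}
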