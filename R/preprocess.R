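# Screening, segmentation and splicing of raw recordings into validated
# gait cycles: contact-threshold stance detection, midgait trimming of
# acceleration/deceleration cycles at the ends of each walkway pass, a
# bimodality validity screen on the total-force curve, and selection of the
# first 60 valid cycles per foot.

# Prominent peaks of a total-force stance curve: smooth with a short
# moving average, pad with one zero per side (force is ~0 in swing, so a
# peak on the first/last stance sample is a real maximum), and keep local
# maxima at or above `prominence` times the curve maximum.
prominent_peaks <- function(total, prominence = 0.3, smooth_width = 3L) {
  sm <- moving_average(total, smooth_width)
  pk <- local_maxima(c(0, sm, 0)) - 1L
  pk <- pk[sm[pk] >= prominence * max(sm)]
  list(idx = pk, smoothed = sm)
}

new_gait_cycle <- function(foot, start, end, pressures, fs, pass = NA_integer_,
                           valid = NA, reason = "none") {
  structure(list(
    foot = foot, start = as.integer(start), end = as.integer(end),
    pressures = pressures, total = rowSums(pressures), fs = fs,
    pass = pass, valid = valid, reason = reason
  ), class = "gait_cycle")
}

#' Detect candidate stance phases in a recording
#'
#' Finds, per foot, maximal runs of samples whose total force exceeds
#' `contact_threshold * max(total force of that foot)`. Runs shorter than
#' `min_stance_s` are flagged `too-short`, longer than `max_stance_s`
#' `too-long`, and runs touching a walkway-pass boundary `edge-of-pass`.
#' Sample indices are 0-based with half-open `[start, end)` spans.
#'
#' @param recording A `pressure_recording` (see [simulate_recording()] or
#'   [read_recording()]).
#' @param contact_threshold Contact threshold as a fraction of the foot's
#'   maximal total force, in (0, 1).
#' @param min_stance_s,max_stance_s Admissible stance duration bounds (s).
#' @return Named list (`left`, `right`) of candidate `gait_cycle` objects;
#'   an all-zero foot yields an empty list.
#' @export
detect_stances <- function(recording, contact_threshold = 0.05,
                           min_stance_s = 0.3, max_stance_s = 2.0) {
  if (contact_threshold <= 0 || contact_threshold >= 1) {
    stopf("contact_threshold must be in (0,1), got %g", contact_threshold)
  }
  if (!(min_stance_s > 0 && min_stance_s < max_stance_s)) {
    stopf("need 0 < min_stance_s < max_stance_s")
  }
  fs <- recording$fs
  out <- list()
  for (foot in c("left", "right")) {
    p <- recording[[foot]]
    total <- rowSums(p)
    cands <- list()
    if (any(total > 0)) {
      thr <- contact_threshold * max(total)
      r <- rle(total > thr)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      bounds <- recording$pass_bounds[[foot]]
      for (k in which(r$values)) {
        s0 <- starts[k] - 1L               # 0-based start
        e0 <- ends[k]                      # 0-based exclusive end
        L <- e0 - s0
        pass <- NA_integer_
        edge <- FALSE
        if (!is.null(bounds) && nrow(bounds) > 0) {
          hit <- which(bounds[, 1] <= s0 & e0 <= bounds[, 2])
          if (length(hit)) {
            pass <- hit[1]
            edge <- s0 == bounds[pass, 1] || e0 == bounds[pass, 2]
          }
        }
        reason <- if (edge) {
          "edge-of-pass"
        } else if (L / fs < min_stance_s) {
          "too-short"
        } else if (L / fs > max_stance_s) {
          "too-long"
        } else {
          "none"
        }
        cands[[length(cands) + 1L]] <- new_gait_cycle(
          foot, s0, e0, p[(s0 + 1L):e0, , drop = FALSE], fs,
          pass = pass, valid = if (reason == "none") NA else FALSE,
          reason = reason
        )
      }
    }
    out[[foot]] <- cands
  }
  out
}

#' Bimodality validity screen for one stance cycle
#'
#' A stance is valid when its smoothed total-force curve (3-sample moving
#' average) has exactly two local maxima at or above
#' `peak_prominence * max(curve)`, and the minimum between them lies below
#' `valley_depth * min(peak1, peak2)`. This is the double-peak shape of
#' normal walking (loading response and push-off separated by midstance
#' unloading).
#'
#' @param cycle A `gait_cycle` with at least 5 samples.
#' @param peak_prominence Fraction of the curve maximum a peak must reach.
#' @param valley_depth Fraction of the smaller peak the valley must stay
#'   below.
#' @param smooth_width Moving-average window (samples) used for peak
#'   detection only.
#' @return The cycle with `valid` and `reason` (`"none"` or
#'   `"non-bimodal"`) filled in.
#' @export
check_bimodality <- function(cycle, peak_prominence = 0.3,
                             valley_depth = 0.9, smooth_width = 3L) {
  if (length(cycle$total) < 5L) {
    stopf("bimodality check needs >= 5 samples, got %d", length(cycle$total))
  }
  pks <- prominent_peaks(cycle$total, peak_prominence, smooth_width)
  pk <- pks$idx
  sm <- pks$smoothed
  ok <- FALSE
  if (length(pk) == 2L) {
    valley <- min(sm[pk[1]:pk[2]])
    ok <- valley < valley_depth * min(sm[pk])
  }
  cycle$valid <- ok
  cycle$reason <- if (ok) "none" else "non-bimodal"
  cycle
}

#' Midgait trimming of pass-edge cycles
#'
#' Operationalises the midgait rule: within every walkway pass, cycles
#' recorded while accelerating from standstill or decelerating before the
#' turn are discarded -- all `edge-of-pass` candidates plus the first and
#' last `n_discard_per_end` remaining candidates of the pass. A pass left
#' with nothing after trimming simply contributes zero cycles. Temporal
#' order is preserved.
#'
#' @param candidates List of candidate `gait_cycle`s for one foot (as one
#'   element of [detect_stances()]'s output).
#' @param n_discard_per_end Cycles to drop at each end of each pass.
#' @return The retained candidates, temporally ordered.
#' @export
midgait_trim <- function(candidates, n_discard_per_end = 2L) {
  if (n_discard_per_end < 0) stopf("n_discard_per_end must be >= 0")
  if (!length(candidates)) return(candidates)
  passes <- vapply(candidates, function(cy) cy$pass, integer(1))
  keep <- logical(length(candidates))
  for (p in unique(passes)) {
    idx <- which(passes %in% p)  # %in% keeps NA passes grouped together
    idx <- idx[vapply(candidates[idx], function(cy) cy$reason != "edge-of-pass",
                      logical(1))]
    n <- length(idx)
    if (n > 2L * n_discard_per_end) {
      span <- (n_discard_per_end + 1L):(n - n_discard_per_end)
      keep[idx[span]] <- TRUE
    }
  }
  candidates[keep]
}

#' Select the required number of valid cycles
#'
#' Takes the temporally first `n_required` cycles whose validity flag is
#' `TRUE`; fails loudly when fewer are available rather than padding or
#' resampling.
#'
#' @param cycles List of `gait_cycle`s that have passed trimming and the
#'   bimodality screen.
#' @param n_required Number of cycles to retain (default 60).
#' @return List of exactly `n_required` valid cycles in temporal order.
#' @export
select_valid_cycles <- function(cycles, n_required = 60L) {
  valid <- cycles[vapply(cycles, function(cy) isTRUE(cy$valid), logical(1))]
  if (length(valid) < n_required) {
    foot <- if (length(cycles)) cycles[[1]]$foot else "?"
    stopf("insufficient valid cycles: foot %s has %d of the %d required",
          foot, length(valid), n_required)
  }
  valid[seq_len(n_required)]
}

#' Full preprocessing of one recording
#'
#' Chains stance detection, midgait trimming, the bimodality screen and
#' valid-cycle selection independently for each foot, returning exactly
#' `n_required` validated cycles per foot plus a bookkeeping table of every
#' candidate and its fate.
#'
#' @inheritParams detect_stances
#' @inheritParams check_bimodality
#' @inheritParams midgait_trim
#' @inheritParams select_valid_cycles
#' @return List with `left` and `right` (each `n_required` valid
#'   `gait_cycle`s) and `table`, a data frame with one row per candidate
#'   (`foot`, `pass`, `cycle_index`, `start`, `end`, `valid`, `reason`,
#'   `retained`).
#' @export
preprocess_recording <- function(recording, contact_threshold = 0.05,
                                 min_stance_s = 0.3, max_stance_s = 2.0,
                                 n_discard_per_end = 2L, n_required = 60L,
                                 peak_prominence = 0.3, valley_depth = 0.9) {
  cands <- detect_stances(recording, contact_threshold, min_stance_s,
                          max_stance_s)
  out <- list()
  tabs <- list()
  counts <- c(left = 0L, right = 0L)
  for (foot in c("left", "right")) {
    kept <- midgait_trim(cands[[foot]], n_discard_per_end)
    kept <- lapply(kept, check_bimodality,
                   peak_prominence = peak_prominence,
                   valley_depth = valley_depth)
    retained_starts <- vapply(kept, function(cy) cy$start, integer(1))
    checked <- lapply(cands[[foot]], function(cy) {
      i <- match(cy$start, retained_starts)
      if (!is.na(i)) kept[[i]] else cy
    })
    n_valid <- sum(vapply(kept, function(cy) isTRUE(cy$valid), logical(1)))
    counts[foot] <- n_valid
    out[[foot]] <- kept
    if (length(checked)) {
      tabs[[foot]] <- data.frame(
        foot = foot,
        pass = vapply(checked, function(cy) cy$pass, integer(1)),
        cycle_index = seq_along(checked),
        start = vapply(checked, function(cy) cy$start, integer(1)),
        end = vapply(checked, function(cy) cy$end, integer(1)),
        valid = vapply(checked, function(cy) isTRUE(cy$valid), logical(1)),
        reason = vapply(checked, function(cy) cy$reason, character(1)),
        retained = vapply(checked, function(cy) cy$start %in% retained_starts,
                          logical(1))
      )
    }
  }
  if (any(counts < n_required)) {
    stopf(paste0("insufficient valid cycles: left %d, right %d ",
                 "(need %d per foot)"),
          counts["left"], counts["right"], n_required)
  }
  list(
    left = select_valid_cycles(out$left, n_required),
    right = select_valid_cycles(out$right, n_required),
    table = do.call(rbind, tabs)
  )
}
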