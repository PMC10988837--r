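# The dynamic plantar pressure feature catalogue: 45 biomechanical
# parameters per foot per cycle (regional peak pressures, pressure
# gradients, impulses; whole-foot curve shape; centre-of-pressure
# statistics), aggregated over 60 valid cycles as mean and SD per foot plus
# 30 left-right symmetry indices -- 210 named features per subject.

# 45 per-cycle parameter names, frozen order
cycle_param_names <- function() {
  c(
    as.vector(t(outer(1:8, c("PPP", "MAXPG", "MINPG", "IMP"), paste0))),
    "peak1", "peak2", "valley", "tpeak1", "tpeak2", "stancetime",
    "loadr", "unloadr", "MLratio",
    "Xcopmean", "Ycopmean", "Xcopstd", "Ycopstd"
  )
}

# the 30 parameters that get a symmetry index (computed on cycle means)
si_param_names <- function() {
  c(paste0(1:8, "PPP"), paste0(1:8, "IMP"), "totIMP",
    "peak1", "peak2", "valley", "loadr", "unloadr", "stancetime",
    "tpeak1", "tpeak2", "MLratio",
    "Xcopmean", "Ycopmean", "Xcopstd", "Ycopstd")
}

#' The frozen 210-name plantar feature registry
#'
#' Ordered names of the dynamic plantar pressure feature set: for each foot
#' (`L`, `R`) and each of the 45 per-cycle parameters, the mean over the 60
#' valid cycles (`f_<side><param>`) and the cycle-to-cycle standard
#' deviation (`f_<side><param>_std`), followed by 30 symmetry indices
#' (`SI_<param>`) computed on cycle-mean parameters. Physiological features
#' (`age`, `gender`, `height`, `weight`, `bmi`) are appended by the
#' extractor but are not part of this registry.
#'
#' @return Character vector of 210 unique feature names.
#' @examples
#' length(feature_registry())
#' head(feature_registry())
#' @export
feature_registry <- function() {
  params <- cycle_param_names()
  per_foot <- function(side) {
    as.vector(rbind(paste0("f_", side, params),
                    paste0("f_", side, params, "_std")))
  }
  c(per_foot("L"), per_foot("R"), paste0("SI_", si_param_names()))
}

physio_feature_names <- function() c("age", "gender", "height", "weight", "bmi")

#' Centre-of-pressure track of one cycle
#'
#' COP at each stance sample is the pressure-weighted centroid of the sensor
#' positions: `COP(t) = sum_r p_r(t) pos_r / sum_r p_r(t)`. Samples with
#' zero total force are excluded from the track and from its statistics.
#'
#' @param cycle A `gait_cycle`.
#' @param layout The foot's [sensor_layout()]; the foot-local `x`
#'   (lateral-positive) and `y` (anterior-positive) columns are used, so
#'   left and right statistics are comparable.
#' @return List with `track` (data frame `x`, `y`, one row per included
#'   sample) and the four summary statistics `Xcopmean`, `Ycopmean`,
#'   `Xcopstd`, `Ycopstd` (SDs over stance samples, n-1 denominator, 0 for
#'   a single sample).
#' @export
compute_cop_track <- function(cycle, layout) {
  p <- cycle$pressures
  total <- cycle$total
  live <- total > 0
  p <- p[live, , drop = FALSE]
  total <- total[live]
  x <- as.vector(p %*% layout$x) / total
  y <- as.vector(p %*% layout$y) / total
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  list(
    track = data.frame(x = x, y = y),
    Xcopmean = mean(x), Ycopmean = mean(y),
    Xcopstd = sd0(x), Ycopstd = sd0(y)
  )
}

#' Regional pressure parameters of one cycle
#'
#' For each of the 8 sensor regions: peak plantar pressure
#' (`PPP = max_t p_r(t)`, kPa), maximal and minimal pressure gradient
#' (forward difference of the raw samples times the sampling rate, kPa/s),
#' and impulse (trapezoidal pressure-time integral over stance, kPa s,
#' with the signal taken to rise from and return to zero over one sample at
#' each stance boundary).
#'
#' @param cycle A `gait_cycle`.
#' @param fs Sampling rate (Hz); defaults to the cycle's own.
#' @return Named vector of 32 values (`1PPP` ... `8IMP`).
#' @export
compute_regional_params <- function(cycle, fs = cycle$fs) {
  p <- cycle$pressures
  d <- diff(p) * fs
  # trapezoid with one-sample zero ramps at both ends reduces to dt * sum
  vals <- rbind(
    PPP = apply(p, 2, max),
    MAXPG = apply(d, 2, max),
    MINPG = apply(d, 2, min),
    IMP = colSums(p) / fs
  )
  stats::setNames(as.vector(vals),
                  as.vector(outer(c("PPP", "MAXPG", "MINPG", "IMP"),
                                  1:8, function(a, b) paste0(b, a))))
}

#' Whole-foot curve parameters of one cycle
#'
#' Locates the two peaks of the bimodal total-force curve (peak positions
#' found on the 3-sample smoothed curve, values read from the raw curve)
#' and derives: `peak1`, `peak2` and the intermediate `valley` (kPa);
#' `tpeak1`, `tpeak2` (s from stance start) and `stancetime` (time spanned
#' by the stance samples); the loading rate `loadr = peak1 / tpeak1` and
#' unloading rate `unloadr = peak2 / (stancetime - tpeak2)` (kPa/s); and
#' the medial-to-lateral impulse ratio
#' `MLratio = (IMP_2 + IMP_5 + IMP_7) / (IMP_4 + IMP_6 + IMP_8)`.
#'
#' @param cycle A `gait_cycle` that has passed the bimodality screen.
#' @param fs Sampling rate (Hz).
#' @param peak_prominence,valley_depth,smooth_width Peak-detection settings,
#'   matching [check_bimodality()].
#' @param regional Optional precomputed [compute_regional_params()] result,
#'   to avoid recomputation.
#' @return Named vector of 9 values.
#' @export
compute_wholefoot_params <- function(cycle, fs = cycle$fs,
                                     peak_prominence = 0.3,
                                     valley_depth = 0.9, smooth_width = 3L,
                                     regional = NULL) {
  total <- cycle$total
  L <- length(total)
  pk <- prominent_peaks(total, peak_prominence, smooth_width)$idx
  if (length(pk) != 2L) {
    stopf(paste0("whole-foot parameters need a bimodal cycle ",
                 "(found %d prominent peaks); run check_bimodality first"),
          length(pk))
  }
  # refine each peak position on the raw curve within one sample
  refine <- function(i) {
    win <- max(1L, i - 1L):min(L, i + 1L)
    win[which.max(total[win])]
  }
  i1 <- refine(pk[1]); i2 <- refine(pk[2])
  peak1 <- total[i1]; peak2 <- total[i2]
  valley <- min(total[i1:i2])
  tpeak1 <- (i1 - 1L) / fs
  tpeak2 <- (i2 - 1L) / fs
  stancetime <- (L - 1L) / fs
  rp <- regional %||% compute_regional_params(cycle, fs)
  imp <- rp[paste0(1:8, "IMP")]
  # a peak on the first/last stance sample loads/unloads over the single
  # sample in which force rose from / returns to zero
  c(peak1 = peak1, peak2 = peak2, valley = valley,
    tpeak1 = tpeak1, tpeak2 = tpeak2, stancetime = stancetime,
    loadr = peak1 / max(tpeak1, 1 / fs),
    unloadr = peak2 / max(stancetime - tpeak2, 1 / fs),
    MLratio = unname((imp[2] + imp[5] + imp[7]) /
                       (imp[4] + imp[6] + imp[8] + 1e-12)))
}

#' All 45 per-cycle parameters of one cycle
#'
#' @param cycle A valid `gait_cycle`.
#' @param layout The foot's [sensor_layout()].
#' @param ... Passed to [compute_wholefoot_params()].
#' @return Named vector of 45 values in registry parameter order.
#' @export
cycle_parameters <- function(cycle, layout, ...) {
  rp <- compute_regional_params(cycle)
  wf <- compute_wholefoot_params(cycle, regional = rp, ...)
  cop <- compute_cop_track(cycle, layout)
  out <- c(rp, wf,
           Xcopmean = cop$Xcopmean, Ycopmean = cop$Ycopmean,
           Xcopstd = cop$Xcopstd, Ycopstd = cop$Ycopstd)
  out[cycle_param_names()]
}

#' Symmetry index between left and right parameter values
#'
#' Robinson absolute symmetry index in percent:
#' `SI = |L - R| / (0.5 (|L| + |R|) + eps) * 100`, with `eps = 1e-12`
#' guarding the degenerate all-zero case. 0 means perfect symmetry.
#'
#' @param left_value,right_value Finite numeric values of the same
#'   parameter on the two sides.
#' @return SI in percent, >= 0.
#' @examples
#' symmetry_index(60, 40)  # 40
#' @export
symmetry_index <- function(left_value, right_value) {
  abs(left_value - right_value) /
    (0.5 * (abs(left_value) + abs(right_value)) + 1e-12) * 100
}

#' Aggregate per-cycle parameters into the 210-feature vector
#'
#' For each foot and each of the 45 parameters, emits the mean
#' (`f_<side><param>`) and sample SD (`f_<side><param>_std`, n-1
#' denominator) over the subject's valid cycles, then 30 symmetry indices
#' on the cycle-mean parameters (including the total impulse
#' `totIMP = sum_r IMP_r`), and finally the five physiological features
#' from the profile.
#'
#' @param cycles_left,cycles_right Lists of exactly `n_required` valid
#'   `gait_cycle`s per foot.
#' @param profile Subject profile list with `age`, `gender`, `height`,
#'   `weight`, `bmi` and optionally `subject_id` and `label`.
#' @param n_required Required cycle count per foot (default 60).
#' @return One-row tibble: `subject_id`, the 210 plantar features in
#'   registry order, `age`, `gender`, `height`, `weight`, `bmi`, `label`.
#' @export
aggregate_features <- function(cycles_left, cycles_right, profile,
                               n_required = 60L) {
  if (length(cycles_left) != n_required || length(cycles_right) != n_required) {
    stopf("need exactly %d cycles per foot (got left %d, right %d)",
          n_required, length(cycles_left), length(cycles_right))
  }
  params <- cycle_param_names()
  per_foot <- function(cycles, side) {
    layout <- sensor_layout(if (side == "L") "left" else "right")
    m <- t(vapply(cycles, cycle_parameters, numeric(45), layout = layout))
    colnames(m) <- params
    mu <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    vals <- as.vector(rbind(mu, sdv))
    names(vals) <- as.vector(rbind(paste0("f_", side, params),
                                   paste0("f_", side, params, "_std")))
    list(values = vals, means = c(mu, totIMP = sum(mu[paste0(1:8, "IMP")])))
  }
  lf <- per_foot(cycles_left, "L")
  rf <- per_foot(cycles_right, "R")
  si <- vapply(si_param_names(), function(p) {
    symmetry_index(lf$means[[p]], rf$means[[p]])
  }, numeric(1))
  names(si) <- paste0("SI_", si_param_names())
  feats <- c(lf$values, rf$values, si)[feature_registry()]
  tibble::tibble(
    subject_id = profile$subject_id %||% NA_character_,
    !!!as.list(feats),
    age = profile$age, gender = profile$gender,
    height = profile$height, weight = profile$weight, bmi = profile$bmi,
    label = profile$label %||% NA_integer_
  )
}

#' Feature table for a whole cohort
#'
#' Runs preprocessing and feature extraction for every subject of a
#' simulated (or ingested) cohort.
#'
#' @param cohort Output of [simulate_cohort()], or a list of elements with
#'   `profile` and `recording`.
#' @param n_required Valid cycles required per foot.
#' @param ... Passed to [preprocess_recording()].
#' @return Tibble with one row per subject (see [aggregate_features()]).
#' @export
cohort_feature_table <- function(cohort, n_required = 60L, ...) {
  rows <- lapply(cohort, function(subj) {
    pre <- tryCatch(
      preprocess_recording(subj$recording, n_required = n_required, ...),
      error = function(e) {
        stopf("subject %s: %s", subj$profile$subject_id %||% "?",
              conditionMessage(e))
      }
    )
    aggregate_features(pre$left, pre$right, subj$profile, n_required)
  })
  do.call(rbind, rows)
}
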