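# Stance detection, the bimodality screen, midgait trimming and valid-cycle
# selection.

test_that("a rectangular force pulse is detected with exact boundaries", {
  rec <- pulse_recording(amp = 100, n_on = 12L, n_pad = 20L)  # 0.6 s at 20 Hz
  cands <- detect_stances(rec, contact_threshold = 0.05)
  expect_length(cands$left, 1)
  cy <- cands$left[[1]]
  expect_equal(cy$end - cy$start, 12L)
  expect_equal(cy$start, 20L)
  expect_equal(cy$reason, "none")
})

test_that("short pulses are flagged too-short and all-zero feet yield nothing", {
  rec <- pulse_recording(n_on = 2L)  # 0.1 s
  cands <- detect_stances(rec, min_stance_s = 0.3)
  expect_equal(cands$left[[1]]$reason, "too-short")
  rec0 <- pulse_recording(amp = 0)
  expect_length(detect_stances(rec0)$left, 0)
})

test_that("runs touching a pass boundary are flagged edge-of-pass", {
  rec <- pulse_recording(n_on = 12L, n_pad = 20L)
  rec$left[1:10, 7] <- 90  # contact from the very first sample of the pass
  cands <- detect_stances(rec)
  expect_equal(cands$left[[1]]$reason, "edge-of-pass")
})

test_that("bimodality screen follows the two-peak / valley-depth rule", {
  good <- check_bimodality(two_bump_cycle())
  expect_true(good$valid)
  single <- check_bimodality(cycle_from_total(
    100 * sin(seq(0, pi, length.out = 15))))
  expect_false(single$valid)
  expect_equal(single$reason, "non-bimodal")
  # valley at 0.99 x min(peaks) with depth threshold 0.9: not deep enough.
  # plateaus survive the 3-sample smoothing unchanged
  shallow <- cycle_from_total(c(5, 100, 100, 100, 99, 99, 99,
                                100, 100, 100, 5))
  expect_false(check_bimodality(shallow, valley_depth = 0.9)$valid)
  deep <- cycle_from_total(c(5, 100, 100, 100, 80, 80, 80, 100, 100, 100, 5))
  expect_true(check_bimodality(deep, valley_depth = 0.9)$valid)
  expect_error(check_bimodality(cycle_from_total(c(1, 2, 3))), ">= 5 samples")
})

test_that("midgait trimming drops n cycles per end of each pass", {
  fake <- function(start, pass, reason = "none") {
    insolegait:::new_gait_cycle("left", start, start + 10L,
                                matrix(1, 10, 8), 20, pass = pass,
                                reason = reason)
  }
  ten <- lapply(seq(0, 180, by = 20), function(s) fake(s, 1L))
  kept <- midgait_trim(ten, 2L)
  expect_length(kept, 6)
  expect_equal(vapply(kept, function(cy) cy$start, integer(1)),
               seq(40, 140, by = 20))
  four <- lapply(seq(0, 60, by = 20), function(s) fake(s, 1L))
  expect_length(midgait_trim(four, 2L), 0)
  # edge-of-pass candidates are removed on top of the end trimming
  with_edge <- c(list(fake(0, 1L, reason = "edge-of-pass")), ten)
  expect_length(midgait_trim(with_edge, 2L), 6)
  # six passes of 14 candidates leave 6 x 10 = 60
  sixty <- unlist(lapply(1:6, function(p) {
    lapply(seq(0, 260, by = 20) + 10000 * p, function(s) fake(s, p))
  }), recursive = FALSE)
  expect_length(midgait_trim(sixty, 2L), 60)
})

test_that("valid-cycle selection takes the temporally first 60 and fails loudly", {
  mk <- function(n) {
    lapply(seq_len(n), function(i) {
      cy <- two_bump_cycle()
      cy$start <- i * 20L
      cy$end <- cy$start + length(cy$total)
      cy$valid <- TRUE
      cy
    })
  }
  got <- select_valid_cycles(mk(73), 60L)
  expect_length(got, 60)
  expect_equal(got[[60]]$start, 60L * 20L)
  expect_identical(select_valid_cycles(mk(60), 60L), mk(60))
  expect_error(select_valid_cycles(mk(59), 60L), "insufficient valid cycles")
})

test_that("full preprocessing returns 60 matching, non-overlapping, bimodal cycles", {
  rec <- simulate_recording(test_profile(), small_config(), seed = 17)
  pre <- preprocess_recording(rec)
  gt <- rec$ground_truth
  for (foot in c("left", "right")) {
    cycles <- pre[[foot]]
    expect_length(cycles, 60)
    starts <- vapply(cycles, function(cy) cy$start, integer(1))
    ends <- vapply(cycles, function(cy) cy$end, integer(1))
    expect_true(all(starts[-1] >= ends[-60]))  # temporal order, no overlap
    expect_true(all(vapply(cycles, function(cy) isTRUE(cy$valid),
                           logical(1))))
    gt_f <- gt[gt$foot == foot & !gt$corrupt, ]
    for (i in seq_along(cycles)) {
      j <- which.min(abs(gt_f$start - starts[i]))
      expect_lte(abs(gt_f$start[j] - starts[i]), 1)
      expect_lte(abs(gt_f$end[j] - ends[i]), 1)
    }
  }
})

test_that("preprocessing is idempotent on re-spliced output", {
  rec <- simulate_recording(test_profile(), small_config(), seed = 23)
  pre <- preprocess_recording(rec)
  # re-splice the 60 left cycles into a fresh single-pass recording
  gap <- matrix(0, 8, 8)
  chunks <- list(gap)
  for (cy in pre$left) chunks <- c(chunks, list(cy$pressures), list(gap))
  spliced <- do.call(rbind, chunks)
  rec2 <- structure(list(
    left = spliced, right = spliced, fs = rec$fs,
    pass_bounds = list(left = matrix(c(0L, nrow(spliced)), 1),
                       right = matrix(c(0L, nrow(spliced)), 1)),
    profile = rec$profile, ground_truth = NULL
  ), class = "pressure_recording")
  pre2 <- preprocess_recording(rec2, n_discard_per_end = 0L)
  expect_length(pre2$left, 60)
  lens1 <- vapply(pre$left, function(cy) cy$end - cy$start, integer(1))
  lens2 <- vapply(pre2$left, function(cy) cy$end - cy$start, integer(1))
  expect_equal(lens2, lens1)
  tot1 <- lapply(pre$left, function(cy) cy$total)
  tot2 <- lapply(pre2$left, function(cy) cy$total)
  expect_equal(tot2, tot1)
})

test_that("insufficient valid cycles abort with per-foot counts", {
  cfg <- small_config(corrupt_frac = 1)
  rec <- simulate_recording(test_profile(), cfg, seed = 2)
  expect_error(preprocess_recording(rec), "insufficient valid cycles")
})
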