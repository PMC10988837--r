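# The 210-feature catalogue: COP, regional and whole-foot parameters,
# symmetry indices, aggregation, and the frozen registry.

test_that("feature registry has 210 unique names including published ones", {
  reg <- feature_registry()
  expect_length(reg, 210)
  expect_length(unique(reg), 210)
  expect_true(all(c("f_L8PPP_std", "f_Rpeak2_std", "f_RYcopstd_std",
                    "f_Runloadr_std", "f_RYcopmean", "SI_Xcopmean") %in% reg))
})

test_that("COP track collapses to sensor positions in degenerate loadings", {
  lay <- sensor_layout("left")
  p <- matrix(0, 10, 8)
  p[, 7] <- 50
  cy <- insolegait:::new_gait_cycle("left", 0, 10, p, 20)
  cop <- compute_cop_track(cy, lay)
  expect_equal(cop$Xcopmean, lay$x[7])
  expect_equal(cop$Ycopmean, lay$y[7])
  expect_equal(cop$Xcopstd, 0)
  expect_equal(cop$Ycopstd, 0)
  p2 <- p; p2[, 8] <- 50  # heels equally loaded -> midpoint
  cy2 <- insolegait:::new_gait_cycle("left", 0, 10, p2, 20)
  cop2 <- compute_cop_track(cy2, lay)
  expect_equal(cop2$Xcopmean, mean(lay$x[7:8]))
  expect_equal(cop2$Ycopmean, mean(lay$y[7:8]))
})

test_that("clean generated cycles have anteriorly progressing COP", {
  rec <- simulate_recording(test_profile(), exact_config(), seed = 1)
  pre_cy <- detect_stances(rec)$left[[1]]
  cop <- compute_cop_track(pre_cy, sensor_layout("left"))
  dy <- diff(cop$track$y)
  step <- max(abs(dy))
  expect_true(all(dy >= -step * 0.05))  # nondecreasing within tolerance
})

test_that("regional parameters match closed forms on pulses and ramps", {
  p <- matrix(0, 10, 8)
  p[, 3] <- 100  # rectangular 100 kPa for 0.5 s at 20 Hz
  cy <- insolegait:::new_gait_cycle("left", 0, 10, p, 20)
  rp <- compute_regional_params(cy)
  expect_equal(unname(rp["3PPP"]), 100)
  expect_equal(unname(rp["3IMP"]), 50)  # one-sample zero ramps at the ends
  ramp <- matrix(0, 21, 8)
  ramp[, 2] <- seq(0, 100, length.out = 21)  # 0 -> 100 kPa over 1 s
  cyr <- insolegait:::new_gait_cycle("left", 0, 21, ramp, 20)
  rpr <- compute_regional_params(cyr)
  expect_equal(unname(rpr["2MAXPG"]), 100)
  expect_equal(unname(rpr["2MINPG"]), 100)  # monotone ramp: min slope = max
  fall <- matrix(0, 22, 8)
  fall[, 2] <- c(seq(0, 100, length.out = 21), 0)
  cyf <- insolegait:::new_gait_cycle("left", 0, 22, fall, 20)
  expect_equal(unname(compute_regional_params(cyf)["2MINPG"]), -2000)
})

test_that("sampled parameters agree with a dense-grid oracle", {
  cfg <- exact_config()
  build <- function(fs) {
    L <- round(0.65 * fs) + 1L
    insolegait:::build_clean_cycle(L, cfg$amp_mean,
                                   insolegait:::region_tau(cfg),
                                   insolegait:::region_width(cfg))
  }
  coarse <- insolegait:::new_gait_cycle("left", 0, 14, build(20), 20)
  dense <- insolegait:::new_gait_cycle("left", 0, 1301, build(2000), 2000)
  rp_c <- compute_regional_params(coarse)
  rp_d <- compute_regional_params(dense)
  imp_idx <- paste0(1:8, "IMP")
  expect_equal(unname(rp_c[imp_idx]), unname(rp_d[imp_idx]),
               tolerance = 0.05)
  ppp_idx <- paste0(1:8, "PPP")  # snapped timing: peaks hit exactly
  expect_equal(unname(rp_c[ppp_idx]), unname(rp_d[ppp_idx]),
               tolerance = 1e-9)
})

test_that("whole-foot parameters match the symmetric closed form", {
  cy <- two_bump_cycle(n = 21L, amp = 600, t1 = 0.25, t2 = 0.75)
  wf <- compute_wholefoot_params(cy)
  expect_equal(unname(wf["peak1"]), 600)
  expect_equal(unname(wf["peak2"]), 600)
  expect_equal(unname(wf["tpeak1"]), 0.25)
  expect_equal(unname(wf["tpeak2"]), 0.75)
  expect_equal(unname(wf["stancetime"]), 1.0)
  expect_equal(unname(wf["loadr"]), 2400)
  expect_equal(unname(wf["unloadr"]), 2400)
  # equal medial and lateral impulses give an M/L ratio of 1
  p <- matrix(0, 21, 8)
  for (r in 1:8) p[, r] <- cy$total / 8
  cym <- insolegait:::new_gait_cycle("left", 0, 21, p, 20)
  expect_equal(unname(compute_wholefoot_params(cym)["MLratio"]), 1,
               tolerance = 1e-9)
  expect_error(compute_wholefoot_params(
    cycle_from_total(100 * sin(seq(0, pi, length.out = 15)))), "bimodal")
})

test_that("generated peak times match configured timing within one sample", {
  cfg <- exact_config()
  rec <- simulate_recording(test_profile(), cfg, seed = 2)
  cy <- detect_stances(rec)$left[[1]]
  wf <- compute_wholefoot_params(cy)
  L <- length(cy$total)
  expect_lte(abs(wf[["tpeak1"]] * 20 - cfg$timing[["heel"]] * (L - 1)), 1)
  expect_lte(abs(wf[["tpeak2"]] * 20 - cfg$timing[["meta"]] * (L - 1)), 1)
})

test_that("symmetry index follows the absolute Robinson form", {
  expect_equal(symmetry_index(60, 60), 0)
  expect_equal(symmetry_index(60, 40), 40)
  expect_equal(symmetry_index(0, 0), 0)
  expect_gte(symmetry_index(-3, 5), 0)
})

test_that("aggregation yields 210 features with exact SDs and zero-SD identity", {
  cy <- two_bump_cycle()
  same <- replicate(60, cy, simplify = FALSE)
  fv <- aggregate_features(same, same, test_profile())
  reg <- feature_registry()
  expect_true(all(reg %in% colnames(fv)))
  expect_true(all(is.finite(unlist(fv[, reg]))))
  stds <- unlist(fv[, grep("_std$", reg, value = TRUE)])
  expect_true(all(stds == 0))
  sis <- unlist(fv[, grep("^SI_", reg, value = TRUE)])
  expect_true(all(sis < 1e-9))  # identical feet -> perfect symmetry
  # sensor-8 peak pressures 90, 100, ... match a two-pass SD oracle
  varied <- lapply(0:59, function(i) {
    v <- cy
    v$pressures[, 8] <- 0
    v$pressures[which.max(v$total), 8] <- 90 + i * 10
    v$total <- rowSums(v$pressures)
    v
  })
  fv2 <- aggregate_features(varied, same, test_profile())
  x <- 90 + (0:59) * 10
  two_pass_sd <- sqrt(sum((x - mean(x))^2) / 59)
  expect_equal(fv2$f_L8PPP_std, two_pass_sd)
  expect_error(aggregate_features(same[1:59], same, test_profile()),
               "exactly 60")
})

test_that("features obey pressure-scale equivariance", {
  rec <- simulate_recording(test_profile(), small_config(), seed = 41)
  pre <- preprocess_recording(rec)
  fv1 <- aggregate_features(pre$left, pre$right, test_profile())
  scale_cycle <- function(cy, c) {
    cy$pressures <- cy$pressures * c
    cy$total <- cy$total * c
    cy
  }
  fv3 <- aggregate_features(lapply(pre$left, scale_cycle, c = 3),
                            lapply(pre$right, scale_cycle, c = 3),
                            test_profile())
  scaled <- unlist(lapply(c("PPP", "MAXPG", "MINPG", "IMP"),
                          function(s) paste0("f_L", 1:8, s)))
  scaled <- c(scaled, paste0("f_L", c("peak1", "peak2", "valley",
                                      "loadr", "unloadr")))
  for (nm in scaled) expect_equal(fv3[[nm]], 3 * fv1[[nm]], tolerance = 1e-9)
  invariant <- c("f_LXcopmean", "f_LYcopmean", "f_LXcopstd", "f_LYcopstd",
                 "f_LMLratio", "f_Ltpeak1", "f_Ltpeak2", "f_Lstancetime",
                 grep("^SI_", feature_registry(), value = TRUE))
  for (nm in invariant) expect_equal(fv3[[nm]], fv1[[nm]], tolerance = 1e-9)
})

test_that("cycle features ignore the cycle's position in the recording", {
  cy <- two_bump_cycle()
  shifted <- cy
  shifted$start <- cy$start + 500L
  shifted$end <- cy$end + 500L
  expect_identical(cycle_parameters(cy, sensor_layout("left")),
                   cycle_parameters(shifted, sensor_layout("left")))
})

test_that("regional impulses sum to the total-force integral", {
  rec <- simulate_recording(test_profile(), small_config(), seed = 43)
  cy <- preprocess_recording(rec)$left[[1]]
  rp <- compute_regional_params(cy)
  expect_equal(sum(rp[paste0(1:8, "IMP")]),
               insolegait:::trapz_padded(cy$total, 1 / cy$fs),
               tolerance = 1e-12)
})
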