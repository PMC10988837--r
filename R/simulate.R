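# Synthetic insole recordings: raised-cosine regional waveforms assembled
# into walkway passes, with seeded cycle-to-cycle variability and targeted
# ROA group effects.

region_groups <- c("toe", "meta", "meta", "meta", "mid", "mid", "heel", "heel")

region_tau <- function(config) unname(config$timing[region_groups])
region_width <- function(config) unname(config$width[region_groups])

# raised-cosine bump, peak 1 at u = tau, support |u - tau| <= w (clipped to stance)
rc_bump <- function(u, tau, w) {
  out <- numeric(length(u))
  inside <- abs(u - tau) <= w
  out[inside] <- 0.5 * (1 + cos(pi * (u[inside] - tau) / w))
  out
}

# Impulse-preserving peak perturbation for sensor 8: adds delta at the peak
# sample with flanking compensation summing to zero, so the cycle's peak
# pressure moves by exactly delta while its impulse is unchanged.
ppp_perturbation <- function(n, peak_idx, delta) {
  shape <- c(-0.25, -0.25, 1, -0.25, -0.25)
  offs <- -2:2
  v <- numeric(n)
  idx <- peak_idx + offs
  ok <- idx >= 1 & idx <= n
  v[idx[ok]] <- shape[ok] * delta
  v
}

# One clean stance cycle for one foot. `amps` are this cycle's realised
# regional amplitudes (kPa); taus/widths are fractions of stance. Timing is
# snapped to the sample grid so each region attains its amplitude exactly at
# one sample. Returns L x 8 pressure matrix (noise-free, non-negative).
build_clean_cycle <- function(L, amps, taus, widths, delta8 = 0) {
  u <- seq(0, 1, length.out = L)
  taus_snap <- round(taus * (L - 1)) / (L - 1)
  p <- sapply(1:8, function(r) amps[r] * rc_bump(u, taus_snap[r], widths[r]))
  if (delta8 != 0) {
    j8 <- round(taus_snap[8] * (L - 1)) + 1L
    p[, 8] <- p[, 8] + ppp_perturbation(L, j8, delta8)
  }
  p[p < 0] <- 0
  p
}

# Anterior-posterior COP dispersion modulation: time-warps the spatial
# share curves (per-sample regional fractions of total force) about
# mid-stance while leaving the total-force curve untouched. zeta3 > 0 slows
# the heel-to-toe progression of the pressure distribution (longer dwell at
# the COP extremes, larger within-stance A/P COP spread); zeta3 < 0 speeds
# it up. Peaks, valley, timing and every whole-foot curve parameter stay
# exactly as constructed because the per-sample total is preserved.
apply_cop_warp <- function(p, zeta3) {
  if (zeta3 == 0) return(p)
  L <- nrow(p)
  total <- rowSums(p)
  live <- total > 0
  if (sum(live) < 3) return(p)
  shares <- p
  shares[live, ] <- p[live, , drop = FALSE] / total[live]
  u <- seq(0, 1, length.out = L)
  v <- pmin(pmax(0.5 + (u - 0.5) / (1 + zeta3), 0), 1)
  # linear interpolation of every share column at the warped positions
  pos <- v * (L - 1) + 1
  lo <- pmin(floor(pos), L - 1)
  frac <- pos - lo
  warped <- shares[lo, , drop = FALSE] * (1 - frac) +
    shares[lo + 1, , drop = FALSE] * frac
  rs <- rowSums(warped)
  warped[rs > 0, ] <- warped[rs > 0, , drop = FALSE] / rs[rs > 0]
  out <- warped * total
  out[!live, ] <- 0
  out
}

# A corrupted (non-bimodal) stance: all regions collapse onto one mid-stance
# bump, so the total-force curve has a single peak.
build_corrupt_cycle <- function(L, amps) {
  u <- seq(0, 1, length.out = L)
  p <- sapply(1:8, function(r) 0.7 * amps[r] * rc_bump(u, 0.5, 0.45))
  p[p < 0] <- 0
  p
}

# Per-cycle jitter SDs for one foot of one subject, after group effects.
foot_effect_sds <- function(config, is_roa, foot) {
  m <- config$roa_mult
  list(
    heel_ppp = config$heel_ppp_sd *
      (if (is_roa && foot == "left") m[["heel_ppp"]] else 1),
    peak2 = config$peak2_sd *
      (if (is_roa && foot == "right") m[["peak2"]] else 1),
    ycop = config$ycop_sd *
      (if (is_roa && foot == "right") m[["ycop"]] else 1)
  )
}

# Simulate all passes for one foot. `amp_base` is the subject-level vector
# of regional amplitude means, shared between feet. Returns pressure matrix,
# pass bounds (0-based half-open sample indices) and ground-truth cycle table.
simulate_foot <- function(foot, profile, config, amp_base, seed) {
  with_seed(seed, {
    is_roa <- identical(profile$group, "ROA")
    amp_subj <- amp_base * (1 + stats::rnorm(8, 0, config$asym_cv))
    if (is_roa) {
      hh <- config$roa_mult[["amp_hallux_heel"]]
      amp_subj[c(1, 7, 8)] <- amp_subj[c(1, 7, 8)] * hh
    }
    amp_subj <- pmax(amp_subj, 1)
    sds <- foot_effect_sds(config, is_roa, foot)
    taus0 <- region_tau(config)
    widths <- region_width(config)
    gap <- max(1L, round(config$swing_s * config$fs))
    lead <- gap + 3L

    chunks <- list()
    bounds <- matrix(integer(0), ncol = 2)
    truth <- list()
    pos <- 0L
    for (pass in seq_len(config$n_passes)) {
      pass_start <- pos
      chunks[[length(chunks) + 1L]] <- matrix(0, lead, 8)
      pos <- pos + lead
      for (k in seq_len(config$cycles_per_pass)) {
        dur <- stats::rnorm(1, config$stance_s_mean, config$stance_s_sd)
        dur <- min(max(dur, 0.35), 1.2)
        L <- max(7L, as.integer(round(dur * config$fs)))
        eps <- stats::rnorm(8, 0, config$amp_cv)
        zeta2 <- stats::rnorm(1, 0, sds$peak2)
        zeta3 <- stats::rnorm(1, 0, sds$ycop)
        zeta8 <- stats::rnorm(1, 0, sds$heel_ppp)
        corrupt <- stats::runif(1) < config$corrupt_frac
        amps <- pmax(amp_subj * (1 + eps), 0.5)
        amps[1:4] <- amps[1:4] * max(1 + zeta2, 0.05)
        p <- if (corrupt) {
          build_corrupt_cycle(L, amps)
        } else {
          apply_cop_warp(
            build_clean_cycle(L, amps, taus0, widths, delta8 = amps[8] * zeta8),
            zeta3)
        }
        if (config$noise_sd > 0) {
          live <- rowSums(p) > 0
          p[live, ] <- pmax(p[live, ] +
            stats::rnorm(sum(live) * 8, 0, config$noise_sd), 0)
        }
        chunks[[length(chunks) + 1L]] <- p
        truth[[length(truth) + 1L]] <- data.frame(
          foot = foot, pass = pass, start = pos, end = pos + L,
          corrupt = corrupt
        )
        pos <- pos + L
        chunks[[length(chunks) + 1L]] <- matrix(0, gap, 8)
        pos <- pos + gap
      }
      chunks[[length(chunks) + 1L]] <- matrix(0, 3L, 8)
      pos <- pos + 3L
      bounds <- rbind(bounds, c(pass_start, pos))
    }
    list(
      pressure = do.call(rbind, chunks),
      pass_bounds = bounds,
      truth = do.call(rbind, truth)
    )
  })
}

#' Simulate a two-foot insole pressure recording
#'
#' Generates one subject's walkway protocol: `n_passes` straight passes with
#' `cycles_per_pass` stance cycles per foot per pass, sampled at `fs` Hz.
#' Clean cycles have the bimodal total-force stance curve (heel sensors
#' active early, metatarsal/toe sensors late); a configured fraction of
#' cycles is generated non-bimodal. In the ROA group the configured jitters
#' are scaled exactly by the `roa_mult` factors (lateral-heel peak-pressure
#' SD on the left foot, forefoot push-off SD and COP timing SD on the
#' right).
#'
#' @param profile Subject profile, e.g. one element of
#'   [simulate_cohort()]'s output, or any list with a `group` element equal
#'   to `"ROA"` or `"non-ROA"`.
#' @param config A [gait_sim_config()].
#' @param seed Integer seed; fixes all randomness of this recording.
#' @return A `pressure_recording`: list with per-foot `T x 8` pressure
#'   matrices (`left`, `right`, kPa), `fs`, per-foot pass boundary matrices
#'   (0-based, half-open), the subject `profile`, and a `ground_truth` table
#'   of constructed cycle boundaries with corruption flags.
#' @examples
#' rec <- simulate_recording(list(group = "non-ROA"),
#'                           gait_sim_config(n_passes = 1, cycles_per_pass = 3),
#'                           seed = 1)
#' dim(rec$left)
#' @export
simulate_recording <- function(profile, config = gait_sim_config(), seed = 1L) {
  validate_sim_config(config)
  amp_base <- with_seed(derive_seed(seed, 0),
    config$amp_mean * (1 + stats::rnorm(8, 0, config$subject_amp_cv)))
  lf <- simulate_foot("left", profile, config, amp_base, derive_seed(seed, 1))
  rf <- simulate_foot("right", profile, config, amp_base, derive_seed(seed, 2))
  out <- list(
    left = lf$pressure,
    right = rf$pressure,
    fs = config$fs,
    pass_bounds = list(left = lf$pass_bounds, right = rf$pass_bounds),
    profile = profile,
    ground_truth = rbind(lf$truth, rf$truth)
  )
  class(out) <- "pressure_recording"
  out
}

draw_profile <- function(group, dem, id) {
  g <- if (group == "ROA") dem$roa else dem$non_roa
  repeat {
    age <- stats::rnorm(1, g$age_mean, g$age_sd)
    if (age >= dem$age_range[1] && age <= dem$age_range[2]) break
  }
  height <- stats::rnorm(1, g$height_mean, g$height_sd)
  bmi <- max(stats::rnorm(1, g$bmi_mean, g$bmi_sd), 14)
  weight <- round(bmi * (height / 100)^2, 1)
  list(
    subject_id = id,
    age = round(age, 1),
    gender = if (stats::runif(1) < g$p_male) "male" else "female",
    height = round(height, 1),
    weight = weight,
    bmi = round(weight / (height / 100)^2, 2),
    affected_side = if (stats::runif(1) < g$p_left) "left" else "right",
    group = group,
    label = as.integer(group == "ROA")
  )
}

#' Simulate a labelled cohort of insole recordings
#'
#' Draws subject demographics from the configured group distributions (ROA
#' subjects older and with higher BMI by default) and one full walking
#' recording per subject. Each subject's randomness comes from a stable
#' stream derived from `seed` and the subject index, so cohorts are
#' reproducible and individual subjects can be regenerated independently.
#'
#' @param n_non_roa,n_roa Number of subjects per group (>= 1).
#' @param config A [gait_sim_config()].
#' @param seed Integer master seed.
#' @return List of subjects; each element has `profile` and `recording`.
#' @export
simulate_cohort <- function(n_non_roa, n_roa, config = gait_sim_config(),
                            seed = 1L) {
  if (n_non_roa < 1 || n_roa < 1) {
    stopf("both group sizes must be >= 1 (got %s non-ROA, %s ROA)",
          n_non_roa, n_roa)
  }
  validate_sim_config(config)
  groups <- c(rep("non-ROA", n_non_roa), rep("ROA", n_roa))
  lapply(seq_along(groups), function(i) {
    pseed <- derive_seed(seed, i)
    profile <- with_seed(pseed,
      draw_profile(groups[i], config$demographics, sprintf("S%03d", i)))
    rec <- simulate_recording(profile, config, seed = derive_seed(seed, i, 7L))
    list(profile = profile, recording = rec)
  })
}
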