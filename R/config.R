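#' Configuration for the synthetic gait generator
#'
#' Bundles every tunable of the insole pressure simulator: the recording
#' protocol (sampling rate, walkway passes), the stance-phase waveform model
#' (per-region amplitudes and activation timing), cycle-to-cycle variability
#' sources, and the multiplicative group effects applied to the radiological
#' knee OA (ROA) group.
#'
#' The waveform model builds each region's stance pressure as
#' `amplitude * raised-cosine bump` over a region-specific activation window
#' within stance: heel sensors (7, 8) peak near 20% of stance, midfoot (5, 6)
#' near 42%, metatarsal heads (2-4) near 70% and the great toe near 85%,
#' which yields the bimodal total-force curve that the preprocessing validity
#' screen assumes.
#'
#' Cycle-to-cycle variability has four sources, each a fraction of the
#' relevant mean: independent per-region amplitude jitter (`amp_cv`), a
#' shared forefoot push-off jitter (`peak2_sd`) that moves the second total
#' force peak, a lateral-heel peak-pressure jitter (`heel_ppp_sd`) applied as
#' an impulse-preserving perturbation localised at the sensor-8 peak, and an
#' anterior-posterior activation-timing jitter (`ycop_sd`) on the midfoot
#' and toe windows that perturbs the within-stance spread of the
#' centre-of-pressure (COP) trajectory. In the ROA group the three jitters
#' are scaled by `roa_mult` on one foot each (heel on the left, push-off and
#' COP timing on the right), and optionally the hallux/heel amplitude means
#' are scaled by `roa_mult["amp_hallux_heel"]` bilaterally.
#'
#' @param fs Sampling rate in Hz.
#' @param n_passes Number of straight walkway passes per recording.
#' @param cycles_per_pass Gait cycles laid down in each pass.
#' @param stance_s_mean,stance_s_sd Mean and SD of stance duration (s).
#' @param swing_s Swing (zero-force) gap between consecutive stances (s).
#' @param amp_mean Named length-8 vector of per-region peak amplitude means
#'   (kPa), sensors 1-8.
#' @param amp_cv Length-8 vector of independent per-region cycle-to-cycle
#'   amplitude coefficients of variation. Sensor 8 defaults to 0 because its
#'   peak-pressure variability is injected exclusively through
#'   `heel_ppp_sd`, making that knob the exact cycle-to-cycle SD of the
#'   sensor-8 peak pressure (as a fraction of its amplitude).
#' @param subject_amp_cv Between-subject SD of regional amplitude means, as
#'   a fraction of `amp_mean`.
#' @param asym_cv Between-foot (left/right) SD of regional amplitude means
#'   within a subject, as a fraction; makes symmetry indices realistically
#'   non-zero.
#' @param heel_ppp_sd Cycle-to-cycle SD of the lateral-heel (sensor 8) peak
#'   pressure, as a fraction of its amplitude.
#' @param peak2_sd Cycle-to-cycle SD of the shared forefoot (sensors 1-4)
#'   amplitude multiplier.
#' @param ycop_sd Cycle-to-cycle SD of the midfoot/toe activation-timing
#'   shift (fraction of stance).
#' @param timing Named vector of activation-peak timing fractions of stance:
#'   `heel`, `mid`, `meta`, `toe`; must be strictly inside (0, 1) and
#'   increasing so the first total-force peak precedes the second.
#' @param width Named vector of raised-cosine half-widths (fraction of
#'   stance) for the same four groups.
#' @param noise_sd Measurement noise SD (kPa), added to in-stance samples
#'   and clipped at zero pressure.
#' @param corrupt_frac Fraction of cycles generated as corrupted
#'   (non-bimodal) stances.
#' @param roa_mult Named vector of ROA group-effect multipliers:
#'   `heel_ppp` (left sensor-8 PPP SD), `peak2` (right forefoot push-off
#'   SD), `ycop` (right COP timing SD), `amp_hallux_heel` (bilateral mean
#'   amplitude scaling of sensors 1, 7, 8).
#' @param demographics Group demographic distributions, see
#'   [cohort_demographics()].
#' @return A `gait_sim_config` list, validated.
#' @export
gait_sim_config <- function(fs = 20,
                            n_passes = 6L,
                            cycles_per_pass = 18L,
                            stance_s_mean = 0.65,
                            stance_s_sd = 0.05,
                            swing_s = 0.35,
                            amp_mean = c(220, 180, 200, 150, 85, 90, 330, 300),
                            amp_cv = c(0.13, 0.13, 0.13, 0.13, 0.18, 0.18, 0.13, 0),
                            subject_amp_cv = 0.10,
                            asym_cv = 0.04,
                            heel_ppp_sd = 0.05,
                            peak2_sd = 0.02,
                            ycop_sd = 0.03,
                            timing = c(heel = 0.20, mid = 0.42, meta = 0.70, toe = 0.85),
                            width = c(heel = 0.25, mid = 0.28, meta = 0.25, toe = 0.25),
                            noise_sd = 1.5,
                            corrupt_frac = 0.06,
                            roa_mult = c(heel_ppp = 1.6, peak2 = 3.0, ycop = 2.0,
                                         amp_hallux_heel = 1.0),
                            demographics = cohort_demographics()) {
  cfg <- list(
    fs = fs, n_passes = as.integer(n_passes),
    cycles_per_pass = as.integer(cycles_per_pass),
    stance_s_mean = stance_s_mean, stance_s_sd = stance_s_sd,
    swing_s = swing_s,
    amp_mean = amp_mean, amp_cv = amp_cv,
    subject_amp_cv = subject_amp_cv, asym_cv = asym_cv,
    heel_ppp_sd = heel_ppp_sd, peak2_sd = peak2_sd, ycop_sd = ycop_sd,
    timing = timing, width = width,
    noise_sd = noise_sd, corrupt_frac = corrupt_frac,
    roa_mult = roa_mult, demographics = demographics
  )
  class(cfg) <- "gait_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stopf("invalid gait_sim_config field '%s': %s", field, msg)
  }
  chk(is.numeric(cfg$fs) && length(cfg$fs) == 1 && cfg$fs > 0, "fs",
      "sampling rate must be a single positive number")
  chk(cfg$n_passes >= 1, "n_passes", "need at least one pass")
  chk(cfg$cycles_per_pass >= 1, "cycles_per_pass", "need at least one cycle")
  chk(cfg$stance_s_mean > 0, "stance_s_mean", "must be > 0")
  chk(cfg$stance_s_sd >= 0, "stance_s_sd", "must be >= 0")
  chk(cfg$swing_s >= 0, "swing_s", "must be >= 0")
  chk(length(cfg$amp_mean) == 8 && all(cfg$amp_mean > 0), "amp_mean",
      "need 8 positive regional amplitudes")
  chk(length(cfg$amp_cv) == 8 && all(cfg$amp_cv >= 0), "amp_cv",
      "need 8 non-negative CVs")
  for (f in c("subject_amp_cv", "asym_cv", "heel_ppp_sd", "peak2_sd",
              "ycop_sd", "noise_sd")) {
    chk(cfg[[f]] >= 0, f, "must be >= 0")
  }
  chk(all(c("heel", "mid", "meta", "toe") %in% names(cfg$timing)), "timing",
      "must name heel, mid, meta, toe")
  chk(all(cfg$timing > 0 & cfg$timing < 1), "timing",
      "fractions must be strictly inside (0,1)")
  chk(cfg$timing["heel"] < cfg$timing["meta"], "timing",
      "first peak (heel) must precede second peak (metatarsal)")
  chk(all(cfg$width > 0), "width", "half-widths must be > 0")
  chk(cfg$corrupt_frac >= 0 && cfg$corrupt_frac <= 1, "corrupt_frac",
      "must lie in [0,1]")
  chk(all(c("heel_ppp", "peak2", "ycop", "amp_hallux_heel") %in%
            names(cfg$roa_mult)), "roa_mult",
      "must name heel_ppp, peak2, ycop, amp_hallux_heel")
  chk(all(cfg$roa_mult >= 0), "roa_mult", "multipliers must be >= 0")
  invisible(cfg)
}

#' Group demographic distributions for cohort simulation
#'
#' Normal group distributions for age, height and BMI (weight is derived
#' from BMI and height, so the body-mass-index invariant holds to rounding),
#' plus Bernoulli male probability and left-side involvement probability.
#' Defaults describe a knee-OA outpatient cohort in which the ROA group is
#' on average older and heavier (higher BMI) than the non-ROA group.
#'
#' @param non_roa,roa Named lists with elements `age_mean`, `age_sd`,
#'   `height_mean`, `height_sd`, `bmi_mean`, `bmi_sd`, `p_male`, `p_left`.
#' @param age_range Ages are truncated to this range (years).
#' @return A `cohort_demographics` list.
#' @export
cohort_demographics <- function(non_roa = list(age_mean = 59.76, age_sd = 7.93,
                                               height_mean = 159.31, height_sd = 7.14,
                                               bmi_mean = 23.72, bmi_sd = 3.08,
                                               p_male = 9 / 49, p_left = 31 / 49),
                                roa = list(age_mean = 66.58, age_sd = 7.45,
                                           height_mean = 156.67, height_sd = 8.45,
                                           bmi_mean = 25.40, bmi_sd = 3.63,
                                           p_male = 8 / 43, p_left = 19 / 43),
                                age_range = c(45, 79)) {
  need <- c("age_mean", "age_sd", "height_mean", "height_sd",
            "bmi_mean", "bmi_sd", "p_male", "p_left")
  for (g in list(non_roa, roa)) {
    if (!all(need %in% names(g))) {
      stopf("demographics groups must name: %s", paste(need, collapse = ", "))
    }
  }
  out <- list(non_roa = non_roa, roa = roa, age_range = age_range)
  class(out) <- "cohort_demographics"
  out
}

#' Null configuration: no group differences
#'
#' Returns `config` with every ROA multiplier set to 1 and both demographic
#' groups set to the pooled non-ROA/ROA midpoint, so simulated cohorts carry
#' no signal. Used for type-I-error calibration.
#'
#' @param config A [gait_sim_config()].
#' @return A `gait_sim_config` with null group effects.
#' @export
null_sim_config <- function(config = gait_sim_config()) {
  config$roa_mult[] <- 1
  d <- config$demographics
  pool <- lapply(names(d$non_roa), function(f) {
    (d$non_roa[[f]] + d$roa[[f]]) / 2
  })
  names(pool) <- names(d$non_roa)
  config$demographics$non_roa <- pool
  config$demographics$roa <- pool
  config
}
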