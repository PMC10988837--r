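# Shared fixtures: fast generator configs and hand-built recordings/cycles.

# deterministic, noise-free, single-cycle configuration
exact_config <- function(...) {
  gait_sim_config(
    n_passes = 1L, cycles_per_pass = 1L,
    stance_s_sd = 0, amp_cv = rep(0, 8), subject_amp_cv = 0, asym_cv = 0,
    heel_ppp_sd = 0, peak2_sd = 0, ycop_sd = 0,
    noise_sd = 0, corrupt_frac = 0,
    ...
  )
}

# small but full-featured config: enough cycles for 60 valid per foot
small_config <- function(...) {
  gait_sim_config(n_passes = 6L, cycles_per_pass = 16L, ...)
}

test_profile <- function(group = "non-ROA", id = "T01") {
  list(subject_id = id, age = 60, gender = "female", height = 160,
       weight = 60, bmi = 23.44, affected_side = "left", group = group,
       label = as.integer(group == "ROA"))
}

# recording with a single rectangular total-force pulse on each foot
pulse_recording <- function(amp = 100, n_on = 12L, n_pad = 20L, fs = 20) {
  m <- matrix(0, n_pad + n_on + n_pad, 8)
  m[(n_pad + 1):(n_pad + n_on), 7] <- amp
  structure(list(
    left = m, right = m, fs = fs,
    pass_bounds = list(left = matrix(c(0L, nrow(m)), 1),
                       right = matrix(c(0L, nrow(m)), 1)),
    profile = test_profile(),
    ground_truth = NULL
  ), class = "pressure_recording")
}

# gait_cycle whose total-force curve equals `total` (all force on sensor 7)
cycle_from_total <- function(total, fs = 20, foot = "left") {
  p <- matrix(0, length(total), 8)
  p[, 7] <- total
  insolegait:::new_gait_cycle(foot, 0L, length(total), p, fs)
}

# valid two-bump stance cycle built from raised cosines, peaks `amp` at
# fractions t1/t2 of an (n-1)/fs-second stance
two_bump_cycle <- function(n = 21L, amp = 600, t1 = 0.25, t2 = 0.75,
                           width = 0.2, fs = 20, foot = "left") {
  u <- seq(0, 1, length.out = n)
  bump <- function(tau) {
    out <- numeric(n)
    inside <- abs(u - tau) <= width
    out[inside] <- 0.5 * (1 + cos(pi * (u[inside] - tau) / width))
    out
  }
  cycle_from_total(amp * (bump(t1) + bump(t2)), fs = fs, foot = foot)
}
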