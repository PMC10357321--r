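# Generator configuration: the stated world the synthetic data emulate.

#' Canonical kinematic variable names
#'
#' The 16 channels of a reach-to-grasp trajectory, in the fixed canonical
#' order used by every feature vector: wrist velocity (mm/s), wrist height
#' (mm, vertical z), wrist horizontal trajectory (mm, transverse x), grip
#' aperture (mm), thumb and index tip coordinates in the hand-local frame
#' (mm), and the unit-normal components of the finger (thumb-index) and
#' dorsum (radius-phalanx) planes.
#'
#' @return character vector of length 16.
#' @export
kp_variables <- function() {
  c("W_V", "W_H", "W_HT", "G_A",
    "T_X", "T_Y", "T_Z", "I_X", "I_Y", "I_Z",
    "FP_X", "FP_Y", "FP_Z", "DP_X", "DP_Y", "DP_Z")
}

default_noise_sd <- function() {
  c(W_V = 60, W_H = 15, W_HT = 10, G_A = 8,
    T_X = 5, T_Y = 5, T_Z = 5, I_X = 5, I_Y = 5, I_Z = 5,
    FP_X = 0.05, FP_Y = 0.05, FP_Z = 0.05,
    DP_X = 0.05, DP_Y = 0.05, DP_Z = 0.05)
}

#' Build and validate a generator configuration
#'
#' Defines the conditions the synthetic data emulate: 30 + 30
#' reach-to-pour/reach-to-drink primes sampled at 100 Hz with movement
#' durations in 0.84-1.36 s, 20 perceivers reading a two-variable subspace
#' (wrist height and wrist horizontal trajectory), a 75% congruent priming
#' design of 240 trials, and a 240-trial (4 repetitions x 60 primes)
#' discrimination session. Intention effect sizes (SD units per variable)
#' default to W_H = 3, W_HT = 1.5, DP_Y = 0.75, all others 0. Perceivers
#' read strongly (high gain, hence highly predictable choices, the ~95%
#' readout-performance regime) but imperfectly (tilted readout vectors), so
#' discrimination accuracy lands in the ~75% target regime; see the methods
#' vignette for the calibration.
#'
#' @param n_primes_per_intention primes per intention (default 30).
#' @param n_perceivers simulated perceivers (default 20).
#' @param sample_rate kinematic sampling rate, Hz.
#' @param duration_range movement duration range, seconds.
#' @param effect_profile named per-variable intention effect sizes, SD units.
#' @param trajectory_noise_sd named per-variable trial-to-trial SDs (channel units).
#' @param readout_subspace variables perceivers read (default W_H, W_HT).
#' @param readout_gain_range per-perceiver readout gain range (uniform).
#' @param readout_noise_sd SD of perceiver-specific noise on readout weights.
#' @param lapse_rate probability of a random choice in the 2AFC task.
#' @param rt_base_ms,rt_probe_effect_ms,rt_priming_gain_ms_per_logodds,rt_gamma_shape
#'   identity-link gamma RT parameters of the priming session.
#' @param rt_participant_sd_ms,rt_prime_sd_ms random-intercept SDs for RTs.
#' @param fixation_base_logit,fixation_priming_gain,fixation_participant_sd
#'   first-fixation logit parameters.
#' @param fixation_none_rate fraction of trials with no initial probe fixation.
#' @param confidence_thresholds 3 increasing cutpoints on the absolute readout
#'   predictor defining confidence bins 1-4.
#' @param confidence_noise_sd jitter SD added before binning confidence.
#' @param congruent_fraction proportion of congruent priming trials.
#' @param n_priming_trials priming trials per participant (default 240).
#' @param n_discrimination_reps repetitions of each prime in the 2AFC task.
#' @param error_rate probe-categorization error rate in the priming task.
#' @param pupil_ar1 AR(1) coefficient of the baseline-pupil noise process.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated list of class `kp_config`.
#' @export
kp_config <- function(n_primes_per_intention = 30,
                      n_perceivers = 20,
                      sample_rate = 100,
                      duration_range = c(0.84, 1.36),
                      effect_profile = NULL,
                      trajectory_noise_sd = NULL,
                      readout_subspace = c("W_H", "W_HT"),
                      readout_gain_range = c(2, 6),
                      readout_noise_sd = 0.6,
                      lapse_rate = 0.05,
                      rt_base_ms = 600,
                      rt_probe_effect_ms = 10,
                      rt_priming_gain_ms_per_logodds = 3,
                      rt_gamma_shape = 20,
                      rt_participant_sd_ms = 40,
                      rt_prime_sd_ms = 10,
                      fixation_base_logit = -0.2,
                      fixation_priming_gain = 0.08,
                      fixation_participant_sd = 0.3,
                      fixation_none_rate = 0.14,
                      confidence_thresholds = c(3, 6, 11),
                      confidence_noise_sd = 1.5,
                      congruent_fraction = 0.75,
                      n_priming_trials = 240,
                      n_discrimination_reps = 4,
                      error_rate = 0.02,
                      pupil_ar1 = 0.8,
                      seed = 1L) {
  vars <- kp_variables()
  ep <- stats::setNames(rep(0, 16), vars)
  ep[c("W_H", "W_HT", "DP_Y")] <- c(3, 1.5, 0.75)
  if (!is.null(effect_profile)) {
    if (is.null(names(effect_profile)) || !all(names(effect_profile) %in% vars))
      stop_kp("effect_profile must be named with kinematic variable names",
              class = "kp_config_error")
    ep[] <- 0
    ep[names(effect_profile)] <- effect_profile
  }
  ns <- default_noise_sd()
  if (!is.null(trajectory_noise_sd)) {
    if (is.null(names(trajectory_noise_sd)) ||
        !all(names(trajectory_noise_sd) %in% vars))
      stop_kp("trajectory_noise_sd must be named with kinematic variable names",
              class = "kp_config_error")
    ns[names(trajectory_noise_sd)] <- trajectory_noise_sd
  }
  cfg <- list(
    n_primes_per_intention = as.integer(n_primes_per_intention),
    n_perceivers = as.integer(n_perceivers),
    sample_rate = sample_rate,
    duration_range = duration_range,
    effect_profile = ep,
    trajectory_noise_sd = ns,
    readout_subspace = readout_subspace,
    readout_gain_range = readout_gain_range,
    readout_noise_sd = readout_noise_sd,
    lapse_rate = lapse_rate,
    rt_base_ms = rt_base_ms,
    rt_probe_effect_ms = rt_probe_effect_ms,
    rt_priming_gain_ms_per_logodds = rt_priming_gain_ms_per_logodds,
    rt_gamma_shape = rt_gamma_shape,
    rt_participant_sd_ms = rt_participant_sd_ms,
    rt_prime_sd_ms = rt_prime_sd_ms,
    fixation_base_logit = fixation_base_logit,
    fixation_priming_gain = fixation_priming_gain,
    fixation_participant_sd = fixation_participant_sd,
    fixation_none_rate = fixation_none_rate,
    confidence_thresholds = confidence_thresholds,
    confidence_noise_sd = confidence_noise_sd,
    congruent_fraction = congruent_fraction,
    n_priming_trials = as.integer(n_priming_trials),
    n_discrimination_reps = as.integer(n_discrimination_reps),
    error_rate = error_rate,
    pupil_ar1 = pupil_ar1,
    seed = as.integer(seed)
  )
  validate_kp_config(cfg)
  structure(cfg, class = "kp_config")
}

validate_kp_config <- function(cfg) {
  fail <- function(msg) stop_kp(msg, class = "kp_config_error")
  counts <- c(cfg$n_primes_per_intention, cfg$n_perceivers,
              cfg$n_priming_trials, cfg$n_discrimination_reps)
  if (any(!is.finite(counts)) || any(counts < 1)) fail("all counts must be >= 1")
  if (cfg$congruent_fraction <= 0 || cfg$congruent_fraction >= 1)
    fail("congruent_fraction must lie in (0, 1)")
  if (length(cfg$confidence_thresholds) != 3 ||
      any(diff(cfg$confidence_thresholds) <= 0))
    fail("confidence_thresholds must be 3 strictly increasing cutpoints")
  if (cfg$rt_gamma_shape <= 0) fail("rt_gamma_shape must be > 0")
  if (length(cfg$duration_range) != 2 || diff(cfg$duration_range) < 0 ||
      cfg$duration_range[1] <= 0)
    fail("duration_range must be positive and non-decreasing")
  if (cfg$lapse_rate < 0 || cfg$lapse_rate > 1) fail("lapse_rate must be in [0, 1]")
  if (length(cfg$readout_gain_range) != 2 ||
      diff(cfg$readout_gain_range) < 0)
    fail("readout_gain_range must be a non-decreasing pair")
  if (!all(cfg$readout_subspace %in% kp_variables()))
    fail("readout_subspace must contain kinematic variable names")
  invisible(cfg)
}
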