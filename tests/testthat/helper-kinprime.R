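# Shared fixtures, built in code and cached per test run.

.kp_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .kp_cache)) assign(key, force(expr), envir = .kp_cache)
  get(key, envir = .kp_cache)
}

# A reduced world for fast unit tests: 12+12 primes, 4 perceivers.
small_config <- function(seed = 7, n_primes_per_intention = 12,
                         n_perceivers = 4, n_priming_trials = 96, ...) {
  kp_config(n_primes_per_intention = n_primes_per_intention,
            n_perceivers = n_perceivers,
            n_priming_trials = n_priming_trials, seed = seed, ...)
}

small_world <- function() {
  cached("small_world", {
    cfg <- small_config()
    primes <- generate_primes(cfg)
    features_raw <- build_feature_matrix(primes)
    features <- zscore_features(features_raw)
    perceivers <- generate_perceivers(cfg, primes$ground_truth$encoding_direction)
    disc <- simulate_discrimination(primes, perceivers, cfg, features = features)
    list(cfg = cfg, primes = primes, features_raw = features_raw,
         features = features, perceivers = perceivers, disc = disc)
  })
}

# The default-scale world (60 primes, 20 perceivers), built once.
default_world <- function() {
  cached("default_world", {
    cfg <- kp_config(seed = 11)
    primes <- generate_primes(cfg)
    features <- zscore_features(build_feature_matrix(primes))
    perceivers <- generate_perceivers(cfg, primes$ground_truth$encoding_direction)
    list(cfg = cfg, primes = primes, features = features, perceivers = perceivers)
  })
}

# Random trajectory whose W_V is a clean unimodal bell (for bounds tests).
random_bell <- function(n = 120, peak = NULL) {
  if (is.null(peak)) peak <- stats::runif(1, 100, 1200)
  t <- seq(0, 1, length.out = n)
  peak * (1 - cos(2 * pi * t)) / 2
}

# Brute-force oracle for movement bounds: exhaustive scan of the definition.
bounds_oracle <- function(v, thr = 20) {
  onset <- NA_integer_
  for (i in seq_along(v)) if (v[i] > thr) { onset <- i; break }
  if (is.na(onset)) return(NULL)
  offset <- NA_integer_
  for (i in seq_along(v)) if (i > onset && v[i] < thr) { offset <- i; break }
  if (is.na(offset)) return(list(onset = onset, offset = NA_integer_))
  list(onset = onset, offset = offset)
}

# Simulate gamma-identity mixed RT data with known fixed effects.
sim_gamma_mixed <- function(n_participants = 20, n_trials = 240,
                            base = 600, cong_effect = -30, shape = 20,
                            participant_sd = 40, seed = 1) {
  set.seed(seed)
  d <- expand.grid(trial = seq_len(n_trials),
                   participant_id = sprintf("g%02d", seq_len(n_participants)),
                   stringsAsFactors = FALSE)
  bp <- stats::rnorm(n_participants, 0, participant_sd)
  names(bp) <- sprintf("g%02d", seq_len(n_participants))
  d$congruency <- sample(c("congruent", "incongruent"), nrow(d), TRUE, c(0.75, 0.25))
  # sum contrasts: congruent = +1 -> effect/2 applied with opposite signs
  d$mu <- base + bp[d$participant_id] +
    ifelse(d$congruency == "congruent", cong_effect / 2, -cong_effect / 2)
  d$rt_ms <- stats::rgamma(nrow(d), shape = shape, rate = shape / d$mu)
  d$prime_id <- sample(sprintf("p%02d", 1:20), nrow(d), TRUE)
  d
}
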