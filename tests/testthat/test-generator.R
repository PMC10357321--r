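test_that("config invariants are validated", {
  expect_s3_class(kp_config(), "kp_config")
  expect_error(kp_config(congruent_fraction = 1), "congruent_fraction")
  expect_error(kp_config(confidence_thresholds = c(2, 1, 3)), "increasing")
  expect_error(kp_config(rt_gamma_shape = 0), "rt_gamma_shape")
  expect_error(kp_config(n_perceivers = 0), "counts")
  expect_error(kp_config(effect_profile = c(BAD = 1)), "effect_profile")
})

test_that("prime generation is seed-deterministic and bounded", {
  cfg <- small_config(seed = 3)
  p1 <- generate_primes(cfg)
  p2 <- generate_primes(cfg)
  expect_identical(p1$trajectories, p2$trajectories)
  expect_length(p1$trajectories, 2 * cfg$n_primes_per_intention)
  # wrist velocity yields detectable 20 mm/s bounds on every prime
  for (tr in p1$trajectories) {
    expect_true(all(tr$channels[, "W_V"] >= 0))
    b <- detect_movement_bounds(tr$channels[, "W_V"], 20)
    expect_lt(b$onset, b$offset)
    dur <- (b$offset - b$onset) / cfg$sample_rate
    expect_gte(dur, cfg$duration_range[1] - 0.15)
    expect_lte(dur, cfg$duration_range[2] + 0.15)
  }
  # ground truth: unit encoding direction, mass only in effect variables
  gt <- p1$ground_truth
  expect_equal(sqrt(sum(gt$encoding_direction^2)), 1, tolerance = 1e-12)
  fv <- sub("_e[0-9]+$", "", names(gt$encoding_direction))
  expect_true(all(gt$encoding_direction[!fv %in% c("W_H", "W_HT", "DP_Y")] == 0))
})

test_that("zero effect profile yields no intention differences", {
  cfg <- kp_config(effect_profile = c(W_H = 0), seed = 5)
  pr <- generate_primes(cfg)
  x <- build_feature_matrix(pr)$values
  ip <- pr$intention == "pour"
  tstats <- apply(x, 2, function(col) {
    unname(t.test(col[ip], col[!ip])$statistic)
  })
  # no injected effect: |t| >= 2 only at the chance rate (~5% of 64
  # features; 7 is the ~99.9% binomial bound)
  expect_lte(sum(abs(tstats) >= 2), 7)
  expect_lt(median(abs(tstats)), 1.5)
})

test_that("configured W_H effect size is realized on epoch-averaged features", {
  # Monte-Carlo calibration check: late-epoch (e4) Cohen's d of W_H across
  # seeds within +/- 25% of the configured effect size (reduced from 100 to
  # 25 seeds for the test budget; the mean estimate's MC error is ~0.06)
  cohend <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / sp
  }
  ds <- vapply(1:25, function(s) {
    cfg <- kp_config(seed = s)
    pr <- generate_primes(cfg)
    x <- build_feature_matrix(pr)$values
    ip <- pr$intention == "pour"
    cohend(x[ip, "W_H_e4"], x[!ip, "W_H_e4"])
  }, numeric(1))
  target <- kp_config()$effect_profile[["W_H"]]
  expect_gt(mean(ds), 0.75 * target)
  expect_lt(mean(ds), 1.25 * target)
})

test_that("perceiver generation respects subspace, gain and noise structure", {
  w <- small_world()
  cfg <- w$cfg
  dir <- w$primes$ground_truth$encoding_direction
  fv <- sub("_e[0-9]+$", "", names(dir))
  pc <- w$perceivers
  # nonzero components restricted to the readout subspace
  outside <- !fv %in% cfg$readout_subspace
  expect_true(all(pc$readout_vectors[, outside] == 0))
  # zero gain range -> all-zero vectors
  pc0 <- generate_perceivers(kp_config(readout_gain_range = c(0, 0)), dir)
  expect_true(all(pc0$readout_vectors == 0))
  # full subspace, no noise -> parallel to the encoding direction
  pc1 <- generate_perceivers(
    kp_config(readout_subspace = kp_variables(), readout_noise_sd = 0,
              n_perceivers = 3), dir)
  for (i in 1:3) {
    cs <- sum(pc1$readout_vectors[i, ] * dir) /
      sqrt(sum(pc1$readout_vectors[i, ]^2) * sum(dir^2))
    expect_equal(cs, 1, tolerance = 1e-12)
  }
  expect_error(generate_perceivers(kp_config(readout_subspace = character(0)), dir),
               "readout_subspace")
})

test_that("across-perceiver gain spread matches the configured range", {
  # SD of U(a, b) is (b - a)/sqrt(12); check over seeds (reduced to 40)
  dir <- small_world()$primes$ground_truth$encoding_direction
  sds <- vapply(1:40, function(s) {
    sd(generate_perceivers(kp_config(seed = s), dir)$gains)
  }, numeric(1))
  target <- diff(kp_config()$readout_gain_range) / sqrt(12)
  expect_gt(mean(sds), 0.75 * target)
  expect_lt(mean(sds), 1.25 * target)
})

test_that("discrimination choices follow the logistic observer", {
  w <- small_world()
  # zero readout vector -> chance accuracy
  cfg0 <- small_config(seed = 21, readout_gain_range = c(0, 0))
  pc0 <- generate_perceivers(cfg0, w$primes$ground_truth$encoding_direction)
  d0 <- simulate_discrimination(w$primes, pc0, cfg0, features = w$features)
  acc0 <- mean(d0$correct[d0$perceiver_id == "s01"])
  expect_gte(acc0, 0.35)
  expect_lte(acc0, 0.65)
  # saturated readout, no lapse -> accuracy > 0.95
  cfgS <- small_config(seed = 22, readout_gain_range = c(50, 50),
                       lapse_rate = 0, readout_noise_sd = 0)
  pcS <- generate_perceivers(cfgS, w$primes$ground_truth$encoding_direction)
  dS <- simulate_discrimination(w$primes, pcS, cfgS, features = w$features)
  expect_gt(mean(dS$correct), 0.95)
  # law of large numbers: per-prime empirical choice rates converge to the
  # sigmoid of the predictor (10^4 repetitions via many blocks)
  cfgL <- small_config(seed = 23, n_perceivers = 1, lapse_rate = 0,
                       n_discrimination_reps = 2500)
  pcL <- generate_perceivers(cfgL, w$primes$ground_truth$encoding_direction)
  dL <- simulate_discrimination(w$primes, pcL, cfgL, features = w$features)
  emp <- tapply(dL$choice == "pour", dL$prime_id, mean)
  theo <- plogis(tapply(dL$predictor, dL$prime_id, function(v) v[1]))
  expect_lt(max(abs(emp - theo[names(emp)])), 0.05)
})

test_that("priming session matches its stated design and identity-link means", {
  w <- small_world()
  cfg <- kp_config(seed = 31, n_perceivers = 2)
  pw <- generate_primes(cfg)
  fm <- zscore_features(build_feature_matrix(pw))
  pc <- generate_perceivers(cfg, pw$ground_truth$encoding_direction)
  pt <- simulate_priming_session(pw, pc, cfg, features = fm)
  # exact congruency counts: 180 congruent / 60 incongruent per participant
  tab <- table(pt$participant_id, pt$congruency)
  expect_true(all(tab[, "congruent"] == 180))
  expect_true(all(tab[, "incongruent"] == 60))
  # congruency consistency invariant
  map <- c(pour = "pouring", drink = "drinking")
  expect_identical(pt$congruency == "congruent",
                   unname(map[pt$prime_intention] == pt$probe))
  # no-gain generator: congruent vs incongruent RT difference ~ 0
  cfg0 <- kp_config(seed = 32, n_perceivers = 4,
                    rt_priming_gain_ms_per_logodds = 0, fixation_priming_gain = 0)
  pt0 <- simulate_priming_session(pw, generate_perceivers(cfg0, pw$ground_truth$encoding_direction),
                                  cfg0, features = fm)
  dd <- t.test(rt_ms ~ congruency, data = pt0)
  expect_lt(abs(diff(dd$estimate)) / dd$stderr, 2.5)
  # Monte-Carlo against the closed-form identity-link mean at ~10^4 trials
  cfgL <- kp_config(seed = 33, n_perceivers = 1, n_priming_trials = 9600,
                    rt_participant_sd_ms = 0, rt_prime_sd_ms = 0)
  pcL <- generate_perceivers(cfgL, pw$ground_truth$encoding_direction)
  ptL <- simulate_priming_session(pw, pcL, cfgL, features = fm)
  mu_theo <- cfgL$rt_base_ms +
    0.5 * cfgL$rt_probe_effect_ms * ifelse(ptL$probe == "pouring", 1, -1) +
    ifelse(ptL$congruency == "congruent", -1, 1) *
      cfgL$rt_priming_gain_ms_per_logodds * ptL$true_readout_index
  for (cell in split(seq_len(nrow(ptL)), ptL$congruency)) {
    se <- sd(ptL$rt_ms[cell]) / sqrt(length(cell))
    expect_lt(abs(mean(ptL$rt_ms[cell]) - mean(mu_theo[cell])), 2 * se)
  }
  # pupil baselines independent of congruency and readout index
  expect_lt(abs(cor(ptL$baseline_pupil, ptL$true_readout_index)), 0.05)
  expect_lt(abs(cor(ptL$baseline_pupil, ptL$congruency == "congruent")), 0.05)
  # impossible means raise a generation error
  cfgBad <- kp_config(seed = 34, rt_base_ms = 5,
                      rt_priming_gain_ms_per_logodds = 500,
                      rt_participant_sd_ms = 0)
  expect_error(
    simulate_priming_session(pw, generate_perceivers(cfgBad, pw$ground_truth$encoding_direction),
                             cfgBad, features = fm),
    "mean RT")
})

test_that("stage substreams are independent", {
  cfg <- small_config(seed = 41)
  pr <- generate_primes(cfg)
  pc1 <- generate_perceivers(cfg, pr$ground_truth$encoding_direction)
  # regenerating primes does not perturb the perceiver stream
  invisible(generate_primes(cfg))
  pc2 <- generate_perceivers(cfg, pr$ground_truth$encoding_direction)
  expect_identical(pc1, pc2)
})
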