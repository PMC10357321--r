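make_priming <- function(seed = 61, ...) {
  cached(sprintf("priming_%d", seed), {
    cfg <- kp_config(seed = seed, n_perceivers = 8, n_priming_trials = 120, ...)
    pr <- generate_primes(cfg)
    fm <- zscore_features(build_feature_matrix(pr))
    pc <- generate_perceivers(cfg, pr$ground_truth$encoding_direction)
    simulate_priming_session(pr, pc, cfg, features = fm)
  })
}

test_that("exclusion rules match a brute-force reimplementation", {
  pt <- make_priming()
  out <- apply_exclusions(pt, for_fixation = TRUE)
  # independent re-derivation of the three rules in the stated order
  t1 <- pt[pt$accuracy == 1, ]
  keep <- rep(TRUE, nrow(t1))
  for (p in unique(t1$participant_id)) {
    sel <- t1$participant_id == p
    thr <- mean(t1$rt_ms[sel]) + 2.5 * sd(t1$rt_ms[sel])
    keep[sel] <- t1$rt_ms[sel] <= thr
  }
  t2 <- t1[keep, ]
  t3 <- t2[t2$first_fixation_class != "none", ]
  expect_equal(out$trials$rt_ms, t3$rt_ms)
  expect_equal(out$report$n_retained, nrow(t3))
  expect_equal(out$report$n_incorrect, sum(pt$accuracy == 0))
  # clean data -> zero exclusions
  clean <- pt[1:50, ]
  clean$accuracy <- 1
  clean$rt_ms <- 600 + (seq_len(50) %% 5)
  clean$first_fixation_class <- "other"
  rep0 <- apply_exclusions(clean, for_fixation = TRUE)$report
  expect_equal(rep0$n_retained, 50)
  # one planted outlier at mean + 3 SD is the only RT exclusion
  one <- clean
  one$rt_ms[25] <- mean(clean$rt_ms[-25]) + 3.2 * sd(clean$rt_ms[-25])
  rep1 <- apply_exclusions(one)$report
  expect_equal(rep1$n_rt_excluded, 1)
  # near-idempotence: the RT threshold is recomputed from the input, so a
  # second pass may trim a stray trial; it must not cascade (< 0.3%)
  again <- apply_exclusions(out$trials, for_fixation = TRUE)
  expect_lte(nrow(out$trials) - nrow(again$trials),
             ceiling(0.003 * nrow(out$trials)))
})

test_that("first-fixation classification follows the quadrant mapping", {
  W <- 1920; H <- 1080
  # pouring probe: bottom-left quadrant is relevant-displayed
  expect_equal(classify_first_fixation(100, 900, "pouring", W, H), "relevant-displayed")
  # pouring probe, top-right quadrant -> relevant for the non-displayed probe
  expect_equal(classify_first_fixation(1500, 100, "pouring", W, H), "relevant-nondisplayed")
  expect_equal(classify_first_fixation(1500, 100, "drinking", W, H), "relevant-displayed")
  expect_equal(classify_first_fixation(100, 100, "drinking", W, H), "other")
  # centre belongs to top-right by the boundary convention
  expect_equal(classify_first_fixation(W / 2, H / 2, "drinking", W, H), "relevant-displayed")
  expect_equal(classify_first_fixation(W / 2, H / 2, "pouring", W, H), "relevant-nondisplayed")
  # outside the image -> none
  expect_equal(classify_first_fixation(-5, 100, "pouring", W, H), "none")
  # vectorized
  out <- classify_first_fixation(c(100, 1500), c(900, 100), c("pouring", "pouring"), W, H)
  expect_equal(out, c("relevant-displayed", "relevant-nondisplayed"))
})

test_that("congruency-information model detects injected priming and its signs", {
  pt <- make_priming()
  ex <- apply_exclusions(pt)$trials
  cim <- congruency_information_model(ex, "true_readout_index", "rt")
  expect_lt(cim$lrt_interaction$p_value, 0.05)
  expect_lt(cim$slopes["congruent", "estimate"], 0)
  expect_gt(cim$slopes["incongruent", "estimate"], 0)
  expect_error(congruency_information_model(ex, "missing_col", "rt"), "missing")
})

test_that("fixation model reports a probability-scale interaction test", {
  pt <- make_priming()
  exf <- apply_exclusions(pt, for_fixation = TRUE)$trials
  cim <- congruency_information_model(exf, "true_readout_index", "fixation")
  expect_true(is.finite(cim$marginal$p_value))
  # sign agreement between latent product term and marginal effect
  cf <- cim$fit$coefficients
  b_int <- cf$estimate[grepl("congruency1:true_readout_index|true_readout_index:congruency1", cf$term)]
  expect_equal(sign(cim$marginal$estimate), sign(b_int))
})

test_that("median split orders priming by readout and validates input", {
  pt <- make_priming()
  ex <- apply_exclusions(pt)$trials
  ms <- median_split_priming(ex, "true_readout_index")
  expect_setequal(ms$effects$stratum, c("low", "high"))
  expect_gt(ms$effects$estimate[ms$effects$stratum == "high"],
            ms$effects$estimate[ms$effects$stratum == "low"])
  # stratum sizes differ at most by median ties
  v <- ex$true_readout_index
  expect_lte(abs(sum(v > median(v)) - sum(v <= median(v))),
             sum(v == median(v)) + 1)
  ex0 <- ex; ex0$true_readout_index <- 1
  expect_error(median_split_priming(ex0, "true_readout_index"), "identical")
})

test_that("zero-vs-high contrast isolates priming to read-out primes", {
  # plant zero-readout primes by zeroing those primes' readout predictor
  cfg <- kp_config(seed = 71, n_perceivers = 8, n_priming_trials = 120)
  pr <- generate_primes(cfg)
  fm <- zscore_features(build_feature_matrix(pr))
  pc <- generate_perceivers(cfg, pr$ground_truth$encoding_direction)
  zero_set <- pr$prime_id[seq(1, 60, by = 6)]
  pc$readout_vectors_orig <- pc$readout_vectors
  pt <- simulate_priming_session(pr, pc, cfg, features = fm)
  pt$true_readout_index[pt$prime_id %in% zero_set] <- 0
  # re-draw RTs for zeroed trials from the no-priming mean (simpler than a
  # bespoke generator branch: identical distributional form)
  sel <- pt$prime_id %in% zero_set
  set.seed(72)
  pt$rt_ms[sel] <- rgamma(sum(sel), cfg$rt_gamma_shape,
                          rate = cfg$rt_gamma_shape / 600)
  ex <- apply_exclusions(pt)$trials
  high_set <- setdiff(pr$prime_id, zero_set)
  zc <- zero_vs_high_readout_contrast(ex, zero_set, high_set)
  expect_gt(zc$effects["high", "estimate"], 0)
  expect_true(zc$effects["zero", "lo"] <= 0 && zc$effects["zero", "hi"] >= 0)
  expect_error(zero_vs_high_readout_contrast(ex, character(0), high_set), "empty")
})

test_that("confidence CLMM links confidence to readout", {
  w <- small_world()
  truth <- as.character(w$primes$intention)
  models <- lapply(split(w$disc, w$disc$perceiver_id), function(d)
    fit_readout(d[, c("perceiver_id", "prime_id", "choice")], w$features))
  idx <- do.call(rbind, lapply(names(models), function(p) {
    s <- single_trial_readout(models[[p]], w$features, truth)
    s$perceiver_id <- p
    s
  }))
  d <- w$disc
  d$readout_index <- idx$value[match(paste(d$perceiver_id, d$prime_id),
                                     paste(idx$perceiver_id, idx$prime_id))]
  cm <- confidence_readout_model(d, "readout_index")
  expect_true(cm$fit$converged)
  expect_gt(cm$coefficient$estimate, 0)
  expect_lt(cm$coefficient$p, 0.05)
  pr_hi <- cm$predicted[, ncol(cm$predicted)]
  expect_true(all(diff(pr_hi) >= -1e-10))
})

test_that("pupil filtering and baseline match first-order behavior", {
  # constant trace -> DC gain exactly 1
  expect_equal(pupil_baseline(rep(4, 1000)), 4)
  # blink gap interpolates linearly between flanking samples
  tr <- seq(0, 1, length.out = 1001)
  gap <- tr; gap[300:400] <- NA
  filled <- approx(seq_along(gap)[-(300:400)], gap[-(300:400)],
                   xout = 300:400, rule = 2)$y
  expect_equal(filled, tr[300:400], tolerance = 1e-12)
  expect_equal(pupil_baseline(gap), pupil_baseline(tr), tolerance = 1e-6)
  expect_true(is.na(pupil_baseline(rep(NA_real_, 100))))
  # white noise: variance reduced; 25 Hz attenuation matches the analog
  # first-order magnitude response within 10%
  set.seed(8)
  x <- rnorm(20000)
  y <- lowpass_first_order(x, 1000, 10)
  expect_lt(var(y), var(x))
  t <- seq_len(20000) / 1000
  s25 <- sin(2 * pi * 25 * t)
  y25 <- lowpass_first_order(s25, 1000, 10)
  gain <- sd(y25[5000:20000]) / sd(s25[5000:20000])
  analog <- 1 / sqrt(1 + (25 / 10)^2)
  expect_lt(abs(gain - analog) / analog, 0.10)
})

test_that("pupil control model leaves the readout interaction intact", {
  pt <- make_priming()
  ex <- apply_exclusions(pt)$trials
  pcm <- pupil_control_model(ex, "true_readout_index")
  expect_lt(pcm$interaction_change, 1)  # pupil independent of priming
  # all-zero pupil: model reduces to the base model
  ex0 <- ex; ex0$baseline_pupil <- 0
  pcm0 <- pupil_control_model(ex0, "true_readout_index")
  b0 <- pcm0$base_fit$coefficients
  b1 <- pcm0$pupil_fit$coefficients
  shared <- intersect(b0$term, b1$term)
  expect_equal(b1$estimate[match(shared, b1$term)],
               b0$estimate[match(shared, b0$term)], tolerance = 1e-4)
})

test_that("Holm adjustment matches the step-down oracle exactly", {
  expect_equal(unname(holm_bonferroni(c(0.01, 0.04))), c(0.02, 0.04))
  expect_equal(unname(holm_bonferroni(0.2)), 0.2)
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    expect_equal(unname(holm_bonferroni(p)), p.adjust(p, method = "holm"))
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("correlation tests behave at the anchors and under the null", {
  x <- rnorm(50)
  expect_equal(correlation_test(x, 2 * x + 1, "pearson")$estimate, 1)
  expect_equal(correlation_test(x, exp(x), "spearman")$estimate, 1)
  expect_error(correlation_test(rep(1, 10), rnorm(10)), "constant")
  expect_error(correlation_test(1:2, 1:2), "n >= 3")
  set.seed(10)
  hits <- mean(vapply(1:60, function(i) {
    abs(correlation_test(rnorm(1000), rnorm(1000), "pearson")$estimate) < 0.08
  }, logical(1)))
  expect_gte(hits, 0.95)
  # agreement with the reference implementation (independent oracle)
  y <- rnorm(50)
  ct <- correlation_test(x, y, "spearman")
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(ct$p_value, ref$p.value)
})
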