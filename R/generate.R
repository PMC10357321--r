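# Synthetic reach-to-pour / reach-to-drink world with known ground truth.
#
# Channels are smooth parametric curves: wrist velocity is a raised-cosine
# bell (movement bounds detectable at 20 mm/s), ramp-like position channels
# are logistic/linear profiles, and all channels carry per-prime smooth
# Gaussian-process variation. Intention differences are injected only in the
# configured effect_profile variables, as offsets that grow toward movement
# end (prospective information accrues late in the reach); the same logistic
# envelope scales the dominant trial-to-trial noise, so the configured
# SD-unit effect sizes are approximately realized on epoch-averaged features.

intention_levels <- function() c("drink", "pour")

# Deterministic base curve per channel at normalized time t in [0,1].
base_curve <- function(v, t) {
  switch(v,
    W_V  = 900 * (1 - cos(2 * pi * t)) / 2,
    W_H  = 50 + 150 * stats::plogis(8 * (t - 0.5)),
    W_HT = -30 + 60 * t,
    G_A  = 20 + 70 * stats::plogis(9 * (t - 0.45)),
    T_X  = 30 + 20 * t,
    T_Y  = 10 + 10 * t,
    T_Z  = 40 - 10 * t,
    I_X  = 60 + 20 * t,
    I_Y  = -10 + 10 * t,
    I_Z  = 50 - 10 * t,
    FP_X = rep(0.20, length(t)),
    FP_Y = rep(0.70, length(t)),
    FP_Z = rep(0.66, length(t)),
    DP_X = rep(0.15, length(t)),
    DP_Y = rep(0.60, length(t)),
    DP_Z = rep(0.75, length(t))
  )
}

effect_envelope <- function(t) stats::plogis(10 * (t - 0.55))

# Mean of the effect envelope over each quarter of normalized time.
epoch_envelope_means <- function(n_epochs = 4) {
  tt <- seq(0, 1, length.out = 2001)
  g <- effect_envelope(tt)
  vapply(seq_len(n_epochs), function(e) {
    sel <- tt >= (e - 1) / n_epochs & tt <= e / n_epochs
    mean(g[sel])
  }, numeric(1))
}

# Nominal ground-truth encoding direction on the z-scored feature scale:
# component (v, e) proportional to the approximate per-feature Cohen's d.
true_encoding_direction <- function(cfg, n_epochs = 4) {
  gbar <- epoch_envelope_means(n_epochs)
  d <- as.numeric(t(outer(cfg$effect_profile, gbar / sqrt(gbar^2 + 0.09))))
  names(d) <- sprintf("%s_e%d", rep(kp_variables(), each = n_epochs),
                      rep(seq_len(n_epochs), 16))
  nrm <- sqrt(sum(d^2))
  if (nrm > 0) d <- d / nrm
  d
}

#' Generate a set of kinematic primes with known ground truth
#'
#' Produces `2 * n_primes_per_intention` trajectories of the 16 canonical
#' channels (plus 0.2 s of sub-threshold padding at each end), with intention
#' differences injected only in the `effect_profile` variables. Ground truth
#' records the unit encoding direction in 64-dimensional feature space.
#'
#' @param config a `kp_config`.
#' @return list of class `kp_primes`: `trajectories`, `prime_id`,
#'   `intention` (factor drink/pour), `ground_truth`.
#' @export
generate_primes <- function(config) {
  validate_kp_config(config)
  cfg <- config
  n2 <- 2L * cfg$n_primes_per_intention
  intent <- factor(rep(intention_levels(), each = cfg$n_primes_per_intention),
                   levels = intention_levels())
  ids <- sprintf("p%03d", seq_len(n2))
  sr <- cfg$sample_rate
  n_pad <- max(2L, round(0.2 * sr))
  vars <- kp_variables()
  trajs <- with_seed(kp_seed(cfg$seed, "primes"), {
    lapply(seq_len(n2), function(i) {
      dur <- stats::runif(1, cfg$duration_range[1], cfg$duration_range[2])
      n_mov <- max(10L, round(dur * sr))
      t <- seq(0, 1, length.out = n_mov)
      env <- effect_envelope(t)
      s_i <- if (intent[i] == "pour") 1 else -1
      ch <- matrix(NA_real_, n_pad + n_mov + n_pad, 16,
                   dimnames = list(NULL, vars))
      for (v in vars) {
        sigma <- cfg$trajectory_noise_sd[[v]]
        d_v <- cfg$effect_profile[[v]]
        e_v <- if (v == "W_V") sin(pi * t) else env
        gp1 <- gp_smooth(n_mov, ell = 0.22 * n_mov)
        gp2 <- gp_smooth(n_mov, ell = 0.15 * n_mov)
        wig_env <- if (v == "W_V") e_v else 1  # keep velocity clean at the bounds
        y <- base_curve(v, t) +
          (d_v * sigma * s_i / 2 + sigma * gp1) * e_v +
          0.3 * sigma * gp2 * wig_env
        if (v == "W_V") {
          y <- pmax(y, 0)
          pad_a <- stats::runif(n_pad, 0, 8)
          pad_b <- stats::runif(n_pad, 0, 8)
        } else {
          pad_a <- rep(y[1], n_pad)
          pad_b <- rep(y[n_mov], n_pad)
        }
        ch[, v] <- c(pad_a, y, pad_b)
      }
      new_trajectory(ch, sr, ids[i])
    })
  })
  gt <- list(
    encoding_direction = true_encoding_direction(cfg),
    effect_profile = cfg$effect_profile,
    epoch_envelope = epoch_envelope_means(),
    intention = stats::setNames(as.character(intent), ids)
  )
  structure(list(trajectories = trajs, prime_id = ids, intention = intent,
                 ground_truth = gt, config = cfg),
            class = "kp_primes")
}

#' Generate per-perceiver ground-truth readout vectors
#'
#' Each perceiver's readout vector is the encoding direction restricted to
#' the readout subspace, perturbed by perceiver-specific noise on those
#' components, and scaled by a gain drawn uniformly from
#' `readout_gain_range` (so a zero gain range yields zero vectors).
#'
#' @param config a `kp_config`.
#' @param encoding_direction named 64-vector (defaults must be supplied from
#'   `kp_primes$ground_truth`).
#' @return list of class `kp_perceivers`: `readout_vectors`
#'   (n_perceivers x 64), `gains`, `perceiver_id`.
#' @export
generate_perceivers <- function(config, encoding_direction) {
  validate_kp_config(config)
  if (length(config$readout_subspace) == 0)
    stop_kp("readout_subspace must not be empty", class = "kp_config_error")
  feats <- names(encoding_direction)
  featvar <- sub("_e[0-9]+$", "", feats)
  sub_idx <- featvar %in% config$readout_subspace
  ids <- sprintf("s%02d", seq_len(config$n_perceivers))
  with_seed(kp_seed(config$seed, "perceivers"), {
    gains <- stats::runif(config$n_perceivers,
                          config$readout_gain_range[1], config$readout_gain_range[2])
    W <- matrix(0, config$n_perceivers, length(feats),
                dimnames = list(ids, feats))
    for (p in seq_len(config$n_perceivers)) {
      w <- rep(0, length(feats))
      w[sub_idx] <- encoding_direction[sub_idx] +
        stats::rnorm(sum(sub_idx), 0, config$readout_noise_sd)
      W[p, ] <- w * gains[p]
    }
    structure(list(readout_vectors = W, gains = stats::setNames(gains, ids),
                   perceiver_id = ids),
              class = "kp_perceivers")
  })
}

# z-scored feature matrix of a prime set (the generator's own pipeline).
prime_feature_matrix <- function(primes, n_epochs = 4) {
  zscore_features(build_feature_matrix(primes, n_epochs = n_epochs))
}

#' Simulate the forced-choice intention discrimination session
#'
#' Each perceiver sees every prime `n_discrimination_reps` times (blocks);
#' the choice is Bernoulli in the sigmoid of the perceiver's readout
#' predictor, mixed toward 0.5 with probability `lapse_rate`; confidence is
#' the ordinal bin of the absolute predictor (plus jitter) by
#' `confidence_thresholds`.
#'
#' @param primes a `kp_primes`.
#' @param perceivers a `kp_perceivers`.
#' @param config a `kp_config`.
#' @param features optional precomputed z-scored `kp_features`.
#' @return data.frame: perceiver_id, prime_id, repetition, choice,
#'   confidence, rt_ms, intention, correct, predictor.
#' @export
simulate_discrimination <- function(primes, perceivers, config, features = NULL) {
  validate_kp_config(config)
  fm <- features %||% prime_feature_matrix(primes)
  Z <- fm$values
  W <- perceivers$readout_vectors
  U <- Z %*% t(W)   # primes x perceivers linear predictors
  y_pour <- primes$intention == "pour"
  nrep <- config$n_discrimination_reps
  with_seed(kp_seed(config$seed, "discrimination"), {
    rows <- list()
    for (p in seq_along(perceivers$perceiver_id)) {
      for (r in seq_len(nrep)) {
        u <- U[, p]
        lapse <- stats::runif(length(u)) < config$lapse_rate
        p_pour <- ifelse(lapse, 0.5, stats::plogis(u))
        choice <- ifelse(stats::runif(length(u)) < p_pour, "pour", "drink")
        conf_raw <- abs(u) + stats::rnorm(length(u), 0, config$confidence_noise_sd)
        confidence <- 1L + findInterval(conf_raw, config$confidence_thresholds)
        rt_mean <- pmax(350, 900 - 25 * pmin(abs(u), 12))
        rt <- stats::rgamma(length(u), shape = config$rt_gamma_shape,
                            rate = config$rt_gamma_shape / rt_mean)
        rows[[length(rows) + 1L]] <- data.frame(
          perceiver_id = perceivers$perceiver_id[p],
          prime_id = primes$prime_id,
          repetition = r,
          choice = choice,
          confidence = confidence,
          rt_ms = rt,
          intention = as.character(primes$intention),
          correct = as.integer(choice == as.character(primes$intention)),
          predictor = u,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate the primed action categorization session
#'
#' Per trial the prime's true readout log-odds for the perceiver,
#' `s = sign(intention) * (w_p . z)`, shifts the identity-link gamma RT mean
#' by `-gain * s` on congruent and `+gain * s` on incongruent trials, and
#' shifts the first-fixation logit by `+/- fixation_priming_gain * s`.
#' Congruency counts respect `congruent_fraction` exactly; baseline pupil is
#' AR(1) noise independent of priming, z-scored within participant.
#'
#' @param primes a `kp_primes`.
#' @param perceivers a `kp_perceivers`.
#' @param config a `kp_config`.
#' @param features optional precomputed z-scored `kp_features`.
#' @return data.frame of priming trials (one row per participant x trial)
#'   with true index columns for parameter recovery.
#' @export
simulate_priming_session <- function(primes, perceivers, config, features = NULL) {
  validate_kp_config(config)
  fm <- features %||% prime_feature_matrix(primes)
  Z <- fm$values
  W <- perceivers$readout_vectors
  U <- Z %*% t(W)
  enc <- primes$ground_truth$encoding_direction
  enc_lp <- as.numeric(Z %*% enc)
  y_sign <- ifelse(primes$intention == "pour", 1, -1)
  n_primes <- length(primes$prime_id)
  n_tr <- config$n_priming_trials
  gamma <- config$rt_priming_gain_ms_per_logodds
  fg <- config$fixation_priming_gain
  with_seed(kp_seed(config$seed, "priming"), {
    b_prime <- stats::rnorm(n_primes, 0, config$rt_prime_sd_ms)
    rows <- list()
    for (p in seq_along(perceivers$perceiver_id)) {
      b_p <- stats::rnorm(1, 0, config$rt_participant_sd_ms)
      b_pf <- stats::rnorm(1, 0, config$fixation_participant_sd)
      reps <- ceiling(n_tr / n_primes)
      prime_seq <- sample(rep(seq_len(n_primes), reps)[seq_len(n_tr)])
      n_cong <- round(config$congruent_fraction * n_tr)
      congruent <- rep(FALSE, n_tr)
      congruent[sample.int(n_tr, n_cong)] <- TRUE
      pi_chr <- as.character(primes$intention[prime_seq])
      probe <- ifelse(congruent, pi_chr,
                      ifelse(pi_chr == "pour", "drink", "pour"))
      probe <- ifelse(probe == "pour", "pouring", "drinking")
      s <- y_sign[prime_seq] * U[cbind(prime_seq, rep(p, n_tr))]
      te <- y_sign[prime_seq] * enc_lp[prime_seq]
      mu <- config$rt_base_ms + b_p + b_prime[prime_seq] +
        0.5 * config$rt_probe_effect_ms * ifelse(probe == "pouring", 1, -1) +
        ifelse(congruent, -gamma * s, gamma * s)
      if (any(mu <= 0))
        stop_kp("mean RT <= 0 for some trial; choose gains/base to avoid",
                class = "kp_generation_error")
      rt <- stats::rgamma(n_tr, shape = config$rt_gamma_shape,
                          rate = config$rt_gamma_shape / mu)
      acc <- stats::rbinom(n_tr, 1, 1 - config$error_rate)
      fix_lp <- config$fixation_base_logit + b_pf +
        fg * s * ifelse(congruent, 1, -1)
      relevant <- stats::rbinom(n_tr, 1, stats::plogis(fix_lp)) == 1
      none <- stats::runif(n_tr) < config$fixation_none_rate
      other_cls <- ifelse(stats::runif(n_tr) < 0.35,
                          "relevant-nondisplayed", "other")
      fix_cls <- ifelse(none, "none",
                        ifelse(relevant, "relevant-displayed", other_cls))
      eps <- stats::rnorm(n_tr)
      pup <- as.numeric(stats::filter(eps * sqrt(1 - config$pupil_ar1^2),
                                      config$pupil_ar1, method = "recursive"))
      pup <- (pup - mean(pup)) / stats::sd(pup)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = perceivers$perceiver_id[p],
        prime_id = primes$prime_id[prime_seq],
        prime_intention = pi_chr,
        probe = probe,
        congruency = ifelse(congruent, "congruent", "incongruent"),
        rt_ms = rt,
        accuracy = acc,
        first_fixation_class = fix_cls,
        baseline_pupil = pup,
        block = as.integer(cut(seq_len(n_tr), 3, labels = FALSE)),
        true_readout_index = s,
        true_encoding_index = te,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "true_priming_gain") <- gamma
    attr(out, "true_fixation_gain") <- fg
    out
  })
}
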