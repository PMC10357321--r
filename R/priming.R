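# Trial-level statistical analyses of the primed action categorization
# task: exclusion rules, congruency-by-information mixed models, median
# splits, zero-vs-high readout contrasts, confidence models, pupil-baseline
# control, Holm correction, and correlation tests.

#' Apply the trial exclusion rules
#'
#' In order: (1) incorrectly categorized trials are removed; (2) trials with
#' RT above the participant's mean + 2.5 SD (computed on that participant's
#' correct trials) are removed; (3) for fixation analyses only, trials with
#' no initial fixation on the probe are removed. Participants with fewer
#' than 2 correct trials have an undefined SD and are flagged, not silently
#' dropped.
#'
#' @param trials priming-trial data.frame (`participant_id`, `rt_ms`,
#'   `accuracy`, `first_fixation_class`).
#' @param for_fixation apply rule (3)?
#' @param sd_mult RT exclusion multiplier (default 2.5).
#' @return list with `trials` (retained) and `report` (counts and fractions
#'   per rule, flagged participants).
#' @export
apply_exclusions <- function(trials, for_fixation = FALSE, sd_mult = 2.5) {
  n0 <- nrow(trials)
  keep1 <- trials$accuracy == 1
  t1 <- trials[keep1, , drop = FALSE]
  stats_p <- tapply(t1$rt_ms, t1$participant_id, function(r) {
    c(n = length(r), mean = mean(r), sd = if (length(r) >= 2) stats::sd(r) else NA_real_)
  })
  flagged <- names(stats_p)[vapply(stats_p, function(s) is.na(s["sd"]), logical(1))]
  thr <- vapply(stats_p, function(s) s[["mean"]] + sd_mult * s[["sd"]], numeric(1))
  keep2 <- t1$rt_ms <= thr[t1$participant_id] | is.na(thr[t1$participant_id])
  t2 <- t1[keep2, , drop = FALSE]
  n_fix <- 0L
  t3 <- t2
  if (for_fixation) {
    keep3 <- t2$first_fixation_class != "none"
    n_fix <- sum(!keep3)
    t3 <- t2[keep3, , drop = FALSE]
  }
  report <- list(
    n_input = n0,
    n_incorrect = sum(!keep1),
    n_rt_excluded = sum(!keep2),
    n_no_fixation = n_fix,
    n_retained = nrow(t3),
    frac_incorrect = sum(!keep1) / n0,
    frac_rt_excluded = sum(!keep2) / max(nrow(t1), 1),
    flagged_participants = flagged
  )
  list(trials = t3, report = report)
}

#' Classify the first fixation on the action probe
#'
#' The probe image is split into four equal quadrants. The task-relevant
#' quadrant is top-right for the drinking probe (mouth-bottle interaction)
#' and bottom-left for the pouring probe (bottle-glass interaction). A
#' fixation in the displayed probe's relevant quadrant is
#' "relevant-displayed", in the other probe's relevant quadrant
#' "relevant-nondisplayed", elsewhere "other", and outside the image "none".
#' Boundary convention: the vertical midline belongs to the right quadrants
#' and the horizontal midline to the top quadrants (screen coordinates,
#' origin top-left, y growing downward), so the exact centre is top-right.
#'
#' @param x,y fixation coordinates in image pixels.
#' @param probe "drinking" or "pouring" (displayed probe), recycled.
#' @param image_width,image_height image size in pixels.
#' @return character vector of fixation classes.
#' @export
classify_first_fixation <- function(x, y, probe,
                                    image_width = 1920, image_height = 1080) {
  probe <- rep_len(as.character(probe), length(x))
  inside <- x >= 0 & x <= image_width & y >= 0 & y <= image_height
  right <- x >= image_width / 2
  top <- y <= image_height / 2
  quadrant <- ifelse(top & right, "top-right",
              ifelse(top & !right, "top-left",
              ifelse(!top & !right, "bottom-left", "bottom-right")))
  relevant_of <- c(drinking = "top-right", pouring = "bottom-left")
  displayed_rel <- relevant_of[probe]
  other_rel <- ifelse(probe == "drinking", relevant_of[["pouring"]],
                      relevant_of[["drinking"]])
  out <- ifelse(!inside, "none",
         ifelse(quadrant == displayed_rel, "relevant-displayed",
         ifelse(quadrant == other_rel, "relevant-nondisplayed", "other")))
  unname(out)
}

slope_contrast <- function(fit, index, level_sign) {
  cf <- fit$coefficients
  i_main <- which(cf$term == index)
  i_int <- which(cf$term %in% c(paste0("congruency1:", index),
                                paste0(index, ":congruency1")))
  a <- rep(0, nrow(cf))
  a[i_main] <- 1
  a[i_int] <- level_sign
  est <- sum(a * cf$estimate)
  se <- sqrt(as.numeric(t(a) %*% fit$vcov %*% a))
  c(estimate = est, se = se)
}

#' Congruency-by-information mixed model
#'
#' Fits response ~ probe x congruency x index with the given random effects
#' (gamma-identity for RTs; binomial-logit for the relevant-displayed
#' first-fixation indicator), tests the congruency-by-index interaction and
#' the three-way term by LRT, and reports the congruent/incongruent slopes
#' of the response on the index. For fixations it additionally computes
#' marginal predicted probabilities (random effects at zero, probe averaged
#' out) and a Wald test of the equality of the marginal index effects across
#' congruency on the probability scale.
#'
#' @param trials retained priming trials.
#' @param index name of the per-trial information index column (encoding or
#'   readout).
#' @param response "rt" or "fixation".
#' @param random random-effect terms.
#' @return list with `fit` (two-way model), `fit_three_way`,
#'   `lrt_interaction` (congruency x index), `lrt_three_way`, `slopes`, and
#'   for fixations `marginal` (probability-scale interaction test).
#' @export
congruency_information_model <- function(trials, index, response = c("rt", "fixation"),
                                         random = c("(1 | participant_id)",
                                                    "(1 | prime_id)")) {
  response <- match.arg(response)
  if (!index %in% names(trials))
    stop_kp("index column missing from trials: ", index, class = "kp_join_error")
  if (anyNA(trials[[index]]))
    stop_kp("index missing for retained trials", class = "kp_join_error")
  if (response == "rt") {
    resp <- "rt_ms"; fam <- "gamma-identity"
  } else {
    trials$fix_relevant <- as.integer(trials$first_fixation_class == "relevant-displayed")
    resp <- "fix_relevant"; fam <- "binomial-logit"
  }
  f3 <- sprintf("probe * congruency * %s", index)
  f2 <- sprintf("probe + congruency + %s + probe:congruency + probe:%s + congruency:%s",
                index, index, index)
  f2r <- sprintf("probe + congruency + %s + probe:congruency + probe:%s",
                 index, index)
  m3 <- fit_mixed(kp_model_spec(resp, fam, f3, random), trials)
  m2 <- fit_mixed(kp_model_spec(resp, fam, f2, random), trials)
  m2r <- fit_mixed(kp_model_spec(resp, fam, f2r, random), trials)
  out <- list(
    fit = m2, fit_three_way = m3,
    lrt_interaction = lrt(m2, m2r),
    lrt_three_way = lrt(m3, m2),
    slopes = rbind(congruent = slope_contrast(m2, index, +1),
                   incongruent = slope_contrast(m2, index, -1))
  )
  if (response == "fixation") {
    qs <- stats::quantile(trials[[index]], c(0.25, 0.75), names = FALSE)
    grid <- expand.grid(congruency = c("congruent", "incongruent"),
                        probe = unique(trials$probe),
                        stringsAsFactors = FALSE)
    rows <- list(); w <- numeric(0)
    for (i in seq_len(nrow(grid))) {
      sgn <- if (grid$congruency[i] == "congruent") 1 else -1
      half <- 1 / length(unique(trials$probe))
      hi <- grid[i, ]; hi[[index]] <- qs[2]
      lo <- grid[i, ]; lo[[index]] <- qs[1]
      rows <- c(rows, list(hi, lo))
      w <- c(w, sgn * half, -sgn * half)
    }
    out$marginal <- wald_marginal_contrast(m2, rows, w)
  }
  out
}

#' Median-split priming effects
#'
#' Splits retained trials at the median of the information index (computed
#' across all trials and participants; ties go to the low stratum), fits a
#' gamma-identity mixed model with probe as covariate within each stratum to
#' estimate the priming effect (mean RT incongruent - congruent), and tests
#' the stratum difference via the congruency-by-stratum interaction LRT.
#' The reported p values are Holm-corrected together.
#'
#' @param trials retained priming trials.
#' @param index per-trial information index column name.
#' @param random random-effect terms.
#' @return list with `effects` (stratum, estimate ms, se, p, p_holm),
#'   `difference` (LRT) and the stratum fits.
#' @export
median_split_priming <- function(trials, index,
                                 random = c("(1 | participant_id)",
                                            "(1 | prime_id)")) {
  v <- trials[[index]]
  if (length(unique(v)) < 2)
    stop_kp("all index values identical: median split undefined",
            class = "kp_input_error")
  med <- stats::median(v)
  trials$stratum <- factor(ifelse(v > med, "high", "low"), levels = c("low", "high"))
  fits <- lapply(split(trials, trials$stratum), function(tt) {
    fit_mixed(kp_model_spec("rt_ms", "gamma-identity", "congruency + probe", random), tt)
  })
  eff <- t(vapply(fits, function(f) {
    cf <- f$coefficients
    i <- which(cf$term == "congruency1")
    est <- -2 * cf$estimate[i]   # incongruent - congruent under sum contrasts
    se <- 2 * cf$se[i]
    c(estimate = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
  }, numeric(3)))
  full <- fit_mixed(kp_model_spec("rt_ms", "gamma-identity",
                                  "congruency * stratum + probe", random), trials)
  red <- fit_mixed(kp_model_spec("rt_ms", "gamma-identity",
                                 "congruency + stratum + probe", random), trials)
  diff_test <- lrt(full, red)
  p_all <- holm_bonferroni(c(eff[, "p"], difference = diff_test$p_value))
  list(
    effects = data.frame(stratum = rownames(eff), estimate = eff[, "estimate"],
                         se = eff[, "se"], p = eff[, "p"],
                         p_holm = p_all[seq_len(nrow(eff))],
                         row.names = NULL, stringsAsFactors = FALSE),
    difference = c(diff_test, list(p_holm = unname(p_all[length(p_all)]))),
    fits = fits
  )
}

#' Priming contrast between zero-readout and high-readout primes
#'
#' Gamma-identity mixed model of RT with congruency and readout level
#' (zero vs high) as sum-contrast categorical predictors plus probe; reports
#' the within-level priming effects (with 95% CI) and the level contrast.
#'
#' @param trials retained priming trials.
#' @param zero_primes,high_primes prime id character vectors.
#' @param random random-effect terms.
#' @return list with `effects` per level, `interaction` LRT, `fit`.
#' @export
zero_vs_high_readout_contrast <- function(trials, zero_primes, high_primes,
                                          random = c("(1 | participant_id)",
                                                     "(1 | prime_id)")) {
  if (length(zero_primes) == 0 || length(high_primes) == 0)
    stop_kp("empty readout stratum", class = "kp_input_error")
  tt <- trials[trials$prime_id %in% c(zero_primes, high_primes), , drop = FALSE]
  tt$readout_level <- factor(ifelse(tt$prime_id %in% zero_primes, "zero", "high"),
                             levels = c("zero", "high"))
  if (any(table(tt$readout_level) == 0))
    stop_kp("empty readout stratum", class = "kp_input_error")
  full <- fit_mixed(kp_model_spec("rt_ms", "gamma-identity",
                                  "congruency * readout_level + probe", random), tt)
  red <- fit_mixed(kp_model_spec("rt_ms", "gamma-identity",
                                 "congruency + readout_level + probe", random), tt)
  cf <- full$coefficients
  ic <- which(cf$term == "congruency1")
  ii <- which(cf$term %in% c("congruency1:readout_level1", "readout_level1:congruency1"))
  eff_level <- function(lsgn) {
    a <- rep(0, nrow(cf)); a[ic] <- -2; a[ii] <- -2 * lsgn
    est <- sum(a * cf$estimate)
    se <- sqrt(as.numeric(t(a) %*% full$vcov %*% a))
    c(estimate = est, se = se, lo = est - 1.96 * se, hi = est + 1.96 * se)
  }
  list(
    effects = rbind(zero = eff_level(+1), high = eff_level(-1)),
    interaction = lrt(full, red),
    fit = full
  )
}

#' Cumulative-link mixed model of confidence on an information index
#'
#' Collapses confidence ratings 1 and 2, fits the in-package CLMM with a
#' perceiver random intercept, and returns predicted category probabilities
#' across the index range.
#'
#' @param trials discrimination trials with `confidence` and the index column.
#' @param index index column name (readout, or encoding as control).
#' @param group random-intercept grouping column (default `perceiver_id`).
#' @return list with `fit`, `coefficient` row for the index, and
#'   `predicted` (index grid x category probabilities).
#' @export
confidence_readout_model <- function(trials, index, group = "perceiver_id") {
  if (!index %in% names(trials))
    stop_kp("index column missing: ", index, class = "kp_join_error")
  spec <- kp_model_spec("confidence", "cumulative-logit", index,
                        sprintf("(1 | %s)", group))
  fit <- fit_mixed(spec, trials)
  grid <- data.frame(seq(stats::quantile(trials[[index]], 0.05),
                         stats::quantile(trials[[index]], 0.95),
                         length.out = 9))
  names(grid) <- index
  list(fit = fit,
       coefficient = fit$coefficients[fit$coefficients$term == index, ],
       predicted = cbind(grid, predict_clmm_probs(fit, grid)))
}

#' First-order low-pass filter
#'
#' Single-pole IIR approximation of a first-order analog low-pass,
#' `y[n] = y[n-1] + a (x[n] - y[n-1])` with `a = dt / (RC + dt)`,
#' `RC = 1 / (2 pi cutoff)`; DC gain is exactly 1.
#'
#' @param x signal.
#' @param sample_rate Hz.
#' @param cutoff_hz -3 dB cutoff (default 10).
#' @return filtered signal, same length.
#' @export
lowpass_first_order <- function(x, sample_rate, cutoff_hz = 10) {
  dt <- 1 / sample_rate
  rc <- 1 / (2 * pi * cutoff_hz)
  a <- dt / (rc + dt)
  as.numeric(stats::filter(a * x, 1 - a, method = "recursive", init = x[1]))
}

#' Baseline pupil value over a pre-stimulus window
#'
#' Blink gaps (NAs) are linearly interpolated between flanking samples, the
#' trace is smoothed with a first-order 10 Hz low-pass filter, and the mean
#' over the window is returned. A fully missing window yields `NA`
#' (the trial is flagged, not imputed).
#'
#' @param trace pupil diameter samples over the 1-s window (NA = blink).
#' @param sample_rate Hz (default 1000).
#' @param cutoff_hz low-pass cutoff (default 10).
#' @return baseline value (mean of the filtered trace), or NA.
#' @export
pupil_baseline <- function(trace, sample_rate = 1000, cutoff_hz = 10) {
  if (all(is.na(trace))) return(NA_real_)
  if (anyNA(trace)) {
    idx <- seq_along(trace)
    trace <- stats::approx(idx[!is.na(trace)], trace[!is.na(trace)],
                           xout = idx, rule = 2)$y
  }
  mean(lowpass_first_order(trace, sample_rate, cutoff_hz))
}

#' Z-score values within groups (e.g. pupil baselines within participant)
#'
#' @param values numeric vector.
#' @param group grouping vector.
#' @return z-scored values.
#' @export
zscore_within <- function(values, group) {
  stats::ave(values, group, FUN = function(v) (v - mean(v)) / stats::sd(v))
}

#' Pupil-baseline control model for the readout-by-congruency effect
#'
#' Extends the RT model with baseline pupil (z-scored within participant)
#' and all two- and three-way products with congruency and the index;
#' reports whether the congruency-by-index interaction survives inclusion.
#'
#' @param trials retained priming trials with `baseline_pupil`.
#' @param index information index column name.
#' @param random random-effect terms.
#' @return list with `base_fit`, `pupil_fit`, and `interaction_change`
#'   (difference of the congruency-by-index coefficient in units of its
#'   base-model SE).
#' @export
pupil_control_model <- function(trials, index,
                                random = c("(1 | participant_id)",
                                           "(1 | prime_id)")) {
  f_base <- sprintf("probe + congruency * %s", index)
  f_pup <- sprintf("probe + congruency * %s * baseline_pupil", index)
  base <- fit_mixed(kp_model_spec("rt_ms", "gamma-identity", f_base, random), trials)
  pup <- fit_mixed(kp_model_spec("rt_ms", "gamma-identity", f_pup, random), trials)
  term <- c(paste0("congruency1:", index), paste0(index, ":congruency1"))
  b0 <- base$coefficients[base$coefficients$term %in% term, ]
  b1 <- pup$coefficients[pup$coefficients$term %in% term, ]
  list(base_fit = base, pupil_fit = pup,
       interaction_change = abs(b1$estimate[1] - b0$estimate[1]) / b0$se[1])
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param pvalues p values in \[0, 1\]; names and order preserved.
#' @return adjusted p values.
#' @export
holm_bonferroni <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_kp("p values must lie in [0, 1]", class = "kp_param_error")
  m <- length(pvalues)
  o <- order(pvalues)
  adj <- pmin(cummax((m - seq_len(m) + 1) * pvalues[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  names(out) <- names(pvalues)
  out
}

#' Correlation test (Pearson t / Spearman asymptotic t)
#'
#' Pearson p via Student t with n - 2 df; Spearman p via the asymptotic t
#' approximation on rho. Constant inputs are an error, not an NA.
#'
#' @param x,y numeric vectors (n >= 3).
#' @param method "pearson" or "spearman".
#' @return list with `estimate`, `p_value`, `method`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) < 3 || length(x) != length(y))
    stop_kp("need paired vectors with n >= 3", class = "kp_input_error")
  if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15)
    stop_kp("constant input: correlation undefined", class = "kp_input_error")
  ct <- if (method == "pearson") stats::cor.test(x, y)
        else suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, method = method)
}
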