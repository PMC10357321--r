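# Raw kinematics -> 64-dimensional single-trial feature vectors.

#' Detect movement onset and offset from wrist velocity
#'
#' Onset is the first sample at which velocity exceeds the threshold; offset
#' is the first sample after onset at which velocity falls back below it
#' (first drop, even for multi-peaked profiles; smooth upstream if needed).
#' Indices are 1-based.
#'
#' @param velocity non-negative wrist speed time series (mm/s).
#' @param threshold detection threshold in mm/s (default 20).
#' @return list of class `kp_bounds` with `onset`, `offset`, `threshold`.
#' @export
detect_movement_bounds <- function(velocity, threshold = 20) {
  if (any(!is.finite(velocity))) stop_kp("velocity must be finite", class = "kp_input_error")
  if (any(velocity < 0)) stop_kp("velocity must be non-negative", class = "kp_input_error")
  above <- which(velocity > threshold)
  if (length(above) == 0) stop_kp("no movement detected", class = "kp_bounds_error")
  onset <- above[1]
  below <- which(velocity < threshold)
  below <- below[below > onset]
  if (length(below) == 0) stop_kp("no offset detected", class = "kp_bounds_error")
  structure(list(onset = onset, offset = below[1], threshold = threshold),
            class = "kp_bounds")
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop_kp("undefined normal: degenerate (collinear) plane points",
                         class = "kp_degenerate_error")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Compute the 16 kinematic variables from 3-D marker trajectories
#'
#' Global-frame variables: wrist velocity (norm of the finite-difference
#' wrist displacement times the sample rate), wrist height (z), wrist
#' horizontal trajectory (x), grip aperture (thumb-tip to index-tip
#' distance). Local-frame variables use a hand-centred frame with origin at
#' the wrist marker, x-axis along radius->phalanx, z-axis normal to the
#' radius-phalanx-dorsum plane, y completing the right-handed triad; thumb
#' and index coordinates are expressed in this frame, and the finger-plane
#' (thumb-index) and dorsum-plane (radius-phalanx) unit normals are reported
#' componentwise in it. The frame convention is a documented stand-in where
#' the hand-local frame is otherwise underdetermined.
#'
#' @param markers named list of n x 3 matrices: `wrist`, `thumb_tip`,
#'   `index_tip`, `radius`, `phalanx`, `dorsum`.
#' @param sample_rate Hz.
#' @param prime_id identifier carried on the output.
#' @return list of class `kp_trajectory` with `channels` (n x 16 matrix with
#'   canonical column names), `sample_rate`, `prime_id`.
#' @export
compute_kinematic_variables <- function(markers, sample_rate, prime_id = "trial") {
  need <- c("wrist", "thumb_tip", "index_tip", "radius", "phalanx", "dorsum")
  missing <- setdiff(need, names(markers))
  if (length(missing))
    stop_kp("missing marker(s): ", paste(missing, collapse = ", "),
            class = "kp_schema_error")
  n <- nrow(markers$wrist)
  if (n < 2) stop_kp("need at least 2 samples", class = "kp_input_error")
  for (m in need) {
    if (!is.matrix(markers[[m]]) || ncol(markers[[m]]) != 3 || nrow(markers[[m]]) != n)
      stop_kp("marker ", m, " must be an n x 3 matrix", class = "kp_schema_error")
  }
  w <- markers$wrist
  dw <- diff(w)
  wv <- sqrt(rowSums(dw^2)) * sample_rate
  wv <- c(wv, wv[length(wv)])
  ga <- sqrt(rowSums((markers$thumb_tip - markers$index_tip)^2))

  out <- matrix(NA_real_, n, 16, dimnames = list(NULL, kp_variables()))
  out[, "W_V"] <- wv
  out[, "W_H"] <- w[, 3]
  out[, "W_HT"] <- w[, 1]
  out[, "G_A"] <- ga
  for (i in seq_len(n)) {
    ax <- unit_vec(markers$phalanx[i, ] - markers$radius[i, ])
    nz <- unit_vec(cross3(ax, markers$dorsum[i, ] - markers$radius[i, ]))
    ay <- cross3(nz, ax)
    R <- rbind(ax, ay, nz)   # rows = local axes in global coords
    tl <- as.numeric(R %*% (markers$thumb_tip[i, ] - w[i, ]))
    il <- as.numeric(R %*% (markers$index_tip[i, ] - w[i, ]))
    fp <- unit_vec(cross3(markers$thumb_tip[i, ] - w[i, ],
                          markers$index_tip[i, ] - w[i, ]))
    dp <- unit_vec(cross3(markers$phalanx[i, ] - markers$radius[i, ],
                          markers$dorsum[i, ] - markers$radius[i, ]))
    out[i, c("T_X", "T_Y", "T_Z")] <- tl
    out[i, c("I_X", "I_Y", "I_Z")] <- il
    out[i, c("FP_X", "FP_Y", "FP_Z")] <- as.numeric(R %*% fp)
    out[i, c("DP_X", "DP_Y", "DP_Z")] <- as.numeric(R %*% dp)
  }
  new_trajectory(out, sample_rate, prime_id)
}

new_trajectory <- function(channels, sample_rate, prime_id) {
  stopifnot(is.matrix(channels), ncol(channels) == 16)
  if (nrow(channels) < 10)
    stop_kp("trajectory needs >= 10 samples", class = "kp_input_error")
  colnames(channels) <- kp_variables()
  structure(list(prime_id = prime_id, sample_rate = sample_rate,
                 channels = channels),
            class = "kp_trajectory")
}

#' Average each kinematic channel over epochs of normalized movement time
#'
#' Movement time between onset and offset is rescaled to \[0, 1\], each
#' channel linearly interpolated at 101 evenly spaced points, and averaged
#' over `n_epochs` equal intervals (half-open, last closed) by trapezoidal
#' quadrature, which is exact for linear segments.
#'
#' @param trajectory a `kp_trajectory`.
#' @param bounds a `kp_bounds` (defaults to detecting on the W_V channel).
#' @param n_epochs number of epochs (default 4).
#' @return named numeric vector of length `16 * n_epochs`, labels
#'   `<variable>_e<epoch>` in canonical order, with attribute `prime_id`.
#' @export
epoch_average <- function(trajectory, bounds = NULL, n_epochs = 4) {
  if (n_epochs < 1) stop_kp("n_epochs must be >= 1", class = "kp_param_error")
  if (is.null(bounds))
    bounds <- detect_movement_bounds(trajectory$channels[, "W_V"])
  if (bounds$onset >= bounds$offset)
    stop_kp("invalid bounds: onset must precede offset", class = "kp_param_error")
  idx <- bounds$onset:bounds$offset
  if (length(idx) < n_epochs)
    stop_kp("more epochs than movement samples", class = "kp_param_error")
  u_obs <- seq(0, 1, length.out = length(idx))
  u_fine <- seq(0, 1, length.out = 101)
  vars <- kp_variables()
  out <- numeric(16 * n_epochs)
  labs <- character(16 * n_epochs)
  k <- 1L
  for (v in vars) {
    y <- stats::approx(u_obs, trajectory$channels[idx, v], xout = u_fine)$y
    for (e in seq_len(n_epochs)) {
      a <- (e - 1) / n_epochs; b <- e / n_epochs
      sub <- stats::approx(u_fine, y, xout = seq(a, b, length.out = 26))$y
      out[k] <- trapz_mean(sub)
      labs[k] <- sprintf("%s_e%d", v, e)
      k <- k + 1L
    }
  }
  # reorder to canonical (variable-major is already canonical)
  names(out) <- labs
  attr(out, "prime_id") <- trajectory$prime_id
  out
}

#' Assemble a feature matrix from a set of primes
#'
#' @param primes a `kp_primes` object (or list of `kp_trajectory`).
#' @param n_epochs epochs per variable (default 4).
#' @param threshold movement-bound velocity threshold, mm/s.
#' @return a `kp_features` object: trials x (16 * n_epochs) matrix plus label
#'   metadata; not yet standardized.
#' @export
build_feature_matrix <- function(primes, n_epochs = 4, threshold = 20) {
  trajs <- if (inherits(primes, "kp_primes")) primes$trajectories else primes
  rows <- lapply(trajs, function(tr) {
    b <- detect_movement_bounds(tr$channels[, "W_V"], threshold)
    epoch_average(tr, b, n_epochs)
  })
  values <- do.call(rbind, rows)
  rownames(values) <- vapply(trajs, function(tr) tr$prime_id, character(1))
  labels <- data.frame(
    feature = colnames(values),
    variable = rep(kp_variables(), each = n_epochs),
    epoch = rep(seq_len(n_epochs), times = 16),
    stringsAsFactors = FALSE
  )
  structure(list(values = values, labels = labels, zscored = FALSE,
                 center = NULL, scale = NULL),
            class = "kp_features")
}

#' Z-score a feature matrix (sample SD), storing the standardization
#'
#' When `ref` is supplied, its stored training mean/SD are applied instead of
#' statistics of `features` itself, so held-out trials are transformed with
#' training parameters only.
#'
#' @param features a `kp_features`.
#' @param ref optional z-scored `kp_features` carrying training parameters.
#' @return standardized `kp_features` with `center`/`scale` recorded.
#' @export
zscore_features <- function(features, ref = NULL) {
  stopifnot(inherits(features, "kp_features"))
  x <- features$values
  if (is.null(ref)) {
    if (nrow(x) < 2) stop_kp("need >= 2 trials to standardize", class = "kp_input_error")
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    bad <- which(scl < 1e-12)
    if (length(bad))
      stop_kp("zero-variance feature: ", paste(colnames(x)[bad], collapse = ", "),
              class = "kp_zero_variance_error")
  } else {
    stopifnot(inherits(ref, "kp_features"), isTRUE(ref$zscored))
    ctr <- ref$center; scl <- ref$scale
  }
  features$values <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  features$center <- ctr
  features$scale <- scl
  features$zscored <- TRUE
  features
}

# Standardize raw numeric features with a model's stored parameters.
apply_standardization <- function(x, center, scale) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  sweep(sweep(x, 2, center), 2, scale, "/")
}
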