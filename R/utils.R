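# Internal numerical and reproducibility helpers.

#' Derive a deterministic substream seed from a global seed and a stage name
#'
#' All randomness in the package flows from one global seed through named
#' substreams, so that changing one stage's stream leaves the others untouched.
#'
#' @param seed integer global seed.
#' @param stream character stage name.
#' @return integer seed below 2^31.
#' @export
kp_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes) * 7919)
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 10007 + h) %% 2147483647)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Gauss-Hermite nodes/weights (physicists' convention: integral of
# f(x) exp(-x^2)) via the Golub-Welsch eigenvalue method.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = (e$vectors[1, idx]^2) * sqrt(pi))
}

# Smooth zero-mean unit-SD Gaussian process on n samples, built by Gaussian
# kernel smoothing of white noise; `ell` is the kernel SD in samples.
gp_smooth <- function(n, ell) {
  m <- ceiling(3 * ell)
  z <- stats::rnorm(n + 2 * m)
  k <- stats::dnorm(seq(-m, m), sd = ell)
  k <- k / sum(k)
  s <- stats::filter(z, k, sides = 2)
  s <- s[(m + 1):(m + n)]
  s <- s - mean(s)
  sdv <- stats::sd(s)
  if (sdv < 1e-12) return(rep(0, n))
  s / sdv
}

# Trapezoidal mean of y over its (implicitly uniform) grid.
trapz_mean <- function(y) {
  n <- length(y)
  if (n == 1L) return(y)
  (sum(y) - (y[1] + y[n]) / 2) / (n - 1)
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) return(NA_real_)
  sum(a * b) / (na * nb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kp <- function(..., class) {
  stop(structure(class = c(class, "kp_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
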