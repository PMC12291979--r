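# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic operations in the package go
# through this so a seed argument fully determines their output without
# disturbing the session RNG.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct child seed from a master seed and a stage label,
# keeping the result inside the 32-bit integer range.
childSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves away from zero, the
#' convention used for printed percentage tables (base `round()` rounds
#' halves to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Gaussian smoothing of a vector (reflective edges). sigma in cells;
# kernel truncated at 3*sigma and clamped to the vector length.
gaussSmooth1d <- function(v, sigma) {
  n <- length(v)
  r <- min(max(1L, ceiling(3 * sigma)), n - 1L)
  if (r < 1L) return(v)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  vp <- c(rev(v[seq_len(r)]), v, rev(v[n - seq_len(r) + 1L]))
  as.numeric(stats::filter(vp, k, sides = 2)[(r + 1):(r + n)])
}

# Separable Gaussian smoothing of a matrix.
gaussSmooth <- function(m, sigma) {
  out <- apply(m, 2, gaussSmooth1d, sigma = sigma)
  t(apply(t(out), 2, gaussSmooth1d, sigma = sigma))
}

# z-score a vector ignoring NA; constant vectors map to 0.
zscore <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  sd <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(sd) || sd == 0) return(ifelse(is.na(x), NA_real_, 0))
  (x - mu) / sd
}

invLogit <- function(x) 1 / (1 + exp(-x))
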