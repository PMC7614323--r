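# Internal helpers shared across modules.

# Scalar finite-number check used by all constructors.
check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  ok <- if (strict) x > lower else x >= lower
  if (!ok)
    stop(sprintf("`%s` must be %s %s", name, if (strict) ">" else ">=", lower),
         call. = FALSE)
  invisible(x)
}

# Wrap angles into [0, 2*pi).
wrap_2pi <- function(theta) {
  out <- theta %% (2 * pi)
  # guard against 2*pi itself from floating point
  out[out >= 2 * pi] <- 0
  out
}

# Shortest circular distance between two angles (radians).
circ_dist <- function(a, b) {
  d <- abs(wrap_2pi(a) - wrap_2pi(b))
  pmin(d, 2 * pi - d)
}

#' Derive a reproducible per-cell seed for sweep grids
#'
#' Mixes a base seed with grid indices (natural-frequency index, amplitude
#' index, repeat index) through a Lehmer-style multiplicative congruential
#' step so that refining or reordering a sweep grid does not shift the random
#' streams of existing cells. The result is always in `[1, 2^31 - 2]`.
#'
#' @param base_seed integer base seed of the sweep.
#' @param i,j,r integer indices (natural frequency, amplitude, repeat).
#' @return a single integer seed.
#' @export
#' @examples
#' cell_seed(1, 3, 2, 1)
cell_seed <- function(base_seed, i, j = 1L, r = 1L) {
  m <- 2147483629 # prime < 2^31
  a <- 48271
  s <- (as.numeric(base_seed) %% m + m) %% m
  for (k in c(i, j, r)) {
    s <- (s * a + as.numeric(k) + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

# gcd for candidate-ratio construction
gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
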