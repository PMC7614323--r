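#' Rotation number of an unwrapped phase sequence
#'
#' The average number of oscillator cycles per stimulation pulse,
#' \deqn{R = \frac{\phi_N - \phi_0}{2\pi N},}
#' computed from phases sampled immediately before each pulse (circle-map
#' trajectory, or the order-parameter phase of a population). A rational
#' R = p/q indicates p:q frequency locking. Phases must be unwrapped; input
#' that looks wrapped (all values inside one turn with large negative jumps)
#' is rejected.
#'
#' @param phases a `phase_trajectory`, or a numeric vector of unwrapped
#'   phases (radians) sampled at pulse times.
#' @return the rotation number (cycles per pulse).
#' @export
#' @examples
#' rotation_number(2 * pi * 0.5 * (0:100)) # 0.5
rotation_number <- function(phases) {
  if (inherits(phases, "phase_trajectory")) phases <- phases$phases
  if (!is.numeric(phases) || length(phases) < 2 || anyNA(phases))
    stop("`phases` must be a numeric vector of length >= 2")
  n <- length(phases) - 1L
  d <- diff(phases)
  # wrapped input heuristic: a long forward-rotating trajectory confined to
  # one turn yet stepping backwards can only come from modulo reduction
  if (max(phases) - min(phases) < 2 * pi && n > 10 && any(d < -1e-9))
    stop("`phases` appear to be wrapped (modulo 2*pi); ",
         "rotation numbers need unwrapped phases")
  (phases[n + 1L] - phases[1L]) / (2 * pi * n)
}

#' Detection configuration for frequency-locking plateaux
#'
#' Tolerances of the plateau criterion: a natural-frequency bin is labelled
#' p:q entrained when `|R - p/q| < tol` and the LOWESS-smoothed derivative
#' of R along f0 satisfies `|S(dR/df0)| < tol_prime`. Defaults are the
#' circle-map values (`tol = 6e-4`, `tol_prime = 1e-2`); population sweeps
#' use `tol = 3e-2`, `tol_prime = 2e-2` (see [kuramoto_detection()]). The
#' LOWESS span is expressed as a nearest-neighbour sample count (4 samples),
#' which is preserved when sweep grids are coarsened.
#'
#' @param tol rotation-number tolerance.
#' @param tol_prime smoothed-derivative tolerance (1/Hz).
#' @param span_samples LOWESS span as a sample count (`>= 2`).
#' @param candidate_ratios data frame with integer columns `p`, `q`
#'   (coprime); default [candidate_ratios()].
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(tol = 6e-4, tol_prime = 1e-2,
                             span_samples = 4L,
                             candidate_ratios = ditherstim::candidate_ratios()) {
  check_scalar(tol, "tol", 0, strict = TRUE)
  check_scalar(tol_prime, "tol_prime", 0, strict = TRUE)
  if (span_samples < 2) stop("`span_samples` must be >= 2")
  stopifnot(is.data.frame(candidate_ratios),
            all(c("p", "q") %in% names(candidate_ratios)))
  structure(list(tol = tol, tol_prime = tol_prime,
                 span_samples = as.integer(span_samples),
                 candidate_ratios = candidate_ratios),
            class = "detection_config")
}

#' @rdname detection_config
#' @export
kuramoto_detection <- function(tol = 3e-2, tol_prime = 2e-2,
                               span_samples = 4L,
                               candidate_ratios = ditherstim::candidate_ratios()) {
  detection_config(tol, tol_prime, span_samples, candidate_ratios)
}

#' Candidate locking ratios
#'
#' All coprime p:q with `p <= p_max`, `q <= q_max`, plus the purely
#' super-harmonic ratios `p:1` up to `extra_p_max`. Covers every ratio the
#' tongue maps in this package resolve (1:2, 1:1, 3:2, 2:1, ...).
#'
#' @param p_max,q_max bounds of the general coprime grid (default 4).
#' @param extra_p_max bound for additional p:1 ratios (default 8).
#' @return data frame with columns `p`, `q`, `ratio`, `label`.
#' @export
candidate_ratios <- function(p_max = 4L, q_max = 4L, extra_p_max = 8L) {
  grid <- expand.grid(p = seq_len(max(p_max, extra_p_max)),
                      q = seq_len(q_max))
  grid <- grid[grid$q == 1L | grid$p <= p_max, ]
  keep <- mapply(gcd2, grid$p, grid$q) == 1L
  grid <- grid[keep, ]
  grid$ratio <- grid$p / grid$q
  grid <- grid[!duplicated(grid$ratio), ]
  grid <- grid[order(grid$ratio), ]
  grid$label <- paste0(grid$p, ":", grid$q)
  rownames(grid) <- NULL
  grid
}

#' Smoothed derivative of the rotation number along natural frequency
#'
#' Central finite differences of R over a uniform f0 grid (one-sided at the
#' edges), followed by locally weighted scatterplot smoothing (LOWESS,
#' local-linear with tricube weights, no robustness iterations) over a span
#' of `span_samples` nearest neighbours.
#'
#' @param f0_grid uniform natural-frequency grid (Hz), length `>= 4`.
#' @param R_values rotation numbers on the grid.
#' @param span_samples LOWESS span as a sample count (`>= 2`).
#' @return numeric vector of smoothed dR/df0 values (1/Hz).
#' @export
smoothed_derivative <- function(f0_grid, R_values, span_samples = 4L) {
  n <- length(f0_grid)
  if (n < 4 || length(R_values) != n)
    stop("need >= 4 samples and matching lengths")
  h <- diff(f0_grid)
  if (any(h <= 0) || max(h) - min(h) > 1e-8 * mean(h))
    stop("`f0_grid` must be uniform and increasing")
  if (span_samples < 2)
    stop("LOWESS span must cover at least 2 grid steps")
  h <- mean(h)
  dR <- numeric(n)
  dR[2:(n - 1)] <- (R_values[3:n] - R_values[1:(n - 2)]) / (2 * h)
  dR[1] <- (R_values[2] - R_values[1]) / h
  dR[n] <- (R_values[n] - R_values[n - 1]) / h
  lowess(f0_grid, dR, f = span_samples / n, iter = 0, delta = 0)$y
}

#' Detect frequency-locking plateaux along a rotation-number curve
#'
#' Applies the plateau criterion of [detection_config()] at every f0 bin:
#' the bin is labelled with the unique candidate ratio p:q for which
#' `|R - p/q| < tol` while the smoothed derivative of R stays below
#' `tol_prime` in magnitude. The candidate set must be separated by more
#' than `2 * tol` so labels are unambiguous.
#'
#' `R_values` may also be a matrix with one column per simulation repeat, in
#' which case a bin is labelled only when *every* repeat satisfies both
#' conditions. This strict rule distinguishes true locking (each repeat's
#' phase is trapped, giving identical plateaux) from residual statistical
#' pinning at a dithering-destroyed tongue, where symmetric phase escapes
#' keep the repeat-*averaged* R close to p/q even though individual repeats
#' wander; sweeps use it by default.
#'
#' @param f0_grid uniform natural-frequency grid (Hz).
#' @param R_values rotation numbers on the grid: a vector (single or
#'   repeat-averaged curve) or a bins-by-repeats matrix.
#' @param cfg a [detection_config()].
#' @return character vector of labels (`"p:q"` or `NA`) along the grid.
#' @export
#' @examples
#' f0 <- seq(60, 70, by = 0.5)
#' R <- ifelse(abs(f0 - 65) < 3, 0.5, f0 / 130)
#' detect_locking(f0, R, detection_config())
detect_locking <- function(f0_grid, R_values, cfg = detection_config()) {
  stopifnot(inherits(cfg, "detection_config"))
  rats <- cfg$candidate_ratios
  if (nrow(rats) == 0) stop("`candidate_ratios` is empty")
  gaps <- diff(sort(rats$ratio))
  if (length(gaps) && min(gaps) <= 2 * cfg$tol)
    stop("`tol` is too large for the candidate set: two ratios are closer ",
         "than 2 * tol, labels would be ambiguous")
  R_mat <- if (is.matrix(R_values)) R_values else matrix(R_values, ncol = 1)
  if (nrow(R_mat) != length(f0_grid))
    stop("`R_values` must have one row (or entry) per f0 bin")
  S_mat <- apply(R_mat, 2, smoothed_derivative, f0_grid = f0_grid,
                 span_samples = cfg$span_samples)
  flat <- apply(abs(S_mat) < cfg$tol_prime, 1, all)
  labels <- rep(NA_character_, length(f0_grid))
  for (k in seq_len(nrow(rats))) {
    near <- apply(abs(R_mat - rats$ratio[k]) < cfg$tol, 1, all)
    labels[flat & near] <- rats$label[k]
  }
  labels
}

#' Tongue width measured from an entrainment map
#'
#' The simulated width of the p:q Arnold tongue at stimulation amplitude
#' `I`: number of natural-frequency bins labelled p:q at that amplitude
#' times the bin width.
#'
#' @param map an `entrainment_map` from [run_sweep()].
#' @param p,q locking ratio.
#' @param I amplitude (must lie on the map's amplitude grid).
#' @return width in Hz.
#' @export
tongue_width_from_map <- function(map, p, q, I) {
  stopifnot(inherits(map, "entrainment_map"))
  j <- which(abs(map$I_grid - I) < 1e-9)
  if (length(j) != 1) stop("`I` must match one value on the amplitude grid")
  if (length(map$f0_grid) < 2) return(0)
  bin <- mean(diff(map$f0_grid))
  lbl <- paste0(p, ":", q)
  sum(map$locking[, j] == lbl, na.rm = TRUE) * bin
}

#' Mean instantaneous frequency of the order-parameter phase
#'
#' Time average of the finite-difference derivative of the unwrapped
#' order-parameter phase divided by 2*pi, over a time window (default: the
#' whole series = the duration of stimulation).
#'
#' @param series an `order_parameter_series`, or a list with numeric
#'   `times` and `psi`.
#' @param window optional `c(t_start, t_end)` in seconds.
#' @return mean instantaneous frequency (Hz).
#' @export
mean_instantaneous_frequency <- function(series, window = NULL) {
  t <- series$times; psi <- series$psi
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; psi <- psi[keep]
  }
  if (length(t) < 2) stop("window contains fewer than 2 samples")
  mean(diff(psi) / diff(t)) / (2 * pi)
}

#' Phase locking value between two phase sequences
#'
#' Modulus of the time-averaged unit phasor of the phase difference,
#' \eqn{|\langle e^{i(\phi_a - \phi_b)}\rangle|}: 1 for perfect 1:1 phase
#' locking (any constant offset), near \eqn{1/\sqrt{n}} for independent
#' phases.
#'
#' @param phase_a,phase_b numeric phase sequences (radians) of equal length.
#' @return PLV in `[0, 1]`.
#' @export
#' @examples
#' plv(1:100 * 0.3, 1:100 * 0.3 + pi / 3) # exactly 1
plv <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b))
    stop("phase sequences must have equal length")
  Mod(mean(exp(1i * (phase_a - phase_b))))
}

#' Instantaneous phase of a pulse train
#'
#' Linear phase ramp from 0 to 2*pi over each inter-pulse interval, sampled
#' at arbitrary times; the stimulation-phase reference used for PLV against
#' the order-parameter phase.
#'
#' @param train a `pulse_train`.
#' @param times sample times (s).
#' @return unwrapped train phase at `times` (radians).
#' @export
train_phase <- function(train, times) {
  stopifnot(inherits(train, "pulse_train"))
  idx <- findInterval(times, train$pulse_times)
  idx <- pmax(1L, pmin(idx, length(train$periods)))
  frac <- (times - train$pulse_times[idx]) / train$periods[idx]
  2 * pi * (idx - 1 + pmin(pmax(frac, 0), 1))
}
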