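#' Sine circle map configuration
#'
#' Parameters of the (optionally dithered) sine circle map
#' \deqn{\theta_{n+1} = \theta_n + 2\pi \frac{f_0}{f_s}(1 + z_n) +
#'       I \sin\theta_n,}
#' where \eqn{\theta_n} is the oscillator phase right before stimulation
#' pulse n, \eqn{f_0} the oscillator natural frequency, \eqn{f_s} the base
#' stimulation frequency, \eqn{I} the stimulation magnitude (phase advance,
#' radians) and \eqn{z_n \sim N(0, \zeta^2)} the per-period dithering
#' perturbation. `zeta = 0` gives the deterministic map.
#'
#' @param f0 oscillator natural frequency (Hz), `>= 0`.
#' @param fs base stimulation frequency (Hz), `> 0`.
#' @param I stimulation magnitude (dimensionless phase advance), `>= 0`.
#' @param zeta dithering level (standard deviation of the relative period
#'   perturbation), `>= 0`.
#' @return an object of class `circle_map_config`.
#' @seealso [iterate_circle_map()]
#' @export
#' @examples
#' circle_map_config(f0 = 125, fs = 130, I = 1)
circle_map_config <- function(f0, fs, I, zeta = 0) {
  check_scalar(f0, "f0", 0)
  check_scalar(fs, "fs", 0, strict = TRUE)
  check_scalar(I, "I", 0)
  check_scalar(zeta, "zeta", 0)
  structure(list(f0 = f0, fs = fs, I = I, zeta = zeta),
            class = "circle_map_config")
}

#' @export
print.circle_map_config <- function(x, ...) {
  cat(sprintf(
    "Sine circle map: f0 = %g Hz, fs = %g Hz, I = %g, zeta = %g (%s)\n",
    x$f0, x$fs, x$I, x$zeta,
    if (x$zeta > 0) "dithered" else "deterministic"))
  invisible(x)
}

#' Iterate the (dithered) sine circle map
#'
#' Produces the unwrapped phase trajectory \eqn{\theta_0, \ldots, \theta_n}
#' of the sine circle map, sampled immediately before each stimulation pulse.
#' With `zeta = 0` the iteration is deterministic; with `zeta > 0` each step
#' receives an independent multiplicative period perturbation
#' \eqn{z_k \sim N(0, \zeta^2)} and a `seed` is required. Phases accumulate
#' without modulo reduction so that rotation numbers can be read off the
#' endpoints.
#'
#' @param config a [circle_map_config()].
#' @param theta0 initial phase (radians). If `NULL`, drawn uniformly on
#'   `[0, 2*pi)` (requires `seed`).
#' @param n number of pulses (iterations), `>= 1`.
#' @param seed integer RNG seed; required whenever the run is stochastic
#'   (`zeta > 0` or `theta0 = NULL`). Identical seeds give bitwise-identical
#'   trajectories.
#' @param burn_in number of initial iterations to discard before the
#'   trajectory starts (default 0; transients contribute only O(1/n) to the
#'   rotation number at n = 1e4).
#' @return an object of class `phase_trajectory`: a list with `phases`
#'   (length `n + 1`, unwrapped radians), `n_pulses`, `seed`, `config`.
#' @export
#' @examples
#' cfg <- circle_map_config(f0 = 125, fs = 130, I = 1)
#' traj <- iterate_circle_map(cfg, theta0 = 0.5, n = 1000)
#' rotation_number(traj)
iterate_circle_map <- function(config, theta0 = NULL, n, seed = NULL,
                               burn_in = 0L) {
  stopifnot(inherits(config, "circle_map_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  if (!is.numeric(burn_in) || burn_in < 0 || burn_in != round(burn_in))
    stop("`burn_in` must be a non-negative integer")
  stochastic <- config$zeta > 0 || is.null(theta0)
  if (stochastic) {
    if (is.null(seed)) stop("`seed` is required for stochastic runs")
    set.seed(seed)
  }
  if (is.null(theta0)) theta0 <- runif(1, 0, 2 * pi)
  check_scalar(theta0, "theta0")
  ratio <- config$f0 / config$fs
  if (burn_in > 0) {
    ph0 <- cpp_circle_map(theta0, as.integer(burn_in), ratio, config$I,
                          config$zeta)
    theta0 <- ph0[length(ph0)]
  }
  phases <- cpp_circle_map(theta0, as.integer(n), ratio, config$I,
                           config$zeta)
  structure(list(phases = phases, n_pulses = as.integer(n),
                 seed = if (stochastic) seed else NULL, config = config),
            class = "phase_trajectory")
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("Phase trajectory: %d pulses, final phase %.4f rad (R = %.6f)\n",
              x$n_pulses, x$phases[length(x$phases)], rotation_number(x)))
  invisible(x)
}

#' @export
as.data.frame.phase_trajectory <- function(x, ...) {
  data.frame(pulse = seq_along(x$phases) - 1L, phase = x$phases)
}

#' Export a phase trajectory as CSV
#'
#' Writes a two-column CSV (pulse index, unwrapped phase in radians).
#'
#' @param traj a `phase_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "phase_trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
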