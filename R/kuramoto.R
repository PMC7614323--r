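#' Stimulated Kuramoto population configuration
#'
#' Parameters of a population of M coupled noisy phase oscillators driven by
#' a stimulation current I(t) through a phase response curve Z:
#' \deqn{d\varphi_k = [\omega_k + \kappa\rho\sin(\psi - \varphi_k) +
#'   I(t) Z(\varphi_k)]\,dt + \xi\, dW_k,}
#' where \eqn{\rho e^{i\psi}} is the population order parameter (mean unit
#' phasor) and the attractive order-parameter form of the homogeneous
#' sinusoidal coupling is used. Intrinsic frequencies \eqn{\omega_k/2\pi}
#' are Lorentzian (Cauchy) around `f0_center` with scale `lorentz_width`.
#' Defaults (`M = 100`, `kappa = 350`, `xi = 7.9`, width 20 Hz,
#' `dt = 1e-4` s) produce a partially synchronised population whose output
#' signal \eqn{X(t) = \rho\cos\psi} resembles a noisy neural oscillation.
#'
#' @param f0_center centre of the intrinsic-frequency distribution (Hz).
#' @param M population size (default 100).
#' @param kappa coupling strength (rad/s, default 350).
#' @param xi intrinsic noise standard deviation (rad/sqrt(s), default 7.9).
#' @param lorentz_width Lorentzian (Cauchy) scale of the intrinsic-frequency
#'   distribution (Hz, default 20). 0 gives identical oscillators.
#' @param prc phase response curve: the string `"sin"` (default, exact
#'   \eqn{Z(\theta)=\sin\theta}), a 2*pi-periodic R function of phase, or a
#'   numeric table sampled uniformly on `[0, 2*pi)` (e.g. a tabulated
#'   Hodgkin-Huxley PRC). Functions/tables are evaluated by linear
#'   interpolation on a 1024-point table.
#' @param coupling reserved hook for non-sinusoidal 2*pi-periodic coupling
#'   functions; only `"sin"` is currently integrated (supplying anything
#'   else is an error).
#' @param dt Euler-Maruyama integration step (s, default 1e-4).
#' @return an object of class `kuramoto_config`.
#' @export
#' @examples
#' kuramoto_config(f0_center = 30)
kuramoto_config <- function(f0_center, M = 100L, kappa = 350, xi = 7.9,
                            lorentz_width = 20, prc = "sin",
                            coupling = "sin", dt = 1e-4) {
  check_scalar(f0_center, "f0_center", 0)
  if (M < 1 || M != round(M)) stop("`M` must be a positive integer")
  check_scalar(kappa, "kappa", 0)
  check_scalar(xi, "xi", 0)
  check_scalar(lorentz_width, "lorentz_width", 0)
  check_scalar(dt, "dt", 0, strict = TRUE)
  if (!identical(coupling, "sin"))
    stop("only sinusoidal coupling is integrated; `coupling` is a hook for ",
         "user-supplied 2*pi-periodic functions in future versions")
  prc_table <- prc_to_table(prc)
  structure(list(f0_center = f0_center, M = as.integer(M), kappa = kappa,
                 xi = xi, lorentz_width = lorentz_width, prc = prc,
                 prc_table = prc_table, dt = dt),
            class = "kuramoto_config")
}

# Convert a PRC specification to the numeric table passed to the
# integrator; numeric(0) selects the exact sinusoidal fast path.
prc_to_table <- function(prc, n = 1024L) {
  if (identical(prc, "sin")) return(numeric(0))
  if (is.function(prc)) {
    theta <- 2 * pi * (seq_len(n) - 1L) / n
    tab <- prc(theta)
    if (!is.numeric(tab) || length(tab) != n || anyNA(tab))
      stop("`prc` function must return one finite value per phase")
    return(as.numeric(tab))
  }
  if (is.numeric(prc) && length(prc) >= 8 && all(is.finite(prc)))
    return(as.numeric(prc))
  stop("`prc` must be \"sin\", a function of phase, or a numeric table ",
       "(length >= 8) sampled uniformly on [0, 2*pi)")
}

#' Sample intrinsic frequencies of a Kuramoto population
#'
#' Draws `M` intrinsic frequencies (rad/s) whose Hz values follow a
#' Lorentzian (Cauchy) law centred at `f0_center` with scale
#' `lorentz_width`. Negative draws from the heavy left tail are resampled so
#' that all oscillators have physical (non-negative) frequencies. With
#' `lorentz_width = 0` all oscillators share `f0_center` exactly.
#'
#' @param config a [kuramoto_config()].
#' @param seed integer RNG seed.
#' @return numeric vector of `M` angular frequencies (rad/s).
#' @export
sample_intrinsic_frequencies <- function(config, seed = NULL) {
  stopifnot(inherits(config, "kuramoto_config"))
  if (!is.null(seed)) set.seed(seed)
  if (config$lorentz_width == 0)
    return(rep(2 * pi * config$f0_center, config$M))
  f <- rcauchy(config$M, config$f0_center, config$lorentz_width)
  bad <- which(f < 0)
  while (length(bad) > 0) {
    f[bad] <- rcauchy(length(bad), config$f0_center, config$lorentz_width)
    bad <- bad[f[bad] < 0]
  }
  2 * pi * f
}

# Per-step stimulation signal for a biphasic pulse train, scaled by
# `amplitude`. Step j covers [t_j, t_j + dt), t_j = (j-1)*dt.
build_stim_signal <- function(train, dt, n_steps, amplitude = 1) {
  if (identical(train$waveform, "impulse"))
    stop("continuous-time simulation needs a biphasic waveform; build the ",
         "train with waveform = biphasic_waveform()")
  wf <- train$waveform
  if (wf$positive_fraction * mean(train$periods) / dt < 10)
    stop("dt too coarse for the waveform: the positive lobe (",
         signif(wf$positive_fraction * mean(train$periods), 3),
         " s at the nominal period) must span at least 10 integration steps")
  t <- (seq_len(n_steps) - 1) * dt
  idx <- findInterval(t, train$pulse_times)
  stim <- numeric(n_steps)
  inside <- idx >= 1 & idx <= length(train$periods)
  off <- t[inside] - train$pulse_times[idx[inside]]
  pos <- off < wf$positive_fraction * train$periods[idx[inside]]
  stim[inside][pos] <- wf$positive_amplitude
  stim[inside][!pos] <- wf$negative_amplitude
  amplitude * stim
}

#' Simulate a stimulated Kuramoto population
#'
#' Euler-Maruyama integration of the order-parameter form of the stimulated
#' Kuramoto model (see [kuramoto_config()]). At every step the order
#' parameter modulus rho and phase psi are recomputed from the current
#' phases and recorded (psi unwrapped); the stimulation current is the
#' charge-balanced biphasic square train held constant over each step.
#'
#' @param config a [kuramoto_config()].
#' @param train a `pulse_train` built with a [biphasic_waveform()], or
#'   `NULL` for an unstimulated run.
#' @param duration simulated time (s); defaults to the train's total span.
#' @param amplitude stimulation amplitude: scale factor applied to the
#'   train's unit waveform (units of phase-advance rate, rad/s, once
#'   multiplied by the PRC).
#' @param seed integer RNG seed; fixes the intrinsic-frequency draw, the
#'   initial phases (uniform on `[0, 2*pi)`) and the noise path.
#' @param decimate record every `decimate`-th sample (default 1 = every
#'   integrator step).
#' @return an object of class `order_parameter_series`: list with `times`
#'   (s), `rho` (in `[0, 1]`), `psi` (unwrapped, radians), `x`
#'   (\eqn{\rho\cos\psi}), `phi_final` (final oscillator phases), `dt`,
#'   `omega` (intrinsic frequencies used), `config`, `train`, `amplitude`,
#'   `seed`.
#' @export
#' @examples
#' cfg <- kuramoto_config(f0_center = 30, M = 20)
#' series <- simulate_kuramoto(cfg, train = NULL, duration = 0.2, seed = 1)
#' range(series$rho)
simulate_kuramoto <- function(config, train, duration = NULL, amplitude = 1,
                              seed = NULL, decimate = 1L) {
  stopifnot(inherits(config, "kuramoto_config"))
  if (is.null(duration)) {
    if (is.null(train)) stop("`duration` is required without a train")
    duration <- sum(train$periods)
  }
  check_scalar(duration, "duration", 0, strict = TRUE)
  n_steps <- as.integer(ceiling(duration / config$dt))
  if (!is.null(seed)) set.seed(seed)
  omega <- sample_intrinsic_frequencies(config)
  phi0 <- runif(config$M, 0, 2 * pi)
  stim <- if (is.null(train)) numeric(n_steps)
          else build_stim_signal(train, config$dt, n_steps, amplitude)
  res <- cpp_kuramoto(omega, config$kappa, config$xi, config$dt, stim, phi0,
                      config$prc_table)
  keep <- seq(1L, n_steps, by = as.integer(decimate))
  structure(list(times = (keep - 1) * config$dt,
                 rho = res$rho[keep], psi = res$psi[keep], x = res$x[keep],
                 phi_final = res$phi_final,
                 dt = config$dt * decimate, step_dt = config$dt,
                 full_psi = res$psi,
                 omega = omega, config = config, train = train,
                 amplitude = amplitude, seed = seed),
            class = "order_parameter_series")
}

#' @export
print.order_parameter_series <- function(x, ...) {
  cat(sprintf(
    "Order-parameter series: %.3f s at dt = %g s, mean rho = %.3f\n",
    x$times[length(x$times)], x$dt, mean(x$rho)))
  invisible(x)
}

#' Order-parameter phase sampled just before each stimulation pulse
#'
#' Extracts `psi(t_n)` one integrator step before each pulse onset of the
#' train that drove the simulation — the phase samples from which the
#' population rotation number is measured.
#'
#' @param series an `order_parameter_series` from [simulate_kuramoto()].
#' @param train pulse train (defaults to the one stored in `series`).
#' @return numeric vector of unwrapped phases, one per pulse.
#' @export
psi_at_pulses <- function(series, train = series$train) {
  stopifnot(inherits(series, "order_parameter_series"))
  if (is.null(train)) stop("no pulse train available")
  psi <- series$full_psi
  idx <- pmax(1L, pmin(length(psi), floor(train$pulse_times / series$step_dt)))
  # pulse at t = 0 has no earlier step; use the initial sample
  idx[train$pulse_times <= 0] <- 1L
  psi[idx]
}

#' Export an order-parameter series as CSV (with a JSON sidecar)
#'
#' Writes columns `t`, `rho`, `psi`, `x` and a `<path>.json` sidecar with
#' the configuration, amplitude and seed.
#'
#' @param series an `order_parameter_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "order_parameter_series"))
  df <- data.frame(t = series$times, rho = series$rho, psi = series$psi,
                   x = series$x)
  write.csv(df, path, row.names = FALSE)
  cfg <- series$config
  meta <- list(f0_center = cfg$f0_center, M = cfg$M, kappa = cfg$kappa,
               xi = cfg$xi, lorentz_width = cfg$lorentz_width,
               prc = if (is.character(cfg$prc)) cfg$prc else "custom",
               dt = cfg$dt, amplitude = series$amplitude,
               seed = series$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
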