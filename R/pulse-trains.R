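#' Charge-balanced biphasic waveform description
#'
#' A biphasic square pulse occupying one stimulation period: a positive lobe
#' of height `positive_amplitude` over the first `positive_fraction` of the
#' period, then a negative lobe over the remainder whose amplitude is set so
#' that the time integral over the period is exactly zero (charge balance):
#' `negative_amplitude = -positive_amplitude * positive_fraction /
#' (1 - positive_fraction)`.
#'
#' @param positive_fraction fraction of the period occupied by the positive
#'   lobe, in `(0, 1)` (default 0.2).
#' @param positive_amplitude peak value of the positive lobe (default 1; the
#'   sweep's stimulation-amplitude axis scales this unit waveform).
#' @return an object of class `biphasic_waveform` with fields
#'   `positive_fraction`, `positive_amplitude`, `negative_amplitude`.
#' @export
#' @examples
#' biphasic_waveform() # 20% positive lobe, negative lobe at -1/4
biphasic_waveform <- function(positive_fraction = 0.2,
                              positive_amplitude = 1) {
  check_scalar(positive_fraction, "positive_fraction", 0, strict = TRUE)
  if (positive_fraction >= 1) stop("`positive_fraction` must be < 1")
  check_scalar(positive_amplitude, "positive_amplitude", 0, strict = TRUE)
  structure(list(
    positive_fraction = positive_fraction,
    positive_amplitude = positive_amplitude,
    negative_amplitude = -positive_amplitude * positive_fraction /
      (1 - positive_fraction)),
    class = "biphasic_waveform")
}

#' Cycling scheme description
#'
#' How successive stimulation periods are chosen: `"periodic"` (constant),
#' `"white_noise"` (independent normal dithering at level `zeta`),
#' `"random_cycling"` (each period drawn uniformly from a finite frequency
#' set), `"deterministic_cycling"` (cycle through the set in order, one
#' period per frequency), or `"slow_deterministic_cycling"` (hold each
#' frequency for `N_r` consecutive periods before toggling).
#'
#' @param mode one of the five modes above.
#' @param N_r repeats per frequency (slow deterministic cycling only).
#' @param zeta dithering level (white-noise mode only).
#' @return an object of class `cycling_scheme`.
#' @export
cycling_scheme <- function(mode = c("periodic", "white_noise",
                                    "random_cycling",
                                    "deterministic_cycling",
                                    "slow_deterministic_cycling"),
                           N_r = 1L, zeta = 0) {
  mode <- match.arg(mode)
  if (N_r < 1 || N_r != round(N_r)) stop("`N_r` must be a positive integer")
  check_scalar(zeta, "zeta", 0)
  structure(list(mode = mode, N_r = as.integer(N_r), zeta = zeta),
            class = "cycling_scheme")
}

new_pulse_train <- function(periods, scheme, seed, waveform) {
  structure(list(
    pulse_times = c(0, cumsum(periods))[seq_along(periods)],
    periods = periods,
    waveform = waveform,
    scheme = scheme,
    seed = seed),
    class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "Pulse train: %d pulses over %.3f s (%s), mean rate %.2f Hz\n",
    length(x$periods), sum(x$periods), x$scheme$mode,
    length(x$periods) / sum(x$periods)))
  invisible(x)
}

#' White-noise dithered pulse train
#'
#' Generates `n_pulses` pulses whose inter-pulse intervals are
#' `(1 + z_k)/fs` with independent `z_k ~ N(0, zeta^2)`. For a continuous
#' -time train intervals must stay positive, so draws with `1 + z_k <= 0`
#' are resampled; for `zeta <= 0.2` this happens with probability below
#' 1e-6 and does not distort the distribution measurably. `zeta = 0` gives a
#' perfectly periodic train.
#'
#' @param fs base stimulation frequency (Hz), `> 0`.
#' @param zeta dithering level, `>= 0`.
#' @param n_pulses number of pulses.
#' @param seed integer RNG seed (required when `zeta > 0`).
#' @param waveform a [biphasic_waveform()], or `"impulse"` for idealised
#'   zero-width pulses (default).
#' @return an object of class `pulse_train` with fields `pulse_times`
#'   (onsets, s, starting at 0), `periods` (s), `waveform`, `scheme`, `seed`.
#' @export
#' @examples
#' tr <- dithered_train(130, zeta = 0.1, n_pulses = 100, seed = 1)
#' mean(tr$periods) * 130 # close to 1
dithered_train <- function(fs, zeta, n_pulses, seed = NULL,
                           waveform = "impulse") {
  check_scalar(fs, "fs", 0, strict = TRUE)
  check_scalar(zeta, "zeta", 0)
  if (n_pulses < 1 || n_pulses != round(n_pulses))
    stop("`n_pulses` must be a positive integer")
  mode <- if (zeta > 0) "white_noise" else "periodic"
  if (zeta > 0) {
    if (is.null(seed)) stop("`seed` is required when zeta > 0")
    set.seed(seed)
    z <- rnorm(n_pulses, 0, zeta)
    bad <- which(1 + z <= 0)
    n_resampled <- 0L
    while (length(bad) > 0) {
      n_resampled <- n_resampled + length(bad)
      if (n_resampled > 0.5 * n_pulses)
        stop("zeta is far outside the intended regime: ",
             "more than 50% of period draws were non-positive")
      z[bad] <- rnorm(length(bad), 0, zeta)
      bad <- bad[1 + z[bad] <= 0]
    }
    periods <- (1 + z) / fs
  } else {
    periods <- rep(1 / fs, n_pulses)
  }
  new_pulse_train(periods, cycling_scheme(mode, zeta = zeta),
                  if (zeta > 0) seed else NULL, waveform)
}

#' Finite stimulation-frequency set with period-uniform spacing
#'
#' Builds the set of `n` stimulation frequencies used by the cycling
#' schemes: the corresponding periods are equally spaced spanning
#' `[1/f_max, 1/f_min]`, so the period distribution is (discretely) uniform
#' and symmetric around the base period. The base frequency is the
#' reciprocal of the mean period; note that a period-uniform set is skewed
#' in frequency. This mirrors implantable-device constraints where only a
#' finite menu of rates is programmable.
#'
#' @param f_min,f_max frequency range (Hz), `0 < f_min < f_max`.
#' @param n number of frequencies, `>= 2`.
#' @return an object of class `frequency_set`: list with `frequencies`
#'   (strictly increasing, Hz), `periods` (s), `base_fs` (Hz).
#' @export
#' @examples
#' fset <- build_frequency_set(100, 185.7, 13)
#' fset$base_fs # ~130 Hz
#' equivalent_zeta(fset) # ~0.17
build_frequency_set <- function(f_min, f_max, n) {
  check_scalar(f_min, "f_min", 0, strict = TRUE)
  check_scalar(f_max, "f_max", f_min, strict = TRUE)
  if (n < 2 || n != round(n)) stop("`n` must be an integer >= 2")
  periods <- seq(1 / f_max, 1 / f_min, length.out = n)
  frequencies <- sort(1 / periods)
  structure(list(frequencies = frequencies, periods = periods,
                 base_fs = 1 / mean(periods)),
            class = "frequency_set")
}

#' Equivalent white-noise dithering level of a frequency set
#'
#' The dithering level that a period-uniform frequency set emulates:
#' standard deviation of the uniform distribution of periods divided by the
#' mean period. By default the continuous uniform over the period range is
#' used (`(T_max - T_min)/sqrt(12)` over the mean period);
#' `method = "discrete"` uses the sample standard deviation of the set's
#' actual periods instead.
#'
#' @param freq_set a [build_frequency_set()] object.
#' @param method `"continuous"` (default) or `"discrete"`.
#' @return the equivalent dithering level (dimensionless).
#' @export
equivalent_zeta <- function(freq_set, method = c("continuous", "discrete")) {
  stopifnot(inherits(freq_set, "frequency_set"))
  method <- match.arg(method)
  Tm <- mean(freq_set$periods)
  if (method == "continuous") {
    (max(freq_set$periods) - min(freq_set$periods)) / sqrt(12) / Tm
  } else {
    sd(freq_set$periods) / Tm
  }
}

#' Pulse train from cycling over a finite frequency set
#'
#' Approximates white-noise dithering with device-implementable toggling
#' over a finite frequency set: `random_cycling` draws each period
#' independently and uniformly from the set's periods;
#' `deterministic_cycling` steps through the set in order (lowest frequency
#' first, wrapping from the last back to the first) one period per
#' frequency; `slow_deterministic_cycling` holds each frequency for
#' `scheme$N_r` consecutive periods before toggling.
#'
#' @param freq_set a [build_frequency_set()] object.
#' @param scheme a [cycling_scheme()] with one of the three cycling modes.
#' @param n_pulses number of pulses.
#' @param seed integer RNG seed (required for random cycling).
#' @param waveform a [biphasic_waveform()] or `"impulse"`.
#' @param start_index index into the set's frequencies at which
#'   deterministic cycling starts (default 1, the lowest frequency).
#' @return a `pulse_train`.
#' @export
#' @examples
#' fset <- build_frequency_set(100, 185.7, 3)
#' tr <- cycling_train(fset, cycling_scheme("deterministic_cycling"), 9)
#' matrix(tr$periods, nrow = 3) # each column one full cycle
cycling_train <- function(freq_set, scheme, n_pulses, seed = NULL,
                          waveform = "impulse", start_index = 1L) {
  stopifnot(inherits(freq_set, "frequency_set"),
            inherits(scheme, "cycling_scheme"))
  if (n_pulses < 1 || n_pulses != round(n_pulses))
    stop("`n_pulses` must be a positive integer")
  # cycle in order of increasing frequency = decreasing period
  Ts <- sort(freq_set$periods, decreasing = TRUE)
  nset <- length(Ts)
  periods <- switch(scheme$mode,
    random_cycling = {
      if (is.null(seed)) stop("`seed` is required for random cycling")
      set.seed(seed)
      Ts[sample.int(nset, n_pulses, replace = TRUE)]
    },
    deterministic_cycling = {
      idx <- ((start_index - 1L + seq_len(n_pulses) - 1L) %% nset) + 1L
      Ts[idx]
    },
    slow_deterministic_cycling = {
      idx <- ((start_index - 1L +
                 (seq_len(n_pulses) - 1L) %/% scheme$N_r) %% nset) + 1L
      Ts[idx]
    },
    stop("`scheme` must use one of the three cycling modes"))
  new_pulse_train(periods, scheme,
                  if (scheme$mode == "random_cycling") seed else NULL,
                  waveform)
}

#' Frequency hold times for slow deterministic cycling
#'
#' How long a device dwells on one stimulation frequency when toggling only
#' every `N_r` periods: `N_r / f` for each frequency `f` in the set. Returns
#' the extremes in milliseconds.
#'
#' @param freq_set a [build_frequency_set()] object.
#' @param N_r consecutive periods per frequency.
#' @return named numeric vector `c(min_hold_ms, max_hold_ms)`.
#' @export
#' @examples
#' switching_interval(build_frequency_set(100, 185.7, 13), N_r = 15)
switching_interval <- function(freq_set, N_r) {
  stopifnot(inherits(freq_set, "frequency_set"))
  if (N_r < 1 || N_r != round(N_r)) stop("`N_r` must be a positive integer")
  c(min_hold_ms = 1000 * N_r / max(freq_set$frequencies),
    max_hold_ms = 1000 * N_r / min(freq_set$frequencies))
}

#' Export a pulse train as CSV (with a JSON sidecar)
#'
#' Writes one row per pulse (index, onset time in s, period in s, frequency
#' in Hz) and a `<path>.json` sidecar recording the scheme, waveform and
#' seed.
#'
#' @param train a `pulse_train`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_train <- function(train, path) {
  stopifnot(inherits(train, "pulse_train"))
  df <- data.frame(pulse = seq_along(train$periods),
                   onset_s = train$pulse_times,
                   period_s = train$periods,
                   frequency_hz = 1 / train$periods)
  write.csv(df, path, row.names = FALSE)
  meta <- list(scheme = unclass(train$scheme),
               waveform = if (inherits(train$waveform, "biphasic_waveform"))
                 unclass(train$waveform) else train$waveform,
               seed = train$seed,
               n_pulses = length(train$periods))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
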