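#' Parameter sweep configuration
#'
#' Defines a sweep over natural frequency and stimulation amplitude for
#' either the sine circle map or the Kuramoto population model. Every cell
#' of the (f0, I) grid is simulated `n_repeats` times (fresh initial
#' conditions and noise per repeat, seeded reproducibly via [cell_seed()]),
#' rotation numbers are averaged over repeats, and locking plateaux are
#' detected along f0 for each amplitude.
#'
#' @param model `"circle_map"` or `"kuramoto"`.
#' @param f0_grid natural-frequency grid (Hz), uniform, increasing.
#' @param I_grid stimulation-amplitude grid.
#' @param fs base stimulation frequency (Hz, default 130).
#' @param zeta dithering level (ignored when `scheme` cycles over a set).
#' @param scheme optional [cycling_scheme()]; with the three cycling modes a
#'   `freq_set` is required and `zeta` is ignored.
#' @param freq_set optional [build_frequency_set()] used by cycling schemes.
#' @param n_pulses stimulation pulses per repeat (default 1e4 for the circle
#'   map, 400 for the Kuramoto model).
#' @param n_repeats repeats per cell (default 10 for the circle map, 5 for
#'   the Kuramoto model).
#' @param seed base integer seed.
#' @param detection a [detection_config()]; defaults to the model-matched
#'   tolerances.
#' @param kuramoto a [kuramoto_config()] template for population sweeps;
#'   its `f0_center` is replaced by each grid value.
#' @return an object of class `sweep_config`.
#' @seealso [run_sweep()]
#' @export
sweep_config <- function(model = c("circle_map", "kuramoto"),
                         f0_grid, I_grid, fs = 130, zeta = 0,
                         scheme = NULL, freq_set = NULL,
                         n_pulses = NULL, n_repeats = NULL, seed = 1L,
                         detection = NULL, kuramoto = NULL) {
  model <- match.arg(model)
  if (length(f0_grid) < 1 || is.unsorted(f0_grid, strictly = TRUE))
    stop("`f0_grid` must be increasing and nonempty")
  if (length(I_grid) < 1) stop("`I_grid` must be nonempty")
  check_scalar(fs, "fs", 0, strict = TRUE)
  check_scalar(zeta, "zeta", 0)
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "cycling_scheme"))
    if (scheme$mode %in% c("random_cycling", "deterministic_cycling",
                           "slow_deterministic_cycling") &&
        is.null(freq_set))
      stop("cycling schemes need a `freq_set`")
  }
  if (is.null(n_pulses))
    n_pulses <- if (model == "circle_map") 1e4 else 400
  if (is.null(n_repeats))
    n_repeats <- if (model == "circle_map") 10L else 5L
  if (is.null(detection))
    detection <- if (model == "circle_map") detection_config()
                 else kuramoto_detection()
  if (model == "kuramoto" && is.null(kuramoto))
    kuramoto <- kuramoto_config(f0_center = f0_grid[1])
  structure(list(model = model, f0_grid = f0_grid, I_grid = I_grid,
                 fs = fs, zeta = zeta, scheme = scheme, freq_set = freq_set,
                 n_pulses = as.integer(n_pulses),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), detection = detection,
                 kuramoto = kuramoto),
            class = "sweep_config")
}

# Build the pulse train for one Kuramoto repeat under the sweep's scheme.
sweep_train <- function(cfg, seed, waveform) {
  if (!is.null(cfg$scheme) &&
      cfg$scheme$mode %in% c("random_cycling", "deterministic_cycling",
                             "slow_deterministic_cycling")) {
    cycling_train(cfg$freq_set, cfg$scheme, cfg$n_pulses, seed = seed,
                  waveform = waveform)
  } else {
    dithered_train(cfg$fs, cfg$zeta, cfg$n_pulses, seed = seed,
                   waveform = waveform)
  }
}

#' Run an entrainment sweep
#'
#' Simulates every (f0, I) grid cell of a [sweep_config()] for every repeat,
#' measures rotation numbers (and, for population sweeps, mean instantaneous
#' frequencies), averages over repeats, and labels locking plateaux per
#' amplitude row. The result is fully reproducible from the configuration
#' and base seed: each cell uses [cell_seed()] streams, so refining the grid
#' leaves existing cells unchanged.
#'
#' @param cfg a [sweep_config()].
#' @param progress print one line per amplitude row (default `FALSE`).
#' @return an object of class `entrainment_map`: list with `f0_grid`,
#'   `I_grid`, `R` (matrix f0 x I of repeat-averaged rotation numbers),
#'   `R_repeats` (f0 x I x repeat array of per-repeat rotation numbers),
#'   `locking` (character matrix of `"p:q"` labels or `NA`; every repeat
#'   must satisfy the plateau criterion, see [detect_locking()]), `f_inst`
#'   (matrix or `NULL`), plus the sweep metadata. Maps re-read from CSV via
#'   [read_entrainment_map()] carry the averaged `R` and labels but not the
#'   per-repeat array.
#' @export
#' @examples
#' cfg <- sweep_config("circle_map", f0_grid = seq(125, 135, 1), I_grid = 1,
#'                     n_pulses = 2000, n_repeats = 2)
#' map <- run_sweep(cfg)
#' tongue_width_from_map(map, 1, 1, 1)
run_sweep <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  nf <- length(cfg$f0_grid); ni <- length(cfg$I_grid)
  R_rep <- array(NA_real_, c(nf, ni, cfg$n_repeats))
  f_inst <- if (cfg$model == "kuramoto") matrix(NA_real_, nf, ni) else NULL
  for (j in seq_len(ni)) {
    for (i in seq_len(nf)) {
      acc_f <- 0
      for (r in seq_len(cfg$n_repeats)) {
        s <- cell_seed(cfg$seed, i, j, r)
        if (cfg$model == "circle_map") {
          set.seed(s)
          theta0 <- runif(1, 0, 2 * pi)
          if (!is.null(cfg$scheme) && cfg$scheme$mode != "white_noise" &&
              cfg$scheme$mode != "periodic") {
            tr <- sweep_train(cfg, cell_seed(s, 1L, 1L, 1L), "impulse")
            ph <- cpp_circle_map_train(theta0, tr$periods, cfg$f0_grid[i],
                                       cfg$I_grid[j])
            R_rep[i, j, r] <- (ph[length(ph)] - ph[1]) /
              (2 * pi * cfg$n_pulses)
          } else {
            R_rep[i, j, r] <- cpp_circle_map_rotation(
              theta0, cfg$n_pulses, cfg$f0_grid[i] / cfg$fs,
              cfg$I_grid[j], cfg$zeta)
          }
        } else {
          kcfg <- cfg$kuramoto
          kcfg$f0_center <- cfg$f0_grid[i]
          tr <- sweep_train(cfg, cell_seed(s, 1L, 1L, 1L), biphasic_waveform())
          series <- simulate_kuramoto(kcfg, tr, amplitude = cfg$I_grid[j],
                                      seed = s, decimate = 10L)
          psi_n <- psi_at_pulses(series, tr)
          R_rep[i, j, r] <- rotation_number(psi_n)
          acc_f <- acc_f + mean_instantaneous_frequency(series)
        }
      }
      if (!is.null(f_inst)) f_inst[i, j] <- acc_f / cfg$n_repeats
    }
    if (progress)
      message(sprintf("amplitude %g done (%d/%d)", cfg$I_grid[j], j, ni))
  }
  R <- apply(R_rep, c(1, 2), mean)
  locking <- matrix(NA_character_, nf, ni)
  if (nf >= 4) {
    for (j in seq_len(ni))
      locking[, j] <- detect_locking(cfg$f0_grid, R_rep[, j, , drop = TRUE],
                                     cfg$detection)
  }
  structure(list(f0_grid = cfg$f0_grid, I_grid = cfg$I_grid, R = R,
                 R_repeats = R_rep,
                 locking = locking, f_inst = f_inst,
                 n_repeats = cfg$n_repeats, n_pulses = cfg$n_pulses,
                 zeta = cfg$zeta, scheme = cfg$scheme, fs = cfg$fs,
                 model = cfg$model, seed = cfg$seed,
                 detection = cfg$detection),
            class = "entrainment_map")
}

#' @export
print.entrainment_map <- function(x, ...) {
  cat(sprintf(
    "Entrainment map (%s): %d f0 x %d I cells, %d repeats x %d pulses\n",
    x$model, length(x$f0_grid), length(x$I_grid), x$n_repeats, x$n_pulses))
  lbl <- table(x$locking[!is.na(x$locking)])
  if (length(lbl))
    cat("  locked bins:",
        paste(sprintf("%s (%d)", names(lbl), lbl), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.entrainment_map <- function(x, ...) {
  grid <- expand.grid(f0 = x$f0_grid, I = x$I_grid)
  grid$R <- as.vector(x$R)
  grid$label <- as.vector(x$locking)
  grid$f_inst <- if (is.null(x$f_inst)) NA_real_ else as.vector(x$f_inst)
  grid$zeta <- x$zeta
  grid$scheme <- if (is.null(x$scheme)) "white_noise" else x$scheme$mode
  grid
}

#' Read/write entrainment maps as tidy CSV plus JSON metadata
#'
#' `write_entrainment_map()` writes one row per (f0, I) cell (columns `f0`,
#' `I`, `R`, `label`, `f_inst`, `zeta`, `scheme`) and a `<path>.json`
#' sidecar with the grids, model, seed and detection tolerances.
#' `read_entrainment_map()` reconstructs the `entrainment_map` object.
#'
#' @param map an `entrainment_map`.
#' @param path CSV file path.
#' @return `write_entrainment_map()` returns `path` invisibly;
#'   `read_entrainment_map()` returns an `entrainment_map`.
#' @export
write_entrainment_map <- function(map, path) {
  stopifnot(inherits(map, "entrainment_map"))
  write.csv(as.data.frame(map), path, row.names = FALSE)
  meta <- list(model = map$model, f0_grid = map$f0_grid,
               I_grid = map$I_grid, fs = map$fs, zeta = map$zeta,
               scheme = if (is.null(map$scheme)) NULL
                        else unclass(map$scheme),
               n_repeats = map$n_repeats, n_pulses = map$n_pulses,
               seed = map$seed,
               detection = list(tol = map$detection$tol,
                                tol_prime = map$detection$tol_prime,
                                span_samples = map$detection$span_samples))
  jsonlite::write_json(meta, paste0(path, ".json"), null = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_entrainment_map
#' @export
read_entrainment_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nf <- length(meta$f0_grid); ni <- length(meta$I_grid)
  structure(list(f0_grid = meta$f0_grid, I_grid = meta$I_grid,
                 R = matrix(df$R, nf, ni),
                 locking = matrix(df$label, nf, ni),
                 f_inst = if (all(is.na(df$f_inst))) NULL
                          else matrix(df$f_inst, nf, ni),
                 n_repeats = meta$n_repeats, n_pulses = meta$n_pulses,
                 zeta = meta$zeta,
                 scheme = if (is.null(meta$scheme)) NULL
                          else do.call(cycling_scheme, meta$scheme),
                 fs = meta$fs, model = meta$model, seed = meta$seed,
                 detection = do.call(detection_config, meta$detection)),
            class = "entrainment_map")
}

#' Tabulate analytic tongue widths and relative widths
#'
#' Evaluates the analytic width formulas ([width_p1()], [width_2pm1_2()])
#' and the leading-order relative widths over grids of stimulation
#' amplitude and dithering level, for both tongue families.
#'
#' @param fs base stimulation frequency (Hz).
#' @param p_values integer orders to tabulate per family (default 1:2).
#' @param I_grid amplitudes.
#' @param zeta_grid dithering levels.
#' @param n_sigma escape threshold (default 4).
#' @return data frame with columns `family`, `p`, `q`, `I`, `zeta`,
#'   `n_sigma`, `width_hz`, `relative_width`.
#' @export
#' @examples
#' theory_report(fs = 130, I_grid = 1, zeta_grid = c(0, 0.05, 0.09))
theory_report <- function(fs = 130, p_values = 1:2, I_grid = c(0.3, 0.65, 1),
                          zeta_grid = seq(0, 0.1, by = 0.01), n_sigma = 4) {
  rows <- expand.grid(p = p_values, I = I_grid, zeta = zeta_grid,
                      family = c("p:1", "(2p-1):2"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(k) {
    r <- rows[k, ]
    cfg <- theory_config(n_sigma = n_sigma, zeta = r$zeta, fs = fs)
    if (r$family == "p:1") {
      data.frame(family = r$family, p = r$p, q = 1L, I = r$I, zeta = r$zeta,
                 n_sigma = n_sigma,
                 width_hz = width_p1(r$I, r$p, cfg),
                 relative_width = relative_width_p1(r$p, r$zeta, n_sigma))
    } else {
      data.frame(family = r$family, p = 2L * r$p - 1L, q = 2L, I = r$I,
                 zeta = r$zeta, n_sigma = n_sigma,
                 width_hz = width_2pm1_2(r$I, r$p, cfg),
                 relative_width = relative_width_2pm1_2(r$p, r$zeta,
                                                        n_sigma))
    }
  }))
  rownames(out) <- NULL
  out
}
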