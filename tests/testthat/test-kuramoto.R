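test_that("intrinsic frequencies follow the Lorentzian law", {
  cfg <- kuramoto_config(f0_center = 30, M = 1e4)
  w <- sample_intrinsic_frequencies(cfg, seed = 1)
  # resampling negative draws truncates the law at 0; the analytic median
  # of the truncated Cauchy(30, 20) is the oracle
  q0 <- stats::pcauchy(0, 30, 20)
  med <- stats::qcauchy(q0 + (1 - q0) / 2, 30, 20)
  expect_lt(abs(stats::median(w / (2 * pi)) - med), 1)
  expect_true(all(w >= 0)) # negative draws resampled
  # degenerate width: all oscillators identical
  cfg0 <- kuramoto_config(f0_center = 30, lorentz_width = 0)
  expect_equal(sample_intrinsic_frequencies(cfg0, seed = 1),
               rep(2 * pi * 30, 100))
  # same seed, same draws
  expect_identical(sample_intrinsic_frequencies(cfg, seed = 5),
                   sample_intrinsic_frequencies(cfg, seed = 5))
})

test_that("decoupled noiseless oscillators drift at their own frequency", {
  cfg <- kuramoto_config(f0_center = 20, M = 5, kappa = 0, xi = 0,
                         lorentz_width = 5)
  s <- simulate_kuramoto(cfg, train = NULL, duration = 1, seed = 3)
  # phi_k(t) = phi_k(0) + omega_k * t up to integrator rounding
  n_steps <- ceiling(1 / cfg$dt)
  set.seed(3)
  omega <- sample_intrinsic_frequencies(cfg)
  phi0 <- runif(5, 0, 2 * pi)
  expected <- phi0 + omega * n_steps * cfg$dt
  expect_equal(s$phi_final, expected, tolerance = 1e-9)
})

test_that("stimulation acts only through the phase response curve", {
  tr <- dithered_train(130, 0, 130, waveform = biphasic_waveform())
  cfg_null <- kuramoto_config(f0_center = 40, M = 20,
                              prc = rep(0, 64)) # Z identically zero
  with_stim <- simulate_kuramoto(cfg_null, tr, amplitude = 500, seed = 11)
  no_stim <- simulate_kuramoto(cfg_null, train = NULL,
                               duration = sum(tr$periods), seed = 11)
  expect_equal(with_stim$rho, no_stim$rho, tolerance = 1e-12)
  expect_equal(with_stim$phi_final, no_stim$phi_final, tolerance = 1e-12)
})

test_that("the order parameter modulus stays in [0, 1] and hits 1 when
           all phases coincide", {
  cfg <- kuramoto_config(f0_center = 30)
  s <- simulate_kuramoto(cfg, train = NULL, duration = 0.5, seed = 9)
  expect_true(all(s$rho >= 0 & s$rho <= 1))
  # single oscillator: mean phasor modulus is exactly 1 at every step
  one <- kuramoto_config(f0_center = 30, M = 1)
  s1 <- simulate_kuramoto(one, train = NULL, duration = 0.1, seed = 2)
  expect_true(all(abs(s1$rho - 1) < 1e-12))
})

test_that("the unstimulated default population is partially synchronised", {
  cfg <- kuramoto_config(f0_center = 30)
  s <- simulate_kuramoto(cfg, train = NULL, duration = 3, seed = 17)
  # reference-run regression value pinned at first implementation; the
  # Cauchy-Kuramoto mean field predicts rho ~ sqrt(1 - kappa_c/kappa) with
  # kappa_c = 2 * (2*pi*20), i.e. about 0.5 for the default parameters
  expect_gt(mean(s$rho), 0.35)
  expect_lt(mean(s$rho), 0.75)
  # mean instantaneous frequency close to the distribution centre
  expect_lt(abs(mean_instantaneous_frequency(s) - 30), 4)
})

test_that("population phase is unwrapped and reproducible under seed", {
  cfg <- kuramoto_config(f0_center = 30)
  a <- simulate_kuramoto(cfg, train = NULL, duration = 0.5, seed = 21)
  b <- simulate_kuramoto(cfg, train = NULL, duration = 0.5, seed = 21)
  expect_identical(a$psi, b$psi)
  expect_identical(a$rho, b$rho)
  # no 2*pi jumps between adjacent samples
  expect_lt(max(abs(diff(a$full_psi))), pi)
})

test_that("a resonant 130 Hz train entrains the default population 1:1", {
  tr <- dithered_train(130, 0, 400, waveform = biphasic_waveform())
  cfg <- kuramoto_config(f0_center = 130)
  s <- simulate_kuramoto(cfg, tr, amplitude = 500, seed = 6)
  R <- rotation_number(psi_at_pulses(s, tr))
  expect_equal(R, 1, tolerance = 3e-2)
  # mean instantaneous frequency pinned at the stimulation frequency
  expect_lt(abs(mean_instantaneous_frequency(s) - 130), 5)
})

test_that("halving the temporal resolution leaves summary output stable", {
  cfg1 <- kuramoto_config(f0_center = 30, dt = 1e-4)
  cfg2 <- kuramoto_config(f0_center = 30, dt = 2e-4)
  s1 <- simulate_kuramoto(cfg1, train = NULL, duration = 3, seed = 13)
  s2 <- simulate_kuramoto(cfg2, train = NULL, duration = 3, seed = 13)
  expect_lt(abs(mean(s2$rho) / mean(s1$rho) - 1), 0.05)
})

test_that("too-coarse dt for the pulse waveform is rejected with its
           constraint named", {
  tr <- dithered_train(1000, 0, 50, waveform = biphasic_waveform())
  cfg <- kuramoto_config(f0_center = 30, dt = 1e-4)
  expect_error(simulate_kuramoto(cfg, tr, seed = 1), "positive lobe")
})

test_that("series export includes data columns and config sidecar", {
  cfg <- kuramoto_config(f0_center = 30, M = 10)
  s <- simulate_kuramoto(cfg, train = NULL, duration = 0.05, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_series(s, path)
  df <- read.csv(path)
  expect_named(df, c("t", "rho", "psi", "x"))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$kappa, 350)
  expect_equal(meta$xi, 7.9)
  unlink(c(path, paste0(path, ".json")))
})

test_that("a harmonically rich PRC yields population 1:2 locking that
           dithering destroys faster than 1:1", {
  # conductance-based-neuron-like PRCs carry a second harmonic; that is the
  # component that couples a 130 Hz biphasic train to oscillators near 65 Hz
  f0g <- seq(56, 68, by = 1.5)
  k <- kuramoto_config(f0_center = 60, prc = prc_two_harmonics)
  m0 <- run_sweep(sweep_config("kuramoto", f0g, I_grid = 300, zeta = 0,
                               seed = 5, kuramoto = k))
  n0 <- sum(m0$locking == "1:2", na.rm = TRUE)
  expect_gte(n0, 5) # broad plateau under periodic stimulation
  sc0 <- apply(m0$R_repeats[, 1, ], 1, function(x) diff(range(x)))
  md <- run_sweep(sweep_config("kuramoto", f0g, I_grid = 300, zeta = 0.15,
                               seed = 5, kuramoto = k))
  nd <- sum(md$locking == "1:2", na.rm = TRUE)
  expect_lt(nd, n0) # dithering shrinks the plateau
  scd <- apply(md$R_repeats[, 1, ], 1, function(x) diff(range(x)))
  # repeat-to-repeat scatter in the plateau core grows under dithering
  core <- which(m0$locking[, 1] == "1:2")
  expect_gt(mean(scd[core]), 2 * mean(sc0[core]))
})
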