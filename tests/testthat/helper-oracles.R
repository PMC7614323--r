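# Shared fixtures and independent oracles used across test files.

# Rotation number of the locked ratio measured at one Fig.-7-style parameter
# set of the deterministic sine circle map.
measure_locked_R <- function(f0, I, fs = 130, n = 1e4, seed = 1) {
  cfg <- circle_map_config(f0 = f0, fs = fs, I = I)
  rotation_number(iterate_circle_map(cfg, theta0 = NULL, n = n, seed = seed))
}

# Plateau width measured from a targeted circle-map window sweep.
measure_width <- function(f0_min, f0_max, I, zeta, p, q, seed = 3,
                          step = 0.05, n_pulses = 1e4, n_repeats = 10) {
  cfg <- sweep_config("circle_map", f0_grid = seq(f0_min, f0_max, by = step),
                      I_grid = I, zeta = zeta, n_pulses = n_pulses,
                      n_repeats = n_repeats, seed = seed)
  tongue_width_from_map(run_sweep(cfg), p, q, I)
}

# Number of labelled p:q bins in a window sweep (plateau occupancy).
count_labelled <- function(f0_min, f0_max, I, zeta, label, seed = 3,
                           step = 0.05, n_pulses = 1e4, n_repeats = 10) {
  cfg <- sweep_config("circle_map", f0_grid = seq(f0_min, f0_max, by = step),
                      I_grid = I, zeta = zeta, n_pulses = n_pulses,
                      n_repeats = n_repeats, seed = seed)
  m <- run_sweep(cfg)
  sum(m$locking == label, na.rm = TRUE)
}

# A phase response curve with a second harmonic (as in conductance-based
# neuron models); provides first-order 1:2 coupling that a pure sinusoid
# lacks under temporally extended stimulation.
prc_two_harmonics <- function(theta) sin(theta) + 0.8 * sin(2 * theta + 1)
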