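test_that("p:1 fixed points match the closed-form trap-size formula", {
  # centred case: sin(theta) = 0, stable at pi, unstable at 0, h = pi
  fp <- fixed_points_p1(130, 130, 1, p = 1)
  expect_equal(fp$theta_stable, pi, tolerance = 1e-12)
  expect_equal(fp$theta_unstable, 0, tolerance = 1e-12)
  expect_equal(fp$trap_size, pi, tolerance = 1e-12)
  # off-centre 1:1 (h = pi + 2 arcsin(2*pi*[f0/fs - 1]/I))
  fp <- fixed_points_p1(125, 130, 1, p = 1)
  expect_equal(fp$trap_size, 2.65343826505662, tolerance = 1e-10)
  # 2:1 at the same detuning gives the same trap size (f0/fs < p branch:
  # h = pi + 2 arcsin(2*pi*[f0/fs - p]/I), the arcsin argument is negative)
  fp2 <- fixed_points_p1(255, 130, 1, p = 2)
  expect_equal(fp2$trap_size, pi + 2 * asin(2 * pi * (255 / 130 - 2)),
               tolerance = 1e-10)
  expect_equal(fp2$trap_size, fp$trap_size, tolerance = 1e-10)
})

test_that("(2p-1):2 fixed points match the one-harmonic doubled map", {
  # tongue centre: h = pi/2
  fp <- fixed_points_2pm1_2(65, 130, 1, p = 1)
  expect_equal(fp$trap_size, pi / 2, tolerance = 1e-12)
  # Fig.-7-style off-centre cases
  fp <- fixed_points_2pm1_2(63, 130, 1.5, p = 1)
  expect_equal(fp$trap_size, 1.39809125612521, tolerance = 1e-10)
  fp32 <- fixed_points_2pm1_2(193, 130, 1.5, p = 2)
  expect_gt(fp32$trap_size, 0)
  expect_lt(fp32$trap_size, pi)
})

test_that("analytic fixed points agree with brute-force root-finding", {
  set.seed(10)
  for (k in 1:25) {
    p <- sample(1:3, 1)
    I <- runif(1, 0.2, 1.8)
    # draw a detuning inside the existence region of each family
    f0 <- 130 * (p + runif(1, -0.9, 0.9) * I / (2 * pi))
    fp <- fixed_points_p1(f0, 130, I, p)
    num <- fixed_points_numeric(f0, 130, I, p, q = 1)
    expect_lt(min(abs(num$roots[num$stable] - fp$theta_stable)), 1e-8)
    expect_lt(min(abs(num$roots[!num$stable] - fp$theta_unstable)), 1e-8)
    expect_lt(abs(num$trap_size - fp$trap_size), 1e-8)

    f0h <- 130 * ((2 * p - 1) / 2 + runif(1, -0.9, 0.9) * I^2 / (8 * pi))
    fph <- fixed_points_2pm1_2(f0h, 130, I, p)
    numh <- fixed_points_numeric(f0h, 130, I, p, q = 2, map = "approximate")
    expect_lt(min(abs(numh$roots[numh$stable] - fph$theta_stable)), 1e-8)
    expect_lt(abs(numh$trap_size - fph$trap_size), 1e-8)
  }
})

test_that("the exact doubled map approaches the one-harmonic form at small I", {
  # approximation error shrinks with I: compare at matched relative detuning
  err <- vapply(c(0.4, 0.2, 0.1), function(I) {
    f0 <- 130 * (0.5 - 0.48 * I^2 / (8 * pi))
    fp <- fixed_points_2pm1_2(f0, 130, I, p = 1)
    ex <- fixed_points_numeric(f0, 130, I, p = 1, q = 2, map = "exact")
    abs(ex$trap_size / fp$trap_size - 1)
  }, numeric(1))
  expect_true(all(diff(err) < 0))  # error decreases as I decreases
  expect_lt(err[3], 0.05)
})

test_that("locking precondition failures signal a no_locking condition", {
  expect_error(fixed_points_p1(150, 130, 0.3, p = 1), class = "no_locking")
  expect_error(fixed_points_2pm1_2(75, 130, 0.5, p = 1),
               class = "no_locking")
})

test_that("tongue boundaries reduce to the deterministic edges at zeta = 0", {
  cfg0 <- theory_config(zeta = 0, fs = 130)
  expect_equal(boundary_p1(135, 1, cfg0), 0.241660973353062,
               tolerance = 1e-12)
  expect_equal(boundary_p1(130, 1, cfg0), 0)
  expect_equal(boundary_2pm1_2(67, 1, cfg0), 0.621817945515322,
               tolerance = 1e-12)
  expect_equal(boundary_2pm1_2(65, 1, cfg0), 0)
})

test_that("zeta = 0 boundaries coincide with simulated locking onsets", {
  # 1:1 at f0 = 135: locking exists just above the boundary I, not below
  Ib <- boundary_p1(135, 1, theory_config(zeta = 0, fs = 130))
  above <- measure_locked_R(135, Ib * 1.1)
  expect_equal(above, 1, tolerance = 6e-4)
  below <- measure_locked_R(135, Ib * 0.9)
  expect_gt(abs(below - 1), 6e-4)
  # 1:2 at f0 = 67 (boundary from the approximate doubled map: allow slack)
  Ib2 <- boundary_2pm1_2(67, 1, theory_config(zeta = 0, fs = 130))
  expect_equal(measure_locked_R(67, Ib2 * 1.25), 0.5, tolerance = 6e-4)
  expect_gt(abs(measure_locked_R(67, Ib2 * 0.75) - 0.5), 6e-4)
})

test_that("analytic widths match their zeta = 0 limits and decay with zeta", {
  cfg0 <- theory_config(zeta = 0, fs = 130)
  expect_equal(width_p1(1, 1, cfg0), 130 / pi, tolerance = 1e-12)
  expect_equal(width_p1(1, 5, cfg0), 130 / pi, tolerance = 1e-12)
  expect_equal(width_2pm1_2(1, 1, cfg0), 130 / (4 * pi), tolerance = 1e-12)
  cfg9 <- theory_config(zeta = 0.09, fs = 130)
  expect_equal(width_p1(1, 1, cfg9), 14.2451480697493, tolerance = 1e-10)
  # strictly decreasing in zeta until clamped at zero
  zg <- seq(0, 0.2, by = 0.005)
  for (fam in list(function(z) width_p1(1, 1, theory_config(zeta = z, fs = 130)),
                   function(z) width_2pm1_2(1, 1, theory_config(zeta = z, fs = 130)))) {
    w <- vapply(zg, fam, numeric(1))
    pos <- w > 0
    expect_true(all(diff(w[pos]) < 0))
    expect_true(all(w >= 0))
  }
  # a (2p-1):2 or p:1 (p > 1) width dies at strictly smaller zeta than 1:1
  death <- function(fam) zg[which(vapply(zg, fam, numeric(1)) == 0)[1]]
  d11 <- death(function(z) width_p1(1, 1, theory_config(zeta = z, fs = 130)))
  d21 <- death(function(z) width_p1(1, 2, theory_config(zeta = z, fs = 130)))
  d12 <- death(function(z) width_2pm1_2(1, 1, theory_config(zeta = z, fs = 130)))
  expect_lt(d21, d11)
  expect_lt(d12, d11)
})

test_that("relative widths reproduce the selective-entrainment ordering", {
  expect_equal(relative_width_p1(1, 0), 1)
  expect_equal(relative_width_2pm1_2(3, 0), 1)
  for (z in c(0.01, 0.03, 0.05)) {
    expect_lt(relative_width_p1(2, z), relative_width_p1(1, z))
    expect_lt(relative_width_2pm1_2(1, z), relative_width_p1(1, z))
    expect_lt(relative_width_2pm1_2(2, z), relative_width_2pm1_2(1, z))
  }
  expect_equal(relative_width_p1(1, 10), 0)  # clamped
  # small-zeta ratios agree with full-width ratios as I -> 0
  z <- 0.02
  for (p in 1:2) {
    full <- width_p1(1e-4, p, theory_config(zeta = z, fs = 130)) /
      width_p1(1e-4, p, theory_config(zeta = 0, fs = 130))
    expect_equal(full, relative_width_p1(p, z), tolerance = 1e-6)
    full2 <- width_2pm1_2(1e-4, p, theory_config(zeta = z, fs = 130)) /
      width_2pm1_2(1e-4, p, theory_config(zeta = 0, fs = 130))
    expect_equal(full2, relative_width_2pm1_2(p, z), tolerance = 1e-6)
  }
})

test_that("boundary and width functions are mutually consistent", {
  # the two f0 roots of boundary_p1(f0) = I are separated by width_p1(I)
  # up to the O(zeta^4) Taylor truncation
  cfg <- theory_config(zeta = 0.01, fs = 130)
  I <- 0.5
  f <- function(f0) boundary_p1(f0, 1, cfg) - I
  hi <- stats::uniroot(f, c(130.5, 145), tol = 1e-12)$root
  lo <- stats::uniroot(f, c(115, 129.5), tol = 1e-12)$root
  expect_equal(hi - lo, width_p1(I, 1, cfg), tolerance = 1e-3)
})

test_that("tongue_spec and theory_config validate their invariants", {
  expect_error(tongue_spec(2, 4), "coprime")
  expect_warning(tongue_spec(2, 3), "analytic")
  expect_silent(tongue_spec(3, 2))
  expect_error(theory_config(n_sigma = 2), "n_sigma")
})
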