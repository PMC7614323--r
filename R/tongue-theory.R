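#' Locking-ratio and theory configuration objects
#'
#' `tongue_spec(p, q)` describes a p:q frequency-locking ratio (p oscillator
#' cycles per q stimulation pulses); p and q must be coprime. The analytic
#' theory in this package covers the two most prominent tongue families of
#' the sine circle map: q = 1 (any p >= 1) and q = 2 with odd p.
#'
#' `theory_config(n_sigma, zeta, fs)` holds the parameters of the stochastic
#' escape argument behind the analytic tongue boundaries and widths:
#' frequency locking survives dithering while the trap between the stable and
#' unstable fixed points is larger than `n_sigma` standard deviations of the
#' random jump distribution. `n_sigma = 4` corresponds to at least 99.99% of
#' locking cycles not escaping the periodic orbit; values below 3 are
#' rejected.
#'
#' @param p,q positive coprime integers.
#' @param n_sigma escape threshold in jump-distribution standard deviations,
#'   `>= 3` (default 4).
#' @param zeta dithering level, `>= 0`.
#' @param fs base stimulation frequency (Hz).
#' @return `tongue_spec` / `theory_config` objects.
#' @export
#' @examples
#' tongue_spec(3, 2)
#' theory_config(zeta = 0.09, fs = 130)
tongue_spec <- function(p, q) {
  if (p < 1 || q < 1 || p != round(p) || q != round(q))
    stop("`p` and `q` must be positive integers")
  if (gcd2(p, q) != 1) stop("`p` and `q` must be coprime")
  if (!(q == 1 || (q == 2 && p %% 2 == 1)))
    warning("analytic theory only covers q = 1 and q = 2 with odd p; ",
            "other ratios can only be measured from sweeps")
  structure(list(p = as.integer(p), q = as.integer(q)), class = "tongue_spec")
}

#' @rdname tongue_spec
#' @export
theory_config <- function(n_sigma = 4, zeta = 0, fs = 130) {
  check_scalar(n_sigma, "n_sigma", 3)
  check_scalar(zeta, "zeta", 0)
  check_scalar(fs, "fs", 0, strict = TRUE)
  structure(list(n_sigma = n_sigma, zeta = zeta, fs = fs),
            class = "theory_config")
}

no_locking_error <- function(msg) {
  stop(structure(class = c("no_locking", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Fixed points and trap size for p:1 locking of the sine circle map
#'
#' Solves \eqn{\sin\theta = 2\pi(p - f_0/f_s)/I} for the stable and unstable
#' fixed points of the map composed with the `-2p*pi` shift, i.e. p complete
#' oscillator rotations per stimulation cycle. Stability is judged by
#' \eqn{|1 + I\cos\theta| < 1}. The trap size `h` is the shortest circular
#' distance between the two fixed points; a random phase jump clearing the
#' trap breaks locking.
#'
#' @param f0 oscillator natural frequency (Hz).
#' @param fs base stimulation frequency (Hz).
#' @param I stimulation magnitude (`> 0`).
#' @param p positive integer (locking order).
#' @return an object of class `fixed_point_pair`: list with `theta_stable`,
#'   `theta_unstable` (radians in `[0, 2*pi)`) and `trap_size` (radians).
#'   Signals a condition of class `no_locking` when no fixed points exist
#'   (`|2*pi*(f0/fs - p)| > I`).
#' @seealso [fixed_points_2pm1_2()], [fixed_points_numeric()]
#' @export
#' @examples
#' fixed_points_p1(125, 130, 1, p = 1)
fixed_points_p1 <- function(f0, fs, I, p = 1) {
  check_scalar(I, "I", 0, strict = TRUE)
  s <- 2 * pi * (p - f0 / fs) / I
  if (abs(s) > 1)
    no_locking_error(sprintf(
      "no p:1 locking: |2*pi*(f0/fs - p)| = %.4g exceeds I = %.4g",
      abs(s) * I, I))
  theta_unstable <- wrap_2pi(asin(s))
  theta_stable <- wrap_2pi(pi - asin(s))
  structure(list(theta_stable = theta_stable,
                 theta_unstable = theta_unstable,
                 trap_size = circ_dist(theta_stable, theta_unstable),
                 p = p, q = 1L),
            class = "fixed_point_pair")
}

#' Fixed points and trap size for (2p-1):2 locking (one-harmonic doubled map)
#'
#' Uses the small-I, near-centre approximation of the twice-iterated sine
#' circle map,
#' \deqn{\theta_{n+2} \approx \theta_n + 4\pi f_0/f_s -
#'       (I^2/2)\sin 2\theta_n,}
#' whose fixed points satisfy \eqn{\sin 2\theta = 8\pi\delta/I^2} with
#' \eqn{\delta = f_0/f_s - (2p-1)/2}. There are two stable and two unstable
#' fixed points; the distances from each stable point to its nearest unstable
#' point are equal, so a single representative pair is returned with the trap
#' size \eqn{h \approx \pi/2 - |\arcsin(8\pi\delta/I^2)|}.
#'
#' @inheritParams fixed_points_p1
#' @return a `fixed_point_pair` (see [fixed_points_p1()]); signals
#'   `no_locking` when `|4*pi*(f0/fs - (2p-1)/2)| > I^2/2`.
#' @export
#' @examples
#' fixed_points_2pm1_2(63, 130, 1.5, p = 1)
fixed_points_2pm1_2 <- function(f0, fs, I, p = 1) {
  check_scalar(I, "I", 0, strict = TRUE)
  delta <- f0 / fs - (2 * p - 1) / 2
  s2 <- 8 * pi * delta / I^2
  if (abs(s2) > 1)
    no_locking_error(sprintf(
      "no (2p-1):2 locking: |4*pi*delta| = %.4g exceeds I^2/2 = %.4g",
      abs(4 * pi * delta), I^2 / 2))
  a <- asin(s2) / 2
  theta_stable <- wrap_2pi(a)
  unstables <- wrap_2pi(c(pi / 2 - a, 3 * pi / 2 - a))
  d <- circ_dist(theta_stable, unstables)
  k <- which.min(d)
  structure(list(theta_stable = theta_stable,
                 theta_unstable = unstables[k],
                 trap_size = d[k],
                 p = as.integer(2 * p - 1), q = 2L),
            class = "fixed_point_pair")
}

#' @export
print.fixed_point_pair <- function(x, ...) {
  cat(sprintf(
    "%d:%d fixed points: stable %.5f, unstable %.5f, trap size h = %.5f rad\n",
    x$p, x$q, x$theta_stable, x$theta_unstable, x$trap_size))
  invisible(x)
}

#' Brute-force fixed points of the (composed) circle map
#'
#' Independent numerical route to the fixed points returned by
#' [fixed_points_p1()] and [fixed_points_2pm1_2()]. For `q = 1` the exact
#' fixed-point condition `F(theta) - theta - 2*p*pi = 0` is bracketed on a
#' dense grid and polished with [stats::uniroot()]. For `q = 2`,
#' `map = "approximate"` solves the one-harmonic doubled-map condition
#' (the same equation the analytic path inverts in closed form), while
#' `map = "exact"` composes the full map twice — useful to quantify the
#' approximation error at moderate I.
#'
#' @inheritParams fixed_points_p1
#' @param q 1 or 2.
#' @param map for `q = 2`: `"approximate"` (one-harmonic doubled map) or
#'   `"exact"` (full composed map).
#' @param grid_n number of grid points used for sign-change bracketing.
#' @return list with `roots` (all fixed points in `[0, 2*pi)`), `stable`
#'   (logical per root: the displacement derivative is negative there) and
#'   `trap_size` (shortest circular stable-unstable distance).
#' @export
fixed_points_numeric <- function(f0, fs, I, p = 1, q = 1,
                                 map = c("approximate", "exact"),
                                 grid_n = 20000L) {
  map <- match.arg(map)
  ratio <- f0 / fs
  # Roots of the displacement g(theta) = (composed map)(theta) - theta -
  # 2*p*pi; a root is attracting when g' < 0 there (the slow-dynamics
  # criterion; overshoot instability at strong forcing lies outside the
  # theory's validity range).
  if (q == 1) {
    g <- function(th) 2 * pi * ratio + I * sin(th) - 2 * p * pi
    dg <- function(th) I * cos(th)
  } else if (q == 2 && map == "approximate") {
    g <- function(th) 4 * pi * ratio - I^2 / 2 * sin(2 * th) -
      2 * (2 * p - 1) * pi
    dg <- function(th) -I^2 * cos(2 * th)
  } else if (q == 2) {
    FF <- function(th) th + 2 * pi * ratio + I * sin(th)
    g <- function(th) FF(FF(th)) - th - 2 * (2 * p - 1) * pi
    dg <- function(th) (1 + I * cos(FF(th))) * (1 + I * cos(th)) - 1
  } else stop("only q = 1 and q = 2 are supported")

  grid <- seq(0, 2 * pi, length.out = grid_n + 1L)
  vals <- g(grid)
  sgn <- sign(vals)
  idx <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-13)$root
  }, numeric(1))
  roots <- wrap_2pi(roots)
  # drop duplicates from wrapping 2*pi -> 0
  if (length(roots) > 1) {
    o <- order(roots)
    roots <- roots[o]
    keep <- c(TRUE, diff(roots) > 1e-9)
    if (circ_dist(roots[1], roots[length(roots)]) < 1e-9)
      keep[length(roots)] <- FALSE
    roots <- roots[keep]
  }
  if (length(roots) == 0)
    no_locking_error("no fixed points found numerically")
  stable <- dg(roots) < 0
  trap <- NA_real_
  if (any(stable) && any(!stable)) {
    trap <- min(outer(roots[stable], roots[!stable], circ_dist))
  }
  list(roots = roots, stable = stable, trap_size = trap)
}

#' Analytic Arnold tongue boundaries under dithered stimulation
#'
#' Tongue boundaries follow from equating the trap size h with `n_sigma`
#' standard deviations of the random jump distribution. For p:1 tongues the
#' jump standard deviation is \eqn{\sigma = 2\pi (f_0/f_s)\zeta} and
#' \deqn{I(f_0) = \left|\frac{2\pi(f_0/f_s - p)}
#'   {\sin(\pi[(f_0/f_s)n_\sigma\zeta - 1/2])}\right|.}
#' For (2p-1):2 tongues the two-step jump has
#' \eqn{\sigma = 2\sqrt2\,\pi (f_0/f_s)\zeta} and
#' \deqn{I(f_0) = \left|\frac{8\pi(f_0/f_s - (2p-1)/2)}
#'   {\sin(\pi[2\sqrt2 (f_0/f_s) n_\sigma\zeta - 1/2])}\right|^{1/2}.}
#' With `zeta = 0` these reduce to the deterministic tongue edges
#' \eqn{I = 2\pi|f_0/f_s - p|} and \eqn{I = (8\pi|f_0/f_s-(2p-1)/2|)^{1/2}}.
#'
#' @param f0 natural frequency (Hz); vectorised.
#' @param p positive integer locking order.
#' @param cfg a [theory_config()].
#' @return boundary stimulation magnitude(s) `|I|` at `f0`.
#' @export
#' @examples
#' boundary_p1(135, p = 1, theory_config(zeta = 0, fs = 130))
boundary_p1 <- function(f0, p = 1, cfg = theory_config()) {
  stopifnot(inherits(cfg, "theory_config"))
  r <- f0 / cfg$fs
  denom <- sin(pi * (r * cfg$n_sigma * cfg$zeta - 0.5))
  abs(2 * pi * (r - p) / denom)
}

#' @rdname boundary_p1
#' @export
boundary_2pm1_2 <- function(f0, p = 1, cfg = theory_config()) {
  stopifnot(inherits(cfg, "theory_config"))
  r <- f0 / cfg$fs
  denom <- sin(pi * (2 * sqrt(2) * r * cfg$n_sigma * cfg$zeta - 0.5))
  sqrt(abs(8 * pi * (r - (2 * p - 1) / 2) / denom))
}

#' Analytic Arnold tongue widths under dithered stimulation
#'
#' Small-zeta, small-I approximations of the frequency width of the p:1 and
#' (2p-1):2 tongue families of the stochastic sine circle map:
#' \deqn{\Delta f^{p:1}(I,\zeta) = \frac{f_s I}{\pi}
#'   \left(1 - \frac{n_\sigma^2\zeta^2}{8}[4p^2\pi^2 + I^2]\right),}
#' \deqn{\Delta f^{(2p-1):2}(I,\zeta) = \frac{f_s I^2}{4\pi}
#'   \left(1 - \frac{n_\sigma^2\zeta^2}{16}[16(2p-1)^2\pi^2 + I^4]\right).}
#' Negative values (beyond the validity range of the Taylor expansion) are
#' clamped to 0: the tongue is destroyed.
#'
#' @param I stimulation magnitude (`> 0`); vectorised.
#' @param p positive integer locking order.
#' @param cfg a [theory_config()].
#' @return tongue width(s) in Hz (`>= 0`).
#' @export
#' @examples
#' width_p1(1, p = 1, theory_config(zeta = 0, fs = 130)) # fs/pi
width_p1 <- function(I, p = 1, cfg = theory_config()) {
  stopifnot(inherits(cfg, "theory_config"))
  w <- cfg$fs * I / pi *
    (1 - cfg$n_sigma^2 * cfg$zeta^2 / 8 * (4 * p^2 * pi^2 + I^2))
  pmax(w, 0)
}

#' @rdname width_p1
#' @export
width_2pm1_2 <- function(I, p = 1, cfg = theory_config()) {
  stopifnot(inherits(cfg, "theory_config"))
  w <- cfg$fs * I^2 / (4 * pi) *
    (1 - cfg$n_sigma^2 * cfg$zeta^2 / 16 *
       (16 * (2 * p - 1)^2 * pi^2 + I^4))
  pmax(w, 0)
}

#' Relative tongue width under dithering (dithered / periodic)
#'
#' Leading-order (in I) ratio of the tongue width with dithered stimulation
#' to the width with perfectly periodic stimulation:
#' \deqn{\frac{\Delta f^{p:1}(I,\zeta)}{\Delta f^{p:1}(I,0)} \approx
#'   1 - \frac{n_\sigma^2\pi^2 p^2}{2}\zeta^2, \qquad
#'   \frac{\Delta f^{(2p-1):2}(I,\zeta)}{\Delta f^{(2p-1):2}(I,0)} \approx
#'   1 - n_\sigma^2\pi^2(2p-1)^2\zeta^2.}
#' For every p > 1 in the first family and every p >= 1 in the second, the
#' relative shrinkage exceeds that of the 1:1 tongue — the selective
#' entrainment guarantee. Values are clamped to `[0, 1]`.
#'
#' @param p positive integer locking order.
#' @param zeta dithering level; vectorised.
#' @param n_sigma escape threshold (default 4).
#' @return dimensionless ratio(s) in `[0, 1]`.
#' @export
#' @examples
#' relative_width_p1(1, zeta = 0.05)
#' relative_width_2pm1_2(1, zeta = 0.05) # shrinks faster than 1:1
relative_width_p1 <- function(p, zeta, n_sigma = 4) {
  pmin(pmax(1 - n_sigma^2 * pi^2 * p^2 * zeta^2 / 2, 0), 1)
}

#' @rdname relative_width_p1
#' @export
relative_width_2pm1_2 <- function(p, zeta, n_sigma = 4) {
  pmin(pmax(1 - n_sigma^2 * pi^2 * (2 * p - 1)^2 * zeta^2, 0), 1)
}
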