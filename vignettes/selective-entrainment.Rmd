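---
title: "Selective neural entrainment by dithered stimulation: models, theory and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective neural entrainment by dithered stimulation: models, theory and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ditherstim)
```

## The problem

Rhythmic brain stimulation (deep brain stimulation, sensory or transcranial
stimulation) can entrain a neural rhythm at the stimulation frequency — but
also, counter-intuitively, at rational multiples of it: a rhythm near half
the stimulation rate can lock 1:2, one near double the rate 2:1, and so on.
Such sub- and super-harmonic entrainment can be harmful (for example,
entrainment of finely tuned gamma rhythms at half of a 130 Hz therapy rate).
*Dithered stimulation* addresses this with an open-loop trick: every
inter-pulse interval is perturbed to $(1 + z_n)/f_s$ with
$z_n \sim \mathcal N(0, \zeta^2)$. The standard deviation $\zeta$ — the
*dithering level* — is the only new parameter. Because higher-order Arnold
tongues are intrinsically less stable than the 1:1 tongue, a moderate
$\zeta$ destroys them while 1:1 entrainment near $f_s$ survives: selective
entrainment.

`ditherstim` implements the two models in which this is studied, the
closed-form tongue theory, the entrainment metrics, and reproducible
parameter sweeps.

## Models

### Sine circle map

A single neural oscillator of natural frequency $f_0$ receiving impulses at
rate $f_s$ is reduced to the phase map

$$\theta_{n+1} = \theta_n + 2\pi \frac{f_0}{f_s}(1 + z_n) + I\sin\theta_n,$$

where $\theta_n$ is the phase just before pulse $n$, $I$ the stimulation
magnitude, and $z_n$ the dithering perturbation ($z_n \equiv 0$ gives the
deterministic map). The sinusoid is the map's phase response curve (PRC).
Phases are stored unwrapped in double precision; wrapping is applied only
where needed. Normal draws are not truncated here: a draw with
$1 + z_n < 0$ simply produces a negative increment, which the map formula
tolerates (continuous-time trains are different, see below).

```{r circle-example}
cfg <- circle_map_config(f0 = 125, fs = 130, I = 1)
traj <- iterate_circle_map(cfg, theta0 = 0.5, n = 1e4)
rotation_number(traj) # 1:1 locked
```

### Kuramoto population

Brain signals are better described by populations of coupled oscillators.
For each natural frequency $f_0$ the package simulates $M = 100$ noisy
phase oscillators with homogeneous sinusoidal coupling in the
order-parameter form

$$d\varphi_k = \left[\omega_k + \kappa\rho\sin(\psi - \varphi_k)
  + I(t) Z(\varphi_k)\right] dt + \xi\, dW_k,$$

with $\rho e^{i\psi}$ the population mean phasor, intrinsic frequencies
$\omega_k/2\pi$ Cauchy-distributed around $f_0$ (scale 20 Hz, negative
draws resampled), $\kappa = 350$ rad/s, $\xi = 7.9$ rad/$\sqrt{\mathrm s}$,
integrated by Euler–Maruyama at $dt = 10^{-4}$ s. These defaults give a
partially synchronised population ($\rho \approx 0.5$) whose output
$X = \rho\cos\psi$ resembles a noisy neural oscillation. The attractive
order-parameter coupling form is the one integrated; the Cauchy "width
20 Hz" is taken as the scale (half width at half maximum) parameter.

$I(t)$ is a charge-balanced biphasic square train: a positive lobe over
20% of each period and a negative lobe over the remainder whose amplitude
makes the per-period integral exactly zero. For continuous-time trains,
period draws with $1 + z \le 0$ are resampled (probability under
$10^{-6}$ for $\zeta \le 0.2$, so the distortion is negligible). The PRC
is pluggable: `"sin"` (exact fast path), any 2$\pi$-periodic function, or
a numeric table (e.g. a tabulated Hodgkin–Huxley PRC) evaluated by linear
interpolation on a 1024-point grid. The non-sinusoidal *coupling* function
remains a hook only.

## Tongue theory

For the stochastic map, locking at $p$:1 corresponds to a stable/unstable
fixed-point pair of the once-iterated map; locking at $(2p-1)$:2 to fixed
points of the twice-iterated map, which near the tongue centre reduces to
the one-harmonic form $\theta_{n+2} \approx \theta_n + 4\pi f_0/f_s -
(I^2/2)\sin 2\theta_n$. Locking survives dithering while the *trap* $h$ —
the circular distance from the stable to the nearest unstable fixed point —
exceeds $n_\sigma$ standard deviations of the per-iteration random jump
($\sigma = 2\pi (f_0/f_s)\zeta$ for one step, $2\sqrt2\,\pi(f_0/f_s)\zeta$
for two). The default $n_\sigma = 4$ keeps at least 99.99% of locking
cycles inside the trap; values below 3 are rejected. Equating $h$ with
$n_\sigma\sigma$ yields boundaries, widths and relative widths:

$$\Delta f^{p:1} = \frac{f_s I}{\pi}\Big(1 -
  \frac{n_\sigma^2\zeta^2}{8}[4p^2\pi^2 + I^2]\Big), \qquad
  \Delta f^{(2p-1):2} = \frac{f_s I^2}{4\pi}\Big(1 -
  \frac{n_\sigma^2\zeta^2}{16}[16(2p-1)^2\pi^2 + I^4]\Big).$$

Negative values are clamped to zero (tongue destroyed) — the Taylor
expansions in $\zeta$ and $I$ are not meaningful beyond that point. The
key ordering is in the relative widths: every higher-order family shrinks
faster in $\zeta$ than 1:1, for any stimulation frequency.

```{r theory}
theory_report(fs = 130, p_values = 1, I_grid = 1,
              zeta_grid = c(0, 0.05, 0.09))
```

Only the $q \in \{1, 2\}$ families have closed forms (these are the
prominent ones); other ratios are measured empirically from sweeps. The
analytic fixed points are checked against an independent numerical route
(`fixed_points_numeric()`: dense-grid bracketing plus root polishing of the
same defining equations) to $10^{-8}$; the exact twice-composed map is also
exposed to quantify the one-harmonic approximation error at moderate $I$.

## Entrainment metrics and the plateau detector

The rotation number $R = (\phi_N - \phi_0)/(2\pi N)$ is measured from
unwrapped phases just before each pulse ($\theta_n$ for the map, the
order-parameter phase $\psi(t_n)$ for populations). A natural-frequency bin
counts as $p$:$q$ locked when $|R - p/q| < \mathrm{tol}$ and the
LOWESS-smoothed derivative of $R$ along $f_0$ stays below
$\mathrm{tol}'$: circle-map tolerances $6\times10^{-4}$ / $10^{-2}$,
population tolerances $3\times10^{-2}$ / $2\times10^{-2}$. Derivatives are
central finite differences (one-sided at the edges) smoothed by
local-linear tricube LOWESS over a 4-sample span; the span is kept at 4
samples when grids are coarsened (a fixed sample count, not a fixed Hz
window, preserves the smoother's behaviour across resolutions). Tongue width at an
amplitude is the number of labelled bins times the bin width.

Two deliberate choices where the design was genuinely open:

* **Per-repeat detection.** Sweeps apply the plateau criterion to *every*
  repeat, not to the repeat-averaged curve. At a dithering-destroyed tongue
  the phase still escapes symmetrically, so the repeat-averaged $R$ can
  remain within tolerance of $p/q$ over a narrow band at any grid
  resolution even though individual repeats wander; requiring all repeats
  to lock rejects such statistical pinning while leaving true plateaus
  (where each repeat is trapped) untouched. The averaged curve is still
  what maps store and export.
* **Derivative threshold.** The stated $\mathrm{tol}'$ exceeds the
  unlocked diagonal slope $1/f_s \approx 7.7\times10^{-3}$ at 130 Hz, so
  the derivative condition alone cannot reject unlocked regions; rejection
  is carried by the tight rotation-number tolerance and the per-repeat
  rule. The thresholds themselves are left at their standard values.

Initial conditions: each repeat draws its initial phase uniformly on
$[0, 2\pi)$ from its own seeded stream (varying both the initial phase and the noise
realisation between repeats makes repeats informative in the
deterministic case too). No
burn-in is discarded by default: with $10^4$ pulses the transient
contributes $O(1/N)$ to $R$, below every tolerance used (a `burn_in`
option exists).

## Pulse trains and device-implementable dithering

Implantable stimulators often cannot draw Gaussian periods. The package
therefore also generates trains that toggle within a finite frequency set
$\{f_{s,1}, \ldots, f_{s,n}\}$ whose *periods* are equally spaced
(period-uniform, hence frequency-skewed) around the base period: random
cycling (uniform independent choice per period), deterministic cycling
(lowest frequency first, wrapping), and slow deterministic cycling (hold
each frequency $N_r$ periods). The equivalent dithering level of a set is
the standard deviation of the uniform period distribution over its range
divided by the mean period; the 100–185.7 Hz set used throughout emulates
$\zeta = 0.17$, and holding each of its frequencies for $N_r = 15$ periods
means switching every 81–150 ms. Reference device tables are not
bundled; sets are constructed as equally spaced periods over a stated
frequency range, which is all the cycling schemes require.

```{r trains}
fset <- build_frequency_set(100, 185.7, 13)
round(equivalent_zeta(fset), 2)
switching_interval(fset, N_r = 15)
```

## What the generators emulate — and what they do not

The synthetic inputs are the study conditions themselves: there is no
external data. The circle map represents uncoupled oscillators with a
purely sinusoidal PRC and instantaneous pulses; the population model adds
coupling, intrinsic noise, frequency heterogeneity and temporally extended
charge-balanced pulses. Neither includes synaptic plasticity,
multi-population network effects, evoked resonant activity, or amplitude
dynamics — so passing tests demonstrate the selective-entrainment
mechanism in these phase models, not a clinical prediction.

Two model-physics findings from building the package are worth recording:

* At the exact tongue centre $f_0 = f_s/2$, a sliver (a few tenths of a
  Hz) of genuine 1:2 locking survives dithering levels that destroy the
  rest of the tongue: escapes there are rare and symmetric, so every
  repeat's rotation number stays within the circle-map tolerance. The
  1:2 tongue is the hardest higher-order tongue to destabilise, and its
  destruction is best stated as a ~96% width collapse rather than literal
  emptiness at $\zeta = 0.09$.
* With a temporally extended charge-balanced waveform, first-order
  subharmonic forcing cancels exactly over two stimulation periods, and a
  pure sinusoid PRC has no second harmonic: the population model then
  shows *no* 1:2 locking at any amplitude. Population-level subharmonic
  entrainment requires a harmonically richer PRC (as conductance-based
  neuron models have); the package's population selectivity test uses
  $Z(\theta) = \sin\theta + 0.8\sin(2\theta + 1)$ for exactly this reason,
  and with it a clean 1:2 plateau appears and is degraded by dithering at
  $\zeta = 0.15$ while 1:1 persists.

## Numerical choices

* Map iteration and the population integrator are compiled (Rcpp); both
  draw from R's RNG so a single `set.seed()` governs reproducibility.
* Sweep cells derive per-(bin, amplitude, repeat) seeds by a Lehmer-style
  integer mix (`cell_seed()`), so refining a grid leaves existing cells'
  streams unchanged.
* Desk-scale sweep defaults are targeted windows at 0.05 Hz (map) or
  1.5–2.5 Hz (population) resolution with 10 × 10⁴ and 5 × 400
  repeats × pulses respectively — the standard repeat/pulse protocol on
  reduced grids; full-range grids are a configuration choice away.
* Stimulation amplitude for populations scales a unit biphasic waveform;
  in the population sweeps shipped here, amplitudes of a few hundred rad/s
  correspond to per-pulse collective phase advances of order one radian
  (the regime where the map and population pictures align). The integrator
  requires at least 10 steps across the positive lobe at the nominal
  period and rejects coarser `dt` with an explicit error.
* `stats::lowess` (tricube local-linear, no robustness iterations)
  implements the smoother; on exactly linear data it returns the data, a
  property the tests pin.
* Degenerate inputs: `zeta = 0` reproduces the deterministic paths
  bitwise; `lorentz_width = 0` gives identical oscillators; waveform
  charge balance holds to $10^{-12}$ relative.

## Known limitations

The analytic widths are leading-order in $\zeta$ and $I$ and degrade near
their clamping point; the $(2p-1)$:2 family uses the one-harmonic
approximation of the doubled map (exact-map fixed points are available for
error control). No Hodgkin–Huxley PRC table or coupling function is bundled; the sinusoidal default
reproduces 1:1 physics faithfully but cannot produce population
subharmonics (see above). PLV against the stimulation train uses a linear
phase ramp per inter-pulse interval as the train phase reference — a
convention this package defines.
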