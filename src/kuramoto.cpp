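#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation of a 2*pi-periodic table sampled at 2*pi*j/L,
// j = 0..L-1.
static inline double prc_lookup(const double *tab, int L, double theta) {
  const double twopi = 2.0 * M_PI;
  double x = theta - twopi * std::floor(theta / twopi);
  if (x < 0.0) x += twopi;
  if (x >= twopi) x = 0.0;
  double pos = x * L / twopi;
  int j = (int)pos;
  double w = pos - j;
  int j1 = (j + 1 == L) ? 0 : j + 1;
  return tab[j] * (1.0 - w) + tab[j1] * w;
}

// Euler-Maruyama integration of the order-parameter form of a stimulated
// Kuramoto population:
//   dphi_k = [omega_k + kappa*rho*sin(psi - phi_k) + I(t)*Z(phi_k)] dt
//            + xi dW_k
// rho and psi are recomputed from the current phases at every step and
// recorded *before* the step update (state at t_j = (j-1)*dt).
// stim[j] is the stimulation waveform value held over step j.
// prc_table of length 0 selects the exact sinusoidal PRC Z = sin(theta);
// otherwise Z is linearly interpolated from the table.
// psi is returned unwrapped. Uses R's RNG (set.seed() in R).
// [[Rcpp::export]]
List cpp_kuramoto(NumericVector omega, double kappa, double xi, double dt,
                  NumericVector stim, NumericVector phi0,
                  NumericVector prc_table) {
  const int M = omega.size();
  const int nsteps = stim.size();
  if (phi0.size() != M) stop("phi0 must have one entry per oscillator");
  const int L = prc_table.size();
  const double *tab = (L > 0) ? &prc_table[0] : (const double *)0;
  const double sqdt = std::sqrt(dt);
  const double twopi = 2.0 * M_PI;

  std::vector<double> phi(phi0.begin(), phi0.end());
  NumericVector rho(nsteps), psi(nsteps), x(nsteps);

  double psi_prev_raw = 0.0, psi_offset = 0.0;
  bool first = true;

  for (int j = 0; j < nsteps; ++j) {
    // order parameter from current phases
    double sc = 0.0, ss = 0.0;
    for (int k = 0; k < M; ++k) {
      sc += std::cos(phi[k]);
      ss += std::sin(phi[k]);
    }
    sc /= M; ss /= M;
    double r = std::sqrt(sc * sc + ss * ss);
    double psi_raw = std::atan2(ss, sc);
    if (first) {
      first = false;
    } else {
      // unwrap: keep |psi_j - psi_{j-1}| <= pi
      double d = psi_raw - psi_prev_raw;
      if (d > M_PI) psi_offset -= twopi;
      else if (d < -M_PI) psi_offset += twopi;
    }
    psi_prev_raw = psi_raw;
    rho[j] = r;
    psi[j] = psi_raw + psi_offset;
    x[j] = r * std::cos(psi_raw);

    const double It = stim[j];
    const double kr = kappa * r;
    for (int k = 0; k < M; ++k) {
      double z = (L > 0) ? prc_lookup(tab, L, phi[k]) : std::sin(phi[k]);
      phi[k] += (omega[k] + kr * std::sin(psi_raw + psi_offset - phi[k])
                 + It * z) * dt + xi * sqdt * norm_rand();
    }
  }

  return List::create(_["rho"] = rho, _["psi"] = psi, _["x"] = x,
                      _["phi_final"] = NumericVector(phi.begin(), phi.end()));
}
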