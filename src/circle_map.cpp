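#include <Rcpp.h>
using namespace Rcpp;

// Iterate the sine circle map theta_{n+1} = theta_n + 2*pi*ratio + I*sin(theta_n),
// optionally with multiplicative period dithering: the rotation term becomes
// 2*pi*ratio*(1 + z_n), z_n ~ N(0, zeta^2). Phases are accumulated unwrapped.
// Uses R's RNG so set.seed() in R governs reproducibility.
// [[Rcpp::export]]
NumericVector cpp_circle_map(double theta0, int n, double ratio, double I,
                             double zeta) {
  NumericVector phases(n + 1);
  const double drift = 2.0 * M_PI * ratio;
  double th = theta0;
  phases[0] = th;
  if (zeta > 0.0) {
    for (int k = 0; k < n; ++k) {
      th += drift * (1.0 + zeta * norm_rand()) + I * std::sin(th);
      phases[k + 1] = th;
    }
  } else {
    for (int k = 0; k < n; ++k) {
      th += drift + I * std::sin(th);
      phases[k + 1] = th;
    }
  }
  return phases;
}

// Rotation number of a single circle-map run without storing the trajectory:
// returns (theta_N - theta_0) / (2*pi*N). Used by sweeps where only the
// rotation number is needed.
// [[Rcpp::export]]
double cpp_circle_map_rotation(double theta0, int n, double ratio, double I,
                               double zeta) {
  const double drift = 2.0 * M_PI * ratio;
  double th = theta0;
  if (zeta > 0.0) {
    for (int k = 0; k < n; ++k)
      th += drift * (1.0 + zeta * norm_rand()) + I * std::sin(th);
  } else {
    for (int k = 0; k < n; ++k)
      th += drift + I * std::sin(th);
  }
  return (th - theta0) / (2.0 * M_PI * n);
}

// Circle map driven by an arbitrary sequence of inter-pulse periods (s):
// theta_{n+1} = theta_n + 2*pi*f0*T_n + I*sin(theta_n). Supports cycling
// pulse trains on the map model.
// [[Rcpp::export]]
NumericVector cpp_circle_map_train(double theta0, NumericVector periods,
                                   double f0, double I) {
  const int n = periods.size();
  NumericVector phases(n + 1);
  double th = theta0;
  phases[0] = th;
  for (int k = 0; k < n; ++k) {
    th += 2.0 * M_PI * f0 * periods[k] + I * std::sin(th);
    phases[k + 1] = th;
  }
  return phases;
}
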