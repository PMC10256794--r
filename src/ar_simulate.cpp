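#include <Rcpp.h>
using namespace Rcpp;

// Coupled linear stochastic network with 1/f-shaped drive, in one pass.
// Per node i the drive is e_i(t) = (w_i(t) + pink_mix * s * u_i(t)) /
// sqrt(1 + pink_mix^2), where u_i is the one-pole (pink_pole) filtered
// version of the same white input w_i and s = sqrt(1 - pink_pole^2)
// normalizes u to unit variance. States follow x_t = A x_{t-1} + e_t from
// x_0 = 0. RNG stays in R (w is passed in), so the simulation is a pure
// function of its arguments.
// [[Rcpp::export]]
NumericMatrix ar_simulate_cpp(NumericMatrix A, NumericMatrix noise,
                              double pink_mix, double pink_pole) {
  const int n = A.nrow();
  const int T = noise.ncol();
  if (A.ncol() != n || noise.nrow() != n)
    stop("dimension mismatch between coupling matrix and noise");
  NumericMatrix x(n, T);
  std::vector<double> prev(n, 0.0), cur(n), u(n, 0.0);
  const double s = std::sqrt(1.0 - pink_pole * pink_pole);
  const double norm = std::sqrt(1.0 + pink_mix * pink_mix);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n; ++i) {
      const double w = noise(i, t);
      u[i] = pink_pole * u[i] + w;
      double e = (w + pink_mix * s * u[i]) / norm;
      for (int j = 0; j < n; ++j) e += A(i, j) * prev[j];
      cur[i] = e;
    }
    for (int i = 0; i < n; ++i) {
      x(i, t) = cur[i];
      prev[i] = cur[i];
    }
  }
  return x;
}

// Root-mean-square over consecutive non-overlapping windows of nw samples,
// one row per channel.
// [[Rcpp::export]]
NumericMatrix rms_envelope_cpp(NumericMatrix X, int nw) {
  const int n = X.nrow(), T = X.ncol();
  if (nw < 1) stop("window must be at least one sample");
  const int nk = T / nw;
  if (nk < 1) stop("panel shorter than the window");
  NumericMatrix out(n, nk);
  for (int k = 0; k < nk; ++k) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int t = k * nw; t < (k + 1) * nw; ++t) acc += X(i, t) * X(i, t);
      out(i, k) = std::sqrt(acc / nw);
    }
  }
  return out;
}
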