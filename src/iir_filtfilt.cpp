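#include <Rcpp.h>
using namespace Rcpp;

// direct-form IIR filter with zero initial conditions, in place
static void iir_filter(const std::vector<double>& b,
                       const std::vector<double>& a,
                       std::vector<double>& x) {
  const size_t nb = b.size(), na = a.size(), n = x.size();
  std::vector<double> y(n, 0.0);
  for (size_t t = 0; t < n; ++t) {
    double acc = 0.0;
    for (size_t k = 0; k < nb && k <= t; ++k) acc += b[k] * x[t - k];
    for (size_t k = 1; k < na && k <= t; ++k) acc -= a[k] * y[t - k];
    y[t] = acc;
  }
  x.swap(y);
}

// Zero-phase (forward-backward) IIR filtering of every row of X, matching
// the pad-with-zeros convention of signal::filtfilt: append 2*max(nb, na)
// zeros, filter, reverse, filter, reverse, truncate.
// [[Rcpp::export]]
NumericMatrix filtfilt_channels_cpp(NumericVector b, NumericVector a,
                                    NumericMatrix X) {
  if (a.size() < 1 || a[0] == 0.0) stop("invalid denominator coefficients");
  std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end());
  if (av[0] != 1.0) {
    for (double& c : bv) c /= av[0];
    for (double& c : av) c /= av[0];
  }
  const int nch = X.nrow(), T = X.ncol();
  const size_t pad = 2 * std::max(bv.size(), av.size());
  NumericMatrix out(nch, T);
  std::vector<double> x;
  for (int i = 0; i < nch; ++i) {
    x.assign(T + pad, 0.0);
    for (int t = 0; t < T; ++t) x[t] = X(i, t);
    iir_filter(bv, av, x);
    std::reverse(x.begin(), x.end());
    iir_filter(bv, av, x);
    for (int t = 0; t < T; ++t) out(i, t) = x[T + pad - 1 - t];
  }
  return out;
}
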