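#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, single pass.
static void df2t(const std::vector<double>& b, const std::vector<double>& a,
                 const double* x, double* y, R_xlen_t n) {
  const size_t nb = b.size(), na = a.size();
  const size_t nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  for (R_xlen_t i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (nz ? z[0] : 0.0);
    for (size_t k = 1; k < nz; ++k) {
      double bk = (k < nb) ? b[k] : 0.0;
      double ak = (k < na) ? a[k] : 0.0;
      z[k - 1] = bk * xi - ak * yi + z[k];
    }
    if (nz) {
      double bk = (nz < nb) ? b[nz] : 0.0;
      double ak = (nz < na) ? a[nz] : 0.0;
      z[nz - 1] = bk * xi - ak * yi;
    }
    y[i] = yi;
  }
}

// Zero-phase IIR filtering: odd-reflection padding at both ends (3x filter
// order, as conventional), forward pass, time reversal, second pass, reversal,
// padding stripped. Coefficients a must be normalised (a[0] == 1).
// [[Rcpp::export(name = ".iir_filtfilt")]]
NumericVector iir_filtfilt(NumericVector bcoef, NumericVector acoef, NumericVector x) {
  std::vector<double> b(bcoef.begin(), bcoef.end());
  std::vector<double> a(acoef.begin(), acoef.end());
  if (a.empty() || a[0] == 0.0) stop("a[1] must be non-zero");
  for (size_t k = 0; k < b.size(); ++k) b[k] /= a[0];
  for (size_t k = 1; k < a.size(); ++k) a[k] /= a[0];
  a[0] = 1.0;
  R_xlen_t n = x.size();
  R_xlen_t npad = 3 * (R_xlen_t)(std::max(a.size(), b.size()) - 1);
  if (n <= npad) stop("signal too short for zero-phase filtering (need > %d samples)", (int)npad);

  R_xlen_t m = n + 2 * npad;
  std::vector<double> ext(m), tmp(m);
  // odd reflection: 2*x[0] - x[npad..1], x, 2*x[n-1] - x[n-2..]
  for (R_xlen_t i = 0; i < npad; ++i) ext[i] = 2.0 * x[0] - x[npad - i];
  for (R_xlen_t i = 0; i < n; ++i) ext[npad + i] = x[i];
  for (R_xlen_t i = 0; i < npad; ++i) ext[npad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];

  df2t(b, a, ext.data(), tmp.data(), m);
  std::reverse(tmp.begin(), tmp.end());
  df2t(b, a, tmp.data(), ext.data(), m);
  std::reverse(ext.begin(), ext.end());

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = ext[npad + i];
  return out;
}

// Stationary AR(1) noise with marginal standard deviation sd_marginal, using
// R's RNG stream so results are reproducible under set.seed().
// [[Rcpp::export(name = ".ar1_noise")]]
NumericVector ar1_noise(R_xlen_t n, double rho, double sd_marginal) {
  if (n < 1) stop("n must be >= 1");
  if (rho <= -1.0 || rho >= 1.0) stop("AR(1) coefficient must be in (-1, 1)");
  NumericVector out(n);
  RNGScope scope;
  double innov_sd = sd_marginal * std::sqrt(1.0 - rho * rho);
  out[0] = norm_rand() * sd_marginal;
  for (R_xlen_t i = 1; i < n; ++i) out[i] = rho * out[i - 1] + innov_sd * norm_rand();
  return out;
}
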