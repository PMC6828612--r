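#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// One direct-form-II-transposed IIR pass over all channels at once.
// X is column-major (channels x samples), so processing sample-by-sample
// with an inner channel loop is cache-friendly and the independent
// per-channel recursions pipeline well. Coefficients normalized (a[0]=1).
static void iir_pass_multi(const std::vector<double>& b,
                           const std::vector<double>& a,
                           const double* x, int nch, int n, double* y) {
  const int p = (int)std::max(b.size(), a.size());
  std::vector<double> bb(p, 0.0), aa(p, 0.0);
  for (size_t i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (size_t i = 0; i < a.size(); ++i) aa[i] = a[i];
  std::vector<double> z((size_t)nch * p, 0.0);   // z[ch*p + j]
  for (int i = 0; i < n; ++i) {
    const double* xi = x + (size_t)i * nch;
    double* yi = y + (size_t)i * nch;
    for (int ch = 0; ch < nch; ++ch) {
      double* zc = z.data() + (size_t)ch * p;
      const double xv = xi[ch];
      const double yv = bb[0] * xv + zc[0];
      for (int j = 0; j < p - 1; ++j) {
        zc[j] = bb[j + 1] * xv + zc[j + 1] - aa[j + 1] * yv;
      }
      yi[ch] = yv;
    }
  }
}

// Zero-phase (forward-backward) IIR filtering of each row of X
// (channels x samples), with odd-reflection edge padding of
// 3 * (filter order) samples to tame startup transients.
// [[Rcpp::export(name = ".filtfilt_channels_cpp")]]
NumericMatrix filtfilt_channels_cpp(NumericVector b, NumericVector a,
                                    NumericMatrix X) {
  const int nch = X.nrow(), n = X.ncol();
  std::vector<double> bv(b.begin(), b.end()), av(a.begin(), a.end());
  if (av.empty() || av[0] == 0.0) stop("invalid filter: a[0] must be nonzero");
  for (auto& c : bv) c /= a[0];
  for (auto& c : av) c /= a[0];
  const int p = (int)std::max(bv.size(), av.size());
  const int pad = std::min(3 * (p - 1), n - 1);
  const int m = n + 2 * pad;
  const double* xp = X.begin();
  std::vector<double> ext((size_t)nch * m), tmp((size_t)nch * m);
  // odd-reflection padding, per channel, keeping channel-major columns
  for (int i = 0; i < pad; ++i) {
    for (int ch = 0; ch < nch; ++ch) {
      ext[(size_t)i * nch + ch] =
        2.0 * xp[ch] - xp[(size_t)(pad - i) * nch + ch];
      ext[(size_t)(pad + n + i) * nch + ch] =
        2.0 * xp[(size_t)(n - 1) * nch + ch] -
        xp[(size_t)(n - 2 - i) * nch + ch];
    }
  }
  std::copy(xp, xp + (size_t)n * nch, ext.begin() + (size_t)pad * nch);
  iir_pass_multi(bv, av, ext.data(), nch, m, tmp.data());
  // reverse the sample order (columns), keep channel order
  for (int i = 0; i < m / 2; ++i) {
    for (int ch = 0; ch < nch; ++ch) {
      std::swap(tmp[(size_t)i * nch + ch],
                tmp[(size_t)(m - 1 - i) * nch + ch]);
    }
  }
  iir_pass_multi(bv, av, tmp.data(), nch, m, ext.data());
  NumericMatrix out(nch, n);
  for (int i = 0; i < n; ++i) {
    for (int ch = 0; ch < nch; ++ch) {
      out[(size_t)i * nch + ch] = ext[(size_t)(m - 1 - pad - i) * nch + ch];
    }
  }
  return out;
}
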