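#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed filtering of x, in place over the C array.
static void df2t_inplace(const double *b, const double *a, int nz,
                         double *x, R_xlen_t n, bool backward) {
  std::vector<double> z(nz, 0.0);
  double *zp = z.data();
  if (!backward) {
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = b[0] * xi + (nz ? zp[0] : 0.0);
      for (int j = 0; j < nz - 1; ++j)
        zp[j] = b[j + 1] * xi + zp[j + 1] - a[j + 1] * yi;
      if (nz) zp[nz - 1] = b[nz] * xi - a[nz] * yi;
      x[i] = yi;
    }
  } else {
    for (R_xlen_t i = n - 1; i >= 0; --i) {
      const double xi = x[i];
      const double yi = b[0] * xi + (nz ? zp[0] : 0.0);
      for (int j = 0; j < nz - 1; ++j)
        zp[j] = b[j + 1] * xi + zp[j + 1] - a[j + 1] * yi;
      if (nz) zp[nz - 1] = b[nz] * xi - a[nz] * yi;
      x[i] = yi;
    }
  }
}

static void pad_coefs(NumericVector b, NumericVector a,
                      std::vector<double> &bb, std::vector<double> &aa,
                      int &nz) {
  nz = std::max(b.size(), a.size()) - 1;
  bb.assign(nz + 1, 0.0);
  aa.assign(nz + 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
}

// Single forward pass, zero initial conditions (a[0] must be 1).
// [[Rcpp::export(name = ".filter_df2t")]]
NumericVector filter_df2t(NumericVector b, NumericVector a, NumericVector x) {
  std::vector<double> bb, aa;
  int nz;
  pad_coefs(b, a, bb, aa, nz);
  NumericVector y = clone(x);
  df2t_inplace(bb.data(), aa.data(), nz, REAL(y), y.size(), false);
  return y;
}

// Forward-backward (zero-phase) filtering with odd-reflection padding of
// `padlen` samples at each end, matching the usual filtfilt convention.
// [[Rcpp::export(name = ".filtfilt_df2t")]]
NumericVector filtfilt_df2t(NumericVector b, NumericVector a,
                            NumericVector x, int padlen) {
  std::vector<double> bb, aa;
  int nz;
  pad_coefs(b, a, bb, aa, nz);
  const R_xlen_t n = x.size(), p = padlen;
  if (n <= p) stop("signal too short for zero-phase filtering");
  std::vector<double> buf(n + 2 * p);
  const double *px = REAL(x);
  for (R_xlen_t i = 0; i < p; ++i) buf[i] = 2.0 * px[0] - px[p - i];
  std::copy(px, px + n, buf.begin() + p);
  for (R_xlen_t i = 0; i < p; ++i)
    buf[p + n + i] = 2.0 * px[n - 1] - px[n - 2 - i];
  df2t_inplace(bb.data(), aa.data(), nz, buf.data(), n + 2 * p, false);
  df2t_inplace(bb.data(), aa.data(), nz, buf.data(), n + 2 * p, true);
  NumericVector y(n);
  std::copy(buf.begin() + p, buf.begin() + p + n, REAL(y));
  return y;
}

// Per-segment root-mean-square of consecutive length-`seg` windows.
// [[Rcpp::export(name = ".seg_rms")]]
NumericVector seg_rms(NumericVector x, int seg) {
  const R_xlen_t n_seg = x.size() / seg;
  NumericVector out(n_seg);
  const double *px = REAL(x);
  for (R_xlen_t k = 0; k < n_seg; ++k) {
    double acc = 0.0;
    const double *q = px + k * seg;
    for (int j = 0; j < seg; ++j) acc += q[j] * q[j];
    out[k] = std::sqrt(acc / seg);
  }
  return out;
}
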