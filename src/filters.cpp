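#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state zi (length
// max(nb, na) - 1, already scaled by the caller). a[0] must be 1.
// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector x, NumericVector b, NumericVector a,
                             NumericVector zi) {
  int n = x.size();
  int nb = b.size(), na = a.size();
  int nfilt = std::max(nb, na);
  std::vector<double> bb(nfilt, 0.0), aa(nfilt, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nfilt - 1, 0.0);
  for (int i = 0; i < (int)z.size() && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int m = 0; m < n; ++m) {
    double xm = x[m];
    double ym = bb[0] * xm + z[0];
    for (int i = 0; i < nfilt - 2; ++i)
      z[i] = bb[i + 1] * xm + z[i + 1] - aa[i + 1] * ym;
    z[nfilt - 2] = bb[nfilt - 1] * xm - aa[nfilt - 1] * ym;
    y[m] = ym;
  }
  return y;
}

// Per-frame gammatone filterbank output energies.
// frames: NS x Nf matrix (one column per frame). sosb: (4*N) x 3 feed-forward
// coefficients, sosa: (4*N) x 3 feedback (a0 = 1), rows grouped 4 consecutive
// biquad sections per filter. Each frame is filtered independently from zero
// state; the energy is the sum of squared output samples.
// [[Rcpp::export]]
NumericMatrix cpp_frame_bank_energies(NumericMatrix frames, NumericMatrix sosb,
                                      NumericMatrix sosa, int n_filters) {
  int ns = frames.nrow(), nf = frames.ncol();
  int n_sections = sosb.nrow() / n_filters;
  NumericMatrix energies(n_filters, nf);
  std::vector<double> buf(ns), out(ns);
  for (int g = 0; g < n_filters; ++g) {
    for (int f = 0; f < nf; ++f) {
      for (int i = 0; i < ns; ++i) buf[i] = frames(i, f);
      for (int s = 0; s < n_sections; ++s) {
        int r = g * n_sections + s;
        double b0 = sosb(r, 0), b1 = sosb(r, 1), b2 = sosb(r, 2);
        double a1 = sosa(r, 1), a2 = sosa(r, 2);
        double z1 = 0.0, z2 = 0.0;
        for (int i = 0; i < ns; ++i) {
          double xm = buf[i];
          double ym = b0 * xm + z1;
          z1 = b1 * xm + z2 - a1 * ym;
          z2 = b2 * xm - a2 * ym;
          out[i] = ym;
        }
        std::swap(buf, out);
      }
      double e = 0.0;
      for (int i = 0; i < ns; ++i) e += buf[i] * buf[i];
      energies(g, f) = e;
    }
  }
  return energies;
}
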