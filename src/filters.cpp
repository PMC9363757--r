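#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, one channel, with initial state zi
// (length max(na, nb) - 1). a[0] must be 1. Returns the filtered signal;
// final state is written back into zi so callers can chain segments.
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int n = x.size();
  const int nf = std::max(a.size(), b.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), z(nf, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  for (int i = 0; i < zi.size() && i < nf - 1; ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = bb[0] * xt + z[0];
    for (int k = 0; k < nf - 2; ++k) {
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    }
    z[nf - 2] = bb[nf - 1] * xt - aa[nf - 1] * yt;
    y[t] = yt;
  }
  for (int i = 0; i < zi.size() && i < nf - 1; ++i) zi[i] = z[i];
  return y;
}
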