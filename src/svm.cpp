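#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dual coordinate descent for L2-regularised L1-loss (hinge) linear SVM
// (Hsieh et al., ICML 2008). X is n x d (dense, row observations), y in
// {-1, +1}. A bias term is handled by the caller through an appended
// constant column. Returns the primal weight vector w (length d).
// [[Rcpp::export(name = ".svm_dcd_cpp")]]
NumericVector svm_dcd_cpp(NumericMatrix X, NumericVector y, double C,
                          int max_iter, double tol, int seed) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> alpha(n, 0.0), w(d, 0.0), Qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    Qii[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  // xorshift PRNG for permutation; independent of R's RNG stream
  unsigned long long state = (unsigned long long)seed * 2685821657736338717ULL + 1ULL;
  auto next_rand = [&]() {
    state ^= state << 13; state ^= state >> 7; state ^= state << 17;
    return state;
  };
  for (int iter = 0; iter < max_iter; ++iter) {
    double max_pg = 0.0;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(next_rand() % (unsigned long long)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    for (int t = 0; t < n; ++t) {
      const int i = idx[t];
      if (Qii[i] <= 0.0) continue;
      double g = 0.0;
      for (int j = 0; j < d; ++j) g += w[j] * X(i, j);
      g = y[i] * g - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= C) pg = std::max(g, 0.0);
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-12) {
        const double old = alpha[i];
        alpha[i] = std::min(std::max(old - g / Qii[i], 0.0), C);
        const double delta = (alpha[i] - old) * y[i];
        for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
      }
    }
    if (max_pg < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
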