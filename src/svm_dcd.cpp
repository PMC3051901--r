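// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear
// soft-margin SVM:
//
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x_i)
//
// following Hsieh et al. (ICML 2008). The bias is expected to be handled by
// the caller as an augmented constant feature. Uses R's RNG for the random
// permutations so results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector svm_dcd(const NumericMatrix& X, const NumericVector& y,
                      double C, int max_iter = 200, double tol = 1e-4) {
  const int n = X.nrow(), d = X.ncol();
  NumericVector w(d);
  std::vector<double> alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  GetRNGstate();
  for (int iter = 0; iter < max_iter; ++iter) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = idx[t];
      if (qii[i] <= 0.0) continue;
      double wx = 0.0;
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      const double G = y[i] * wx - 1.0;
      double pg = G;
      if (alpha[i] <= 0.0) pg = std::min(G, 0.0);
      else if (alpha[i] >= C) pg = std::max(G, 0.0);
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-12) {
        const double old = alpha[i];
        double a = old - G / qii[i];
        if (a < 0.0) a = 0.0;
        if (a > C) a = C;
        alpha[i] = a;
        const double delta = (a - old) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
        }
      }
    }
    if (max_pg < tol) break;
  }
  PutRNGstate();
  return w;
}
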