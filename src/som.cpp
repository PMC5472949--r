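#include <Rcpp.h>
using namespace Rcpp;

// Online SOM training with a bubble (hard-radius) neighbourhood.
// X: G x d data, W: K x d initial codebook, grid: K x 2 unit coordinates,
// idx: 1-based sample index per update, alpha/radius: per-update learning
// rate and neighbourhood radius.  Returns the trained codebook.
// [[Rcpp::export]]
NumericMatrix som_train(const NumericMatrix& X, NumericMatrix W,
                        const NumericMatrix& grid, const IntegerVector& idx,
                        const NumericVector& alpha,
                        const NumericVector& radius) {
  const int K = W.nrow(), d = W.ncol(), T = idx.size();
  for (int t = 0; t < T; ++t) {
    const int g = idx[t] - 1;
    // best-matching unit
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = X(g, j) - W(k, j);
        s += diff * diff;
      }
      if (s < best) { best = s; bmu = k; }
    }
    // bubble: units strictly inside the radius move with the BMU; at the
    // final radius of 1 only the BMU itself is updated
    const double r2 = radius[t] * radius[t];
    const double a = alpha[t];
    for (int k = 0; k < K; ++k) {
      const double dx = grid(k, 0) - grid(bmu, 0);
      const double dy = grid(k, 1) - grid(bmu, 1);
      if (dx * dx + dy * dy < r2) {
        for (int j = 0; j < d; ++j)
          W(k, j) += a * (X(g, j) - W(k, j));
      }
    }
  }
  return W;
}
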