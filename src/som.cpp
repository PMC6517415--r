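#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Online SOM training. Each presented cell updates its best-matching unit
// (BMU, squared Euclidean distance; ties -> lowest node index) and all nodes
// whose grid distance to the BMU is within the current radius, by the current
// learning rate. Learning rate and radius decay linearly over the total
// number of presentations. Presentation order is supplied from R (0-based),
// seed-shuffled per pass, so training is deterministic given the seed.
// Data and codebook are copied to row-contiguous buffers for cache locality.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(const NumericMatrix& data,
                            const NumericMatrix& codebook,
                            const IntegerVector& order,
                            const NumericMatrix& grid_dist,
                            double alpha0, double alpha1,
                            double radius0, double radius1) {
  const int n = data.nrow();
  const int K = codebook.nrow();
  const int M = codebook.ncol();
  const R_xlen_t T = order.size();

  std::vector<double> X((size_t)n * M), cb((size_t)K * M);
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < M; ++m) X[(size_t)i * M + m] = data(i, m);
  for (int k = 0; k < K; ++k)
    for (int m = 0; m < M; ++m) cb[(size_t)k * M + m] = codebook(k, m);

  for (R_xlen_t t = 0; t < T; ++t) {
    const double f = (T > 1) ? (double)t / (double)(T - 1) : 0.0;
    const double alpha = alpha0 + (alpha1 - alpha0) * f;
    const double radius = radius0 + (radius1 - radius0) * f;
    const double* x = &X[(size_t)order[t] * M];

    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < K; ++k) {
      const double* w = &cb[(size_t)k * M];
      double d = 0.0;
      for (int m = 0; m < M; ++m) {
        const double diff = x[m] - w[m];
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = k; }
    }

    const double* gd = &grid_dist(0, bmu);  // column bmu, contiguous
    for (int k = 0; k < K; ++k) {
      if (gd[k] <= radius) {
        double* w = &cb[(size_t)k * M];
        for (int m = 0; m < M; ++m) w[m] += alpha * (x[m] - w[m]);
      }
    }
  }

  NumericMatrix out(K, M);
  for (int k = 0; k < K; ++k)
    for (int m = 0; m < M; ++m) out(k, m) = cb[(size_t)k * M + m];
  return out;
}

// Nearest-codebook assignment (1-based labels; ties -> lowest node index).
// [[Rcpp::export]]
IntegerVector som_map_cpp(const NumericMatrix& data,
                          const NumericMatrix& codebook) {
  const int n = data.nrow();
  const int K = codebook.nrow();
  const int M = codebook.ncol();
  std::vector<double> X((size_t)n * M), cb((size_t)K * M);
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < M; ++m) X[(size_t)i * M + m] = data(i, m);
  for (int k = 0; k < K; ++k)
    for (int m = 0; m < M; ++m) cb[(size_t)k * M + m] = codebook(k, m);

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double* x = &X[(size_t)i * M];
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < K; ++k) {
      const double* w = &cb[(size_t)k * M];
      double d = 0.0;
      for (int m = 0; m < M; ++m) {
        const double diff = x[m] - w[m];
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = k; }
    }
    out[i] = bmu + 1;
  }
  return out;
}
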