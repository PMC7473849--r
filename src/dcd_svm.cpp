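#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) soft-margin linear SVM
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i <w, x_i>)
// with the intercept absorbed as an extra constant feature of value `bias`
// (so the intercept is weakly regularized, as in LIBLINEAR).
// Sweeps over the dual variables in a freshly permuted order each epoch
// (Hsieh et al. 2008, Alg. 1) and stops on LIBLINEAR's criterion: the gap
// between the largest and smallest projected gradient over an epoch falls
// below `tol`. The permutation uses a fixed-seed internal xorshift
// generator, so fits are deterministic and independent of R's RNG state.
// [[Rcpp::export(name = ".dcd_svm_fit")]]
NumericVector dcd_svm_fit(NumericMatrix X, NumericVector y, double C,
                          double bias, double tol, int max_epochs) {
  const int n = X.nrow(), p = X.ncol();
  const int d = p + 1;
  // row-major copy (each sample contiguous, bias feature appended)
  std::vector<double> Xr((size_t)n * d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) Xr[(size_t)i * d + j] = X(i, j);
    Xr[(size_t)i * d + p] = bias;
  }
  std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) {
    order[i] = i;
    double s = 0.0;
    const double *xi = &Xr[(size_t)i * d];
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }
  uint64_t rng = 88172645463325252ULL;
  int epoch = 0;
  for (; epoch < max_epochs; ++epoch) {
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates, xorshift64 draws
      rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
      std::swap(order[i], order[(int)(rng % (uint64_t)(i + 1))]);
    }
    double pg_max = -1e300, pg_min = 1e300;
    for (int k = 0; k < n; ++k) {
      const int i = order[k];
      const double *xi = &Xr[(size_t)i * d];
      double xi_w = 0.0;
      for (int j = 0; j < d; ++j) xi_w += w[j] * xi[j];
      const double G = y[i] * xi_w - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (PG > pg_max) pg_max = PG;
      if (PG < pg_min) pg_min = PG;
      if (PG != 0.0) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > C) a_new = C;
        alpha[i] = a_new;
        const double delta = (a_new - a_old) * y[i];
        if (delta != 0.0)
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
      }
    }
    if (pg_max - pg_min < tol) break;
  }
  NumericVector out(d + 1);
  for (int j = 0; j < d; ++j) out[j] = w[j];
  out[d] = epoch;
  return out;
}
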