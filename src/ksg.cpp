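#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger MI estimator (algorithm 1), max-norm,
// brute force O(N^2 d) with O(N) memory. eps_i is the distance to the k-th
// nearest neighbour in the joint space; n_x / n_y count marginal points
// strictly inside eps_i. Ties in the k-th distance are resolved by
// nth_element's deterministic partial ordering of the index-ordered
// distance list.
// [[Rcpp::export(name = ".ksgMICpp")]]
double ksg_mi_cpp(NumericMatrix x, NumericMatrix y, int k) {
  const int N = x.nrow(), dx = x.ncol(), dy = y.ncol();
  std::vector<double> dj(N - 1);
  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    int m = 0;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      double d = 0.0;
      for (int c = 0; c < dx; ++c) d = std::max(d, std::abs(x(j, c) - x(i, c)));
      for (int c = 0; c < dy; ++c) d = std::max(d, std::abs(y(j, c) - y(i, c)));
      dj[m++] = d;
    }
    std::nth_element(dj.begin(), dj.begin() + (k - 1), dj.begin() + m);
    const double eps = dj[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      double dxx = 0.0, dyy = 0.0;
      for (int c = 0; c < dx; ++c)
        dxx = std::max(dxx, std::abs(x(j, c) - x(i, c)));
      for (int c = 0; c < dy; ++c)
        dyy = std::max(dyy, std::abs(y(j, c) - y(i, c)));
      if (dxx < eps) ++nx;
      if (dyy < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)N) - acc / N;
}
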