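#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Distance to the k-th nearest neighbour of each point (self excluded)
// under the Chebyshev (max-coordinate) metric in the joint (x, y) space.
// Brute force O(n^2); n up to ~10^4 stays well under a second.
// [[Rcpp::export]]
NumericVector chebyshev_knn_dist(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have the same length");
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1]");
  NumericVector out(n);
  std::vector<double> d(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    const double xi = x[i], yi = y[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = std::fabs(x[j] - xi);
      const double dy = std::fabs(y[j] - yi);
      d[m++] = dx > dy ? dx : dy;
    }
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
    out[i] = d[k - 1];
  }
  return out;
}
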