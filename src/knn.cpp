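#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Exact K-nearest-neighbour search by brute-force scan.
// Neighbours are ordered by (distance, index); ties on distance are
// broken towards the smaller index so output is deterministic.
// Returns 1-based indices and Euclidean distances.
// [[Rcpp::export(name = ".knn_brute_force")]]
List knn_brute_force(NumericMatrix x, int k) {
  const int n = x.nrow(), d = x.ncol();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n");
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<double> d2(n);
  std::vector<int> ord(n - 1);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = x(i, c) - x(j, c);
        s += diff * diff;
      }
      d2[j] = s;
    }
    int m = 0;
    for (int j = 0; j < n; ++j)
      if (j != i) ord[m++] = j;
    std::partial_sort(
        ord.begin(), ord.begin() + k, ord.end(), [&](int a, int b) {
          return d2[a] < d2[b] || (d2[a] == d2[b] && a < b);
        });
    for (int s = 0; s < k; ++s) {
      idx(i, s) = ord[s] + 1;
      dist(i, s) = std::sqrt(std::max(0.0, d2[ord[s]]));
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
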