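#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact nearest-neighbour distances by uniform-grid bucketing.
// Cells are sized for ~2 points each; for every point, rings of cells are
// scanned outward and the search stops once no unscanned cell can contain a
// closer point. Worst case degenerates to O(N^2) (all points in one cell),
// typical cost is O(N).
// [[Rcpp::export(name = ".nn_dist_cpp")]]
NumericVector nn_dist_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 2) stop("at least two points are required");
  if (y.size() != n) stop("x and y must have equal length");
  NumericVector out(n);

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double w = xmax - xmin, h = ymax - ymin;
  if (w <= 0.0 && h <= 0.0) return out;  // all points coincident: NN = 0

  int nx, ny;
  if (w > 0.0 && h > 0.0) {
    double cell = std::sqrt(w * h / std::max(1.0, n / 2.0));
    nx = std::max(1, (int)std::floor(w / cell) + 1);
    ny = std::max(1, (int)std::floor(h / cell) + 1);
  } else if (w > 0.0) {                  // collinear along x
    nx = std::max(1, n / 2); ny = 1;
  } else {                               // collinear along y
    nx = 1; ny = std::max(1, n / 2);
  }
  double csx = w > 0.0 ? w / nx : 1.0;
  double csy = h > 0.0 ? h / ny : 1.0;
  double csmin = std::min(w > 0.0 ? csx : R_PosInf,
                          h > 0.0 ? csy : R_PosInf);

  std::vector< std::vector<int> > buckets((size_t)nx * ny);
  std::vector<int> ci(n), cj(n);
  for (int i = 0; i < n; ++i) {
    int bi = w > 0.0 ? std::min(nx - 1, (int)((x[i] - xmin) / csx)) : 0;
    int bj = h > 0.0 ? std::min(ny - 1, (int)((y[i] - ymin) / csy)) : 0;
    ci[i] = bi; cj[i] = bj;
    buckets[(size_t)bj * nx + bi].push_back(i);
  }

  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int maxring = std::max(nx, ny);
    for (int k = 0; k <= maxring; ++k) {
      // every point in a ring-k cell lies at distance >= (k-1)*csmin
      if (k > 1 && best <= (k - 1) * csmin) break;
      int lo_i = ci[i] - k, hi_i = ci[i] + k;
      int lo_j = cj[i] - k, hi_j = cj[i] + k;
      for (int bj = std::max(lo_j, 0); bj <= std::min(hi_j, ny - 1); ++bj) {
        bool edge_j = (bj == lo_j || bj == hi_j);
        int from = std::max(lo_i, 0), to = std::min(hi_i, nx - 1);
        for (int bi = from; bi <= to; ++bi) {
          if (!edge_j && bi != lo_i && bi != hi_i) {
            // interior of the ring: jump across to the right edge column
            if (hi_i <= to) bi = hi_i; else break;
          }
          const std::vector<int>& b = buckets[(size_t)bj * nx + bi];
          for (size_t q = 0; q < b.size(); ++q) {
            int j = b[q];
            if (j == i) continue;
            double dx = x[i] - x[j], dy = y[i] - y[j];
            double d2 = dx * dx + dy * dy;
            if (d2 < best * best) best = std::sqrt(d2);
          }
        }
      }
    }
    out[i] = best;
  }
  return out;
}
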