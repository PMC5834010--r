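#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Exact k-nearest-neighbour mean distances for every point of a planar
// pattern, via a uniform grid of buckets with expanding ring search.
// A point in Chebyshev ring r around the query cell is at Euclidean
// distance >= (r - 1) * h from the query, so the search can stop once the
// current k-th best distance is below that bound.
//
// Returns, for each point i, the mean Euclidean distance from point i to
// its k nearest neighbours among the other points (self excluded).
// [[Rcpp::export(name = ".knnMeanDistAll")]]
NumericVector knn_mean_dist_all(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (n < 2) stop("need at least 2 points");
  if (k < 1 || k > n - 1) stop("k must be in [1, n - 1]");

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double w = xmax - xmin, hgt = ymax - ymin;
  if (w <= 0) w = 1e-9;
  if (hgt <= 0) hgt = 1e-9;
  // bucket size aimed at ~2 points per cell; rings then grow in small steps
  double h = std::sqrt(2.0 * w * hgt / n);
  if (!(h > 0) || !std::isfinite(h)) h = 1.0;
  int ncx = std::max(1, (int)std::floor(w / h) + 1);
  int ncy = std::max(1, (int)std::floor(hgt / h) + 1);
  // cap grid size for very uneven aspect ratios
  if ((double)ncx * ncy > 4.0 * n + 64.0) {
    double shrink = std::sqrt(((double)ncx * ncy) / (4.0 * n + 64.0));
    h *= shrink;
    ncx = std::max(1, (int)std::floor(w / h) + 1);
    ncy = std::max(1, (int)std::floor(hgt / h) + 1);
  }

  std::vector<std::vector<int> > cells((size_t)ncx * ncy);
  std::vector<int> cxi(n), cyi(n);
  for (int i = 0; i < n; ++i) {
    int cx = std::min(ncx - 1, (int)std::floor((x[i] - xmin) / h));
    int cy = std::min(ncy - 1, (int)std::floor((y[i] - ymin) / h));
    cxi[i] = cx; cyi[i] = cy;
    cells[(size_t)cy * ncx + cx].push_back(i);
  }

  NumericVector out(n);
  const int max_ring = std::max(ncx, ncy);
  std::priority_queue<double> heap; // max-heap of squared distances

  for (int i = 0; i < n; ++i) {
    while (!heap.empty()) heap.pop();
    const double xi = x[i], yi = y[i];
    const int cx = cxi[i], cy = cyi[i];

    for (int r = 0; r <= max_ring; ++r) {
      if ((int)heap.size() == k && r >= 2) {
        double bound = (double)(r - 1) * h;
        if (bound * bound >= heap.top()) break;
      }
      int x0 = cx - r, x1 = cx + r, y0 = cy - r, y1 = cy + r;
      for (int gy = y0; gy <= y1; ++gy) {
        if (gy < 0 || gy >= ncy) continue;
        bool edge_row = (gy == y0 || gy == y1);
        for (int gx = x0; gx <= x1; ++gx) {
          if (gx < 0 || gx >= ncx) continue;
          if (!edge_row && gx != x0 && gx != x1) continue; // ring only
          const std::vector<int>& cell = cells[(size_t)gy * ncx + gx];
          for (size_t t = 0; t < cell.size(); ++t) {
            int j = cell[t];
            if (j == i) continue;
            double dx = x[j] - xi, dy = y[j] - yi;
            double d2 = dx * dx + dy * dy;
            if ((int)heap.size() < k) {
              heap.push(d2);
            } else if (d2 < heap.top()) {
              heap.pop();
              heap.push(d2);
            }
          }
        }
      }
    }

    double s = 0.0;
    int m = (int)heap.size();
    while (!heap.empty()) { s += std::sqrt(heap.top()); heap.pop(); }
    out[i] = s / m;
  }
  return out;
}
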