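#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <queue>
#include <vector>
using namespace Rcpp;

// k-th nearest-neighbour Chebyshev (L-infinity) radius from each query to a
// 2-D point set. Points are bucketed on a uniform grid of width `cell`
// (dense CSR layout over the bounding box); the search expands square rings
// of cells outward from the query until the current k-th smallest distance
// can no longer be improved. Returns NA for every query when fewer than k
// points exist.
// [[Rcpp::export]]
NumericVector knn_chebyshev_radius(NumericVector px, NumericVector py,
                                   NumericVector qx, NumericVector qy,
                                   int k, double cell) {
  const int n = px.size(), m = qx.size();
  NumericVector out(m, NA_REAL);
  if (n < k || k <= 0) return out;

  double xmin = px[0], ymin = py[0], xmax = px[0], ymax = py[0];
  for (int i = 1; i < n; ++i) {
    if (px[i] < xmin) xmin = px[i];
    if (px[i] > xmax) xmax = px[i];
    if (py[i] < ymin) ymin = py[i];
    if (py[i] > ymax) ymax = py[i];
  }
  int64_t nx = (int64_t)std::floor((xmax - xmin) / cell) + 1;
  int64_t ny = (int64_t)std::floor((ymax - ymin) / cell) + 1;
  while (nx * ny > 64000000LL) {  // coarsen overly fine grids
    cell *= 2.0;
    nx = (int64_t)std::floor((xmax - xmin) / cell) + 1;
    ny = (int64_t)std::floor((ymax - ymin) / cell) + 1;
  }
  const int64_t ncell = nx * ny;
  std::vector<int> counts((size_t)ncell + 1, 0);
  std::vector<int> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)((px[i] - xmin) / cell);
    cy[i] = (int)((py[i] - ymin) / cell);
    ++counts[(size_t)((int64_t)cx[i] * ny + cy[i]) + 1];
  }
  for (size_t c = 1; c <= (size_t)ncell; ++c) counts[c] += counts[c - 1];
  std::vector<int> order(n);
  {
    std::vector<int> cursor(counts.begin(), counts.end() - 1);
    for (int i = 0; i < n; ++i) {
      order[(size_t)cursor[(size_t)((int64_t)cx[i] * ny + cy[i])]++] = i;
    }
  }

  const int64_t max_span = std::max(nx, ny);
  for (int q = 0; q < m; ++q) {
    const double x = qx[q], y = qy[q];
    const int64_t qcx = (int64_t)std::floor((x - xmin) / cell);
    const int64_t qcy = (int64_t)std::floor((y - ymin) / cell);
    std::priority_queue<double> heap;
    int seen = 0;
    auto scan_cell = [&](int64_t gx, int64_t gy) {
      if (gx < 0 || gy < 0 || gx >= nx || gy >= ny) return;
      const size_t c = (size_t)(gx * ny + gy);
      for (int t = counts[c]; t < counts[c + 1]; ++t) {
        const int p = order[t];
        const double d = std::max(std::fabs(px[p] - x), std::fabs(py[p] - y));
        ++seen;
        if ((int)heap.size() < k) heap.push(d);
        else if (d < heap.top()) { heap.pop(); heap.push(d); }
      }
    };
    const int64_t off = std::max({(int64_t)0, -qcx, -qcy, qcx - nx, qcy - ny});
    for (int64_t r = 0; r <= max_span + off + 1; ++r) {
      if ((int)heap.size() == k && heap.top() <= (double)(r - 1) * cell) break;
      if (seen >= n && (int)heap.size() == k) break;
      if (r == 0) {
        scan_cell(qcx, qcy);
      } else {
        for (int64_t dx = -r; dx <= r; ++dx) {
          scan_cell(qcx + dx, qcy - r);
          scan_cell(qcx + dx, qcy + r);
        }
        for (int64_t dy = -r + 1; dy <= r - 1; ++dy) {
          scan_cell(qcx - r, qcy + dy);
          scan_cell(qcx + r, qcy + dy);
        }
      }
    }
    if ((int)heap.size() == k) out[q] = heap.top();
  }
  return out;
}
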