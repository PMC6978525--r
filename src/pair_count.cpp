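#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Histogram of pairwise distances of a planar point set, binned by `breaks`
// (strictly increasing). Uses a uniform grid of cell size >= max(breaks) so
// only neighboring cells are scanned: O(N * local density) instead of O(N^2).
// [[Rcpp::export]]
NumericVector pairCountHist(NumericVector x, NumericVector y,
                            NumericVector breaks) {
  const int n = x.size();
  const int nb = breaks.size() - 1;
  NumericVector counts(nb);
  if (n < 2 || nb < 1) return counts;

  const double rmax = breaks[nb];
  const double r2max = rmax * rmax;
  const double rmin = breaks[0];
  const double r2min = rmin * rmin;

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  const double cell = std::max(rmax, 1e-12);
  const int ncx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
  const int ncy = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);

  std::vector<std::vector<int> > grid((size_t)ncx * ncy);
  std::vector<int> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = std::min(ncx - 1, (int)std::floor((x[i] - xmin) / cell));
    cy[i] = std::min(ncy - 1, (int)std::floor((y[i] - ymin) / cell));
    grid[(size_t)cx[i] * ncy + cy[i]].push_back(i);
  }

  const double *br = breaks.begin();
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx) {
      const int gx = cx[i] + dx;
      if (gx < 0 || gx >= ncx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int gy = cy[i] + dy;
        if (gy < 0 || gy >= ncy) continue;
        const std::vector<int> &bucket = grid[(size_t)gx * ncy + gy];
        for (size_t bi = 0; bi < bucket.size(); ++bi) {
          const int j = bucket[bi];
          if (j <= i) continue;              // each unordered pair once
          const double ddx = x[i] - x[j];
          const double ddy = y[i] - y[j];
          const double d2 = ddx * ddx + ddy * ddy;
          if (d2 > r2max || d2 < r2min) continue;
          const double d = std::sqrt(d2);
          // first bin with breaks[k] <= d < breaks[k+1]
          const double *pos = std::upper_bound(br, br + nb + 1, d);
          int k = (int)(pos - br) - 1;
          if (k == nb) k = nb - 1;           // d == rmax lands in last bin
          if (k >= 0 && k < nb) counts[k] += 1.0;
        }
      }
    }
  }
  return counts;
}
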