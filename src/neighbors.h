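#ifndef EVACSIM_NEIGHBORS_H
#define EVACSIM_NEIGHBORS_H

#include <vector>
#include <cmath>
#include <algorithm>

// Uniform-grid spatial hash for fixed-radius neighbour queries in 2D.
// Bin size equals the query radius, so candidates lie in the 3x3 bin block.
struct SpatialHash {
  double bin, x0, y0;
  int nbx, nby;
  std::vector<std::vector<int> > bins;

  void build(const double* x, const double* y, const std::vector<int>& ids,
             double bin_size) {
    bin = bin_size;
    double xmin = 0.0, ymin = 0.0, xmax = bin, ymax = bin;
    if (!ids.empty()) {
      xmin = xmax = x[ids[0]]; ymin = ymax = y[ids[0]];
      for (size_t k = 1; k < ids.size(); ++k) {
        int i = ids[k];
        xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
        ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      }
    }
    x0 = xmin; y0 = ymin;
    nbx = (int)std::floor((xmax - x0) / bin) + 1;
    nby = (int)std::floor((ymax - y0) / bin) + 1;
    bins.assign((size_t)nbx * nby, std::vector<int>());
    for (size_t k = 0; k < ids.size(); ++k) {
      int i = ids[k];
      int bx = (int)std::floor((x[i] - x0) / bin);
      int by = (int)std::floor((y[i] - y0) / bin);
      bins[bx + (size_t)nbx * by].push_back(i);
    }
  }

  // All stored ids within `radius` (<=) of point (px, py), excluding `self`.
  void query(double px, double py, double radius, int self,
             const double* x, const double* y, std::vector<int>& out) const {
    out.clear();
    int rings = (int)std::ceil(radius / bin);
    int bx = (int)std::floor((px - x0) / bin);
    int by = (int)std::floor((py - y0) / bin);
    double r2 = radius * radius;
    for (int dy = -rings; dy <= rings; ++dy) {
      int cy = by + dy;
      if (cy < 0 || cy >= nby) continue;
      for (int dx = -rings; dx <= rings; ++dx) {
        int cx = bx + dx;
        if (cx < 0 || cx >= nbx) continue;
        const std::vector<int>& cell = bins[cx + (size_t)nbx * cy];
        for (size_t k = 0; k < cell.size(); ++k) {
          int j = cell[k];
          if (j == self) continue;
          double ddx = x[j] - px, ddy = y[j] - py;
          if (ddx * ddx + ddy * ddy <= r2) out.push_back(j);
        }
      }
    }
  }
};

#endif
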