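#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over the cell-centre lattice of a cost raster.
// Edge weight between adjacent cells a,b: step_length * (cost_a + cost_b) / 2,
// step_length = res (axis) or res*sqrt(2) (diagonal). Raster is nx x ny,
// cell (ix, iy) 0-based covers [ix*res, (ix+1)*res) x [iy*res, (iy+1)*res).
// [[Rcpp::export]]
List cpp_nav_field(NumericMatrix cost, IntegerMatrix dest_cells, double res,
                   int connectivity) {
  const int nx = cost.nrow(), ny = cost.ncol();
  const int n = nx * ny;
  const double SQ2 = std::sqrt(2.0);

  std::vector<double> dist(n, R_PosInf);
  std::vector<bool> done(n, false);
  std::vector<bool> is_dest(n, false);

  typedef std::pair<double, int> QE; // (dist, idx), idx = ix + nx*iy
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  for (int k = 0; k < dest_cells.nrow(); ++k) {
    int ix = dest_cells(k, 0), iy = dest_cells(k, 1);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny)
      stop("destination cell outside raster");
    int idx = ix + nx * iy;
    is_dest[idx] = true;
    dist[idx] = 0.0;
    pq.push(QE(0.0, idx));
  }

  const int ndir = (connectivity == 4) ? 4 : 8;
  const int DX[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int DY[8] = {0, 0, 1, -1, 1, -1, 1, -1};

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = true;
    int ux = u % nx, uy = u / nx;
    double cu = cost[u];
    for (int d = 0; d < ndir; ++d) {
      int vx = ux + DX[d], vy = uy + DY[d];
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny) continue;
      int v = vx + nx * vy;
      if (done[v]) continue;
      double step = (d < 4) ? res : res * SQ2;
      double nd = dist[u] + step * 0.5 * (cu + cost[v]);
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(QE(nd, v));
      }
    }
  }

  NumericMatrix cum(nx, ny), dirx(nx, ny), diry(nx, ny);
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix)
      cum(ix, iy) = dist[ix + nx * iy];

  // Desired direction: unit vector toward the lowest-cumulative-cost
  // neighbour; zero at destination and unreachable cells. Ties broken by
  // fixed neighbour order (E, W, N, S, NE, SE, NW, SW).
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      int idx = ix + nx * iy;
      if (is_dest[idx] || !R_FINITE(dist[idx])) continue;
      double best = R_PosInf;
      int bd = -1;
      for (int d = 0; d < ndir; ++d) {
        int vx = ix + DX[d], vy = iy + DY[d];
        if (vx < 0 || vx >= nx || vy < 0 || vy >= ny) continue;
        double dv = dist[vx + nx * vy];
        if (dv < best) { best = dv; bd = d; }
      }
      if (bd >= 0 && best < dist[idx]) {
        double norm = (bd < 4) ? 1.0 : SQ2;
        dirx(ix, iy) = DX[bd] / norm;
        diry(ix, iy) = DY[bd] / norm;
      }
    }
  }

  return List::create(_["cumcost"] = cum, _["dir_x"] = dirx, _["dir_y"] = diry);
}
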