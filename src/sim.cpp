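#include <Rcpp.h>
#include "neighbors.h"
#include <vector>
#include <cmath>
using namespace Rcpp;

// Land-use category codes (match R side): 0 other, 1 road, 2 building, 3 water.
static const int LU_BUILDING = 2;
static const int LU_WATER = 3;

// Anticipatory collision-avoidance force exerted on agent i by agent j.
// Time to collision tau_c solves |d + v_rel t| = 2 r from linear
// extrapolation; force magnitude k / tau_c^2 * exp(-tau_c / tau0) along the
// predicted separation at closest approach; zero without a projected
// collision or beyond the time cutoff. Already-overlapping pairs use a small
// tau_c floor (speed capping keeps the dynamics bounded).
static inline void ttc_force(double dx, double dy, double dvx, double dvy,
                             double k, double tau0, double r2sum,
                             double cutoff, double tau_floor,
                             double& fx, double& fy) {
  fx = 0.0; fy = 0.0;
  double a = dvx * dvx + dvy * dvy;
  double b = dx * dvx + dy * dvy;          // d . v_rel
  double c = dx * dx + dy * dy - r2sum * r2sum;
  double tau_c;
  if (c <= 0.0) {
    tau_c = tau_floor;                     // already in contact
  } else {
    if (a < 1e-12 || b >= 0.0) return;     // not approaching
    double disc = b * b - a * c;
    if (disc <= 0.0) return;               // paths miss
    tau_c = (-b - std::sqrt(disc)) / a;
    if (tau_c <= 0.0 || tau_c > cutoff) return;
    if (tau_c < tau_floor) tau_c = tau_floor;
  }
  // separation direction at predicted contact, pushing i away from j
  double sx = -(dx + dvx * tau_c), sy = -(dy + dvy * tau_c);
  double sn = std::sqrt(sx * sx + sy * sy);
  if (sn < 1e-12) return;
  double mag = k / (tau_c * tau_c) * std::exp(-tau_c / tau0);
  fx = mag * sx / sn;
  fy = mag * sy / sn;
}

struct Raster {
  const int* lu;
  int nx, ny;
  double res;
  inline int code(double x, double y) const {
    int ix = (int)std::floor(x / res), iy = (int)std::floor(y / res);
    if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
    if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
    return lu[ix + (size_t)nx * iy];
  }
  inline bool inside(double x, double y) const {
    return x >= 0.0 && y >= 0.0 && x < nx * res && y < ny * res;
  }
};

// Movement blocking: entering a building (or water) cell is blocked unless
// the agent is already inside one (agents start indoors and must walk out);
// leaving the domain is always blocked.
static inline bool blocked(const Raster& r, double x, double y, int cur_code) {
  if (!r.inside(x, y)) return true;
  int c = r.code(x, y);
  if (c == LU_BUILDING && cur_code != LU_BUILDING) return true;
  if (c == LU_WATER && cur_code != LU_WATER) return true;
  return false;
}

// [[Rcpp::export]]
List cpp_run_sim(IntegerMatrix landuse, NumericMatrix cumcost,
                 NumericMatrix dirx, NumericMatrix diry,
                 NumericMatrix dest, double res,
                 NumericMatrix pos0, NumericVector att0, LogicalVector leader,
                 Function eps_fn, double mu, double radius,
                 double comm_interval, double threshold,
                 double v0, double tau_alpha, double dt,
                 double force_k, double force_tau0, double agent_radius,
                 double force_cutoff, double overshoot_cap,
                 double arrival_radius, double horizon, double record_interval,
                 bool retain_evacuated) {
  const int n = pos0.nrow();
  const int nd = dest.nrow();
  Raster ras;
  ras.lu = INTEGER(landuse);
  ras.nx = landuse.nrow(); ras.ny = landuse.ncol(); ras.res = res;

  std::vector<double> x(n), y(n), vx(n, 0.0), vy(n, 0.0), A(n);
  std::vector<int> state(n, 0); // 0 idle, 1 evacuating, 2 evacuated
  std::vector<double> arrival(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); A[i] = att0[i];
  }

  const long n_steps = (long)std::lround(horizon / dt);
  const long comm_every = std::max(1L, (long)std::lround(comm_interval / dt));
  const long rec_every = std::max(1L, (long)std::lround(record_interval / dt));
  const double vmax = v0 * overshoot_cap;
  const double force_range =
      2.0 * vmax * force_cutoff + 2.0 * agent_radius;
  const double tau_floor = dt;

  std::vector<double> times;
  List snap_pos, snap_att, snap_state;

  SpatialHash hash, hash_moving;
  std::vector<int> active_ids, moving_ids, nb;
  std::vector<double> newA(n), fx_acc(n), fy_acc(n);

  int n_evacuated = 0;
  double last_dA = R_PosInf;
  double t_end = 0.0;
  bool done_all = false;

  for (long step = 0; step <= n_steps; ++step) {
    double t = step * dt;
    t_end = t;

    // --- communication + decisions every comm_interval ------------------
    if (step % comm_every == 0) {
      // participants: sources j may include evacuated agents when retained;
      // receivers are non-evacuated, non-leader agents
      active_ids.clear();
      for (int i = 0; i < n; ++i)
        if (state[i] != 2 || retain_evacuated) active_ids.push_back(i);
      NumericVector Acur(n);
      for (int i = 0; i < n; ++i) Acur[i] = A[i];
      NumericVector eps = as<NumericVector>(eps_fn(Acur));
      if (eps.size() != n) stop("epsilon_fn must return one value per agent");
      last_dA = 0.0;
      if (!active_ids.empty()) {
        hash.build(x.data(), y.data(), active_ids, radius);
        for (int i = 0; i < n; ++i) newA[i] = A[i];
        for (size_t k = 0; k < active_ids.size(); ++k) {
          int i = active_ids[k];
          if (state[i] == 2 || leader[i]) continue;
          hash.query(x[i], y[i], radius, i, x.data(), y.data(), nb);
          double s = 0.0; int cnt = 0;
          for (size_t m = 0; m < nb.size(); ++m) {
            int j = nb[m];
            if (std::fabs(A[i] - A[j]) < eps[i]) { s += A[j] - A[i]; ++cnt; }
          }
          if (cnt > 0) {
            double a2 = A[i] + mu * s / cnt;
            if (a2 > 1.0) a2 = 1.0; else if (a2 < -1.0) a2 = -1.0;
            newA[i] = a2;
            double d = std::fabs(a2 - A[i]);
            if (d > last_dA) last_dA = d;
          }
        }
        for (int i = 0; i < n; ++i) A[i] = newA[i];
      }
      // synchronous decisions, both directions (start and stop evacuating)
      for (int i = 0; i < n; ++i)
        if (state[i] != 2) state[i] = (A[i] >= threshold) ? 1 : 0;
    }

    // --- snapshot --------------------------------------------------------
    if (step % rec_every == 0) {
      times.push_back(t);
      NumericMatrix p(n, 2); NumericVector a(n); IntegerVector st(n);
      for (int i = 0; i < n; ++i) {
        p(i, 0) = x[i]; p(i, 1) = y[i]; a[i] = A[i]; st[i] = state[i];
      }
      snap_pos.push_back(p); snap_att.push_back(a); snap_state.push_back(st);
    }

    if (step == n_steps) break;

    // --- early exits ------------------------------------------------------
    if (n_evacuated == n) { done_all = true; break; }
    if (step % comm_every == 0 && step > 0) {
      bool any_evac = false;
      double max_sp2 = 0.0;
      for (int i = 0; i < n; ++i) {
        if (state[i] == 1) { any_evac = true; break; }
        double sp2 = vx[i] * vx[i] + vy[i] * vy[i];
        if (sp2 > max_sp2) max_sp2 = sp2;
      }
      // attitude fixed point with nobody moving: state can never change
      if (!any_evac && max_sp2 < 1e-12 && last_dA < 1e-12) {
        done_all = true; break;
      }
    }

    // --- movement step (explicit Euler on the social-force model) --------
    // anticipatory forces require relative motion, so only pairs involving
    // a moving agent are evaluated: movers scan all active agents, resting
    // agents scan movers only
    active_ids.clear();
    moving_ids.clear();
    for (int i = 0; i < n; ++i) {
      if (state[i] == 2) continue;
      active_ids.push_back(i);
      if (state[i] == 1 || vx[i] * vx[i] + vy[i] * vy[i] > 1e-12)
        moving_ids.push_back(i);
    }
    if (!active_ids.empty())
      hash.build(x.data(), y.data(), active_ids, radius);
    hash_moving.build(x.data(), y.data(), moving_ids, radius);
    for (size_t k = 0; k < active_ids.size(); ++k) {
      int i = active_ids[k];
      fx_acc[i] = 0.0; fy_acc[i] = 0.0;
      bool i_moving = state[i] == 1 || vx[i] * vx[i] + vy[i] * vy[i] > 1e-12;
      const SpatialHash& h = i_moving ? hash : hash_moving;
      h.query(x[i], y[i], force_range, i, x.data(), y.data(), nb);
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double fx, fy;
        ttc_force(x[j] - x[i], y[j] - y[i], vx[j] - vx[i], vy[j] - vy[i],
                  force_k, force_tau0, 2.0 * agent_radius, force_cutoff,
                  tau_floor, fx, fy);
        fx_acc[i] += fx; fy_acc[i] += fy;
      }
    }
    for (size_t k = 0; k < active_ids.size(); ++k) {
      int i = active_ids[k];
      // resting non-evacuating agents with no force stay in equilibrium
      if (state[i] == 0 && fx_acc[i] == 0.0 && fy_acc[i] == 0.0 &&
          vx[i] * vx[i] + vy[i] * vy[i] <= 1e-12) {
        vx[i] = 0.0; vy[i] = 0.0;
        continue;
      }
      double ex = 0.0, ey = 0.0;
      if (state[i] == 1) {
        int ix = (int)std::floor(x[i] / res), iy = (int)std::floor(y[i] / res);
        if (ix < 0) ix = 0; if (ix >= ras.nx) ix = ras.nx - 1;
        if (iy < 0) iy = 0; if (iy >= ras.ny) iy = ras.ny - 1;
        ex = dirx(ix, iy); ey = diry(ix, iy);
        // the least-cost field treats buildings as crossable at high cost;
        // movement does not, so when the steepest-descent neighbour is not
        // enterable, re-aim at the cheapest enterable neighbour (the agent
        // follows the wall around the obstacle)
        if (ex != 0.0 || ey != 0.0) {
          int cur = ras.code(x[i], y[i]);
          int sx2 = (ex > 1e-12) - (ex < -1e-12);
          int sy2 = (ey > 1e-12) - (ey < -1e-12);
          double tcx = (ix + sx2 + 0.5) * res, tcy = (iy + sy2 + 0.5) * res;
          double cum_here = cumcost(ix, iy);
          bool t_ok = !blocked(ras, tcx, tcy, cur);
          if (!t_ok && ras.inside(tcx, tcy) &&
              ras.code(tcx, tcy) == LU_BUILDING &&
              cumcost(ix + sx2, iy + sy2) < cum_here)
            t_ok = true;  // descending cut-through is allowed
          if (!t_ok) {
            double best = R_PosInf;
            int bdx = 0, bdy = 0;
            for (int dy2 = -1; dy2 <= 1; ++dy2) {
              for (int dx2 = -1; dx2 <= 1; ++dx2) {
                if (dx2 == 0 && dy2 == 0) continue;
                int nx2 = ix + dx2, ny2 = iy + dy2;
                if (nx2 < 0 || nx2 >= ras.nx || ny2 < 0 || ny2 >= ras.ny)
                  continue;
                double ccx = (nx2 + 0.5) * res, ccy = (ny2 + 0.5) * res;
                double cval = cumcost(nx2, ny2);
                bool ok = !blocked(ras, ccx, ccy, cur) ||
                  (ras.code(ccx, ccy) == LU_BUILDING && cval < cum_here);
                if (!ok) continue;
                if (cval < best) { best = cval; bdx = dx2; bdy = dy2; }
              }
            }
            if (R_FINITE(best)) {
              double nrm = std::sqrt((double)(bdx * bdx + bdy * bdy));
              ex = bdx / nrm; ey = bdy / nrm;
            } else { ex = 0.0; ey = 0.0; }
          }
        }
      }
      double ax = (v0 * ex - vx[i]) / tau_alpha + fx_acc[i];
      double ay = (v0 * ey - vy[i]) / tau_alpha + fy_acc[i];
      vx[i] += ax * dt; vy[i] += ay * dt;
      double sp = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
      if (sp > vmax) { vx[i] *= vmax / sp; vy[i] *= vmax / sp; }
      double nxp = x[i] + vx[i] * dt, nyp = y[i] + vy[i] * dt;
      int cur = ras.code(x[i], y[i]);
      int cix = (int)std::floor(x[i] / res), ciy = (int)std::floor(y[i] / res);
      if (cix < 0) cix = 0; if (cix >= ras.nx) cix = ras.nx - 1;
      if (ciy < 0) ciy = 0; if (ciy >= ras.ny) ciy = ras.ny - 1;
      double cum_cur = cumcost(cix, ciy);
      // evacuating agents may cut through a building cell when that
      // strictly descends the cost field (the 1 m raster over-blocks
      // narrow passable gaps); all other building entries are walls
      bool evac_i = state[i] == 1;
      // local lambda-free helper via macro-ish inline checks
      #define MOVE_BLOCKED(px, py)         (blocked(ras, (px), (py), cur) &&          !(evac_i && ras.inside((px), (py)) &&            ras.code((px), (py)) == LU_BUILDING &&            cumcost(std::min(std::max((int)std::floor((px) / res), 0), ras.nx - 1),                    std::min(std::max((int)std::floor((py) / res), 0), ras.ny - 1)) < cum_cur))
      if (!MOVE_BLOCKED(nxp, nyp)) {
        x[i] = nxp; y[i] = nyp;
      } else if (!MOVE_BLOCKED(nxp, y[i])) {
        x[i] = nxp; vy[i] = 0.0;       // slide along wall, cancel normal part
      } else if (!MOVE_BLOCKED(x[i], nyp)) {
        y[i] = nyp; vx[i] = 0.0;
      } else {
        vx[i] = 0.0; vy[i] = 0.0;
      }
      #undef MOVE_BLOCKED
      // arrival check: evacuating agents reaching any destination
      if (state[i] == 1) {
        for (int d = 0; d < nd; ++d) {
          double ddx = x[i] - dest(d, 0), ddy = y[i] - dest(d, 1);
          if (std::sqrt(ddx * ddx + ddy * ddy) <= arrival_radius) {
            state[i] = 2;
            arrival[i] = t + dt;
            ++n_evacuated;
            break;
          }
        }
      }
    }
  }

  // terminal snapshot when the loop exited early
  if (done_all && (times.empty() || times.back() < t_end)) {
    times.push_back(t_end);
    NumericMatrix p(n, 2); NumericVector a(n); IntegerVector st(n);
    for (int i = 0; i < n; ++i) {
      p(i, 0) = x[i]; p(i, 1) = y[i]; a[i] = A[i]; st[i] = state[i];
    }
    snap_pos.push_back(p); snap_att.push_back(a); snap_state.push_back(st);
  }

  NumericMatrix fpos(n, 2); NumericVector fatt(n); IntegerVector fstate(n);
  NumericMatrix fvel(n, 2);
  for (int i = 0; i < n; ++i) {
    fpos(i, 0) = x[i]; fpos(i, 1) = y[i];
    fvel(i, 0) = vx[i]; fvel(i, 1) = vy[i];
    fatt[i] = A[i]; fstate[i] = state[i];
  }
  return List::create(
      _["times"] = times, _["pos"] = snap_pos, _["att"] = snap_att,
      _["state"] = snap_state, _["arrival"] = wrap(arrival),
      _["final_pos"] = fpos, _["final_vel"] = fvel, _["final_att"] = fatt,
      _["final_state"] = fstate, _["t_end"] = t_end,
      _["ended_early"] = done_all);
}
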