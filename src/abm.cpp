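// Brownian-dynamics core of the reduced-scale actomyosin network simulator.
//
// Units: nm, pN, s. Overdamped dynamics: dx/dt = F / gamma (+ optional
// thermal noise). F-actin = bead-spring chains with worm-like-chain bending
// (kappa = l_p kB T); myosin thick filaments = 4-node backbones with stiff
// springs and hinge bending, two motor arms per node. Arms bind to filament
// segments within a capture radius, take stochastic 7 nm steps toward the
// barbed end with a linear force-velocity relation, and unbind with
// load-dependent (catch-like) kinetics inside the activation disc or at a
// constant high rate outside it (the blebbistatin-inhibited, non-processive
// state). All randomness comes from R's RNG so set.seed() gives identical
// trajectories.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double dt, k_seg, rest_seg, kappa_fil, k_back, rest_back, kappa_back;
  double k_arm, gamma_bead, gamma_mot, v0, f_stall, k_on, k0, f0, k_off_out;
  double capture, act_x, act_y, act_r, step_nm, noise_kbt;
  int rebuild_every;
};

Params read_params(const List& pl) {
  Params p;
  p.dt = pl["dt"]; p.k_seg = pl["k_seg"]; p.rest_seg = pl["rest_seg"];
  p.kappa_fil = pl["kappa_fil"]; p.k_back = pl["k_back"];
  p.rest_back = pl["rest_back"]; p.kappa_back = pl["kappa_back"];
  p.k_arm = pl["k_arm"]; p.gamma_bead = pl["gamma_bead"];
  p.gamma_mot = pl["gamma_mot"]; p.v0 = pl["v0"]; p.f_stall = pl["f_stall"];
  p.k_on = pl["k_on"]; p.k0 = pl["k0"]; p.f0 = pl["f0"];
  p.k_off_out = pl["k_off_out"]; p.capture = pl["capture"];
  p.act_x = pl["act_x"]; p.act_y = pl["act_y"]; p.act_r = pl["act_r"];
  p.step_nm = pl["step_nm"]; p.noise_kbt = pl["noise_kbt"];
  p.rebuild_every = pl["rebuild_every"];
  return p;
}

struct State {
  // filament beads
  std::vector<double> bx, by, fbx, fby;   // positions and forces
  std::vector<int> fil_first, fil_len;    // 0-based first bead, bead count
  std::vector<int> seg_first;             // first segment index per filament
  std::vector<char> anchored;
  // motor nodes (4 per motor) and arms (8 per motor)
  std::vector<double> mx, my, fmx, fmy;
  std::vector<int> arm_bound, arm_fil, arm_seg;  // seg 0-based within filament
  std::vector<double> arm_off;
  int nb, nf, nm, narm, nseg;
};

inline int arm_node(int a) { return (a % 8) / 2 + 4 * (a / 8); }

// --- cell list over filament segments --------------------------------------
struct CellList {
  double cell, x0, y0;
  int ncx, ncy;
  std::vector<std::vector<int>> cells;  // segment ids (global)
  void build(const State& s, double capture) {
    cell = std::max(400.0, 2.0 * capture);
    double xmin = 1e300, xmax = -1e300, ymin = 1e300, ymax = -1e300;
    for (int i = 0; i < s.nb; ++i) {
      xmin = std::min(xmin, s.bx[i]); xmax = std::max(xmax, s.bx[i]);
      ymin = std::min(ymin, s.by[i]); ymax = std::max(ymax, s.by[i]);
    }
    x0 = xmin - cell; y0 = ymin - cell;
    ncx = std::max(1, (int)((xmax - x0) / cell) + 2);
    ncy = std::max(1, (int)((ymax - y0) / cell) + 2);
    cells.assign((size_t)ncx * ncy, {});
    int g = 0;
    for (int f = 0; f < s.nf; ++f) {
      int fb = s.fil_first[f];
      for (int q = 0; q < s.fil_len[f] - 1; ++q, ++g) {
        double mxs = 0.5 * (s.bx[fb + q] + s.bx[fb + q + 1]);
        double mys = 0.5 * (s.by[fb + q] + s.by[fb + q + 1]);
        int cx = std::min(ncx - 1, std::max(0, (int)((mxs - x0) / cell)));
        int cy = std::min(ncy - 1, std::max(0, (int)((mys - y0) / cell)));
        cells[(size_t)cy * ncx + cx].push_back(g);
      }
    }
  }
};

void seg_lookup(const State& s, int g, int& f, int& q) {
  // global segment id -> (filament, local segment); linear scan cached by caller
  int lo = 0, hi = s.nf - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (s.seg_first[mid] <= g) lo = mid; else hi = mid - 1;
  }
  f = lo; q = g - s.seg_first[lo];
}

void compute_forces(State& s, const Params& p, std::vector<double>* tension) {
  std::fill(s.fbx.begin(), s.fbx.end(), 0.0);
  std::fill(s.fby.begin(), s.fby.end(), 0.0);
  std::fill(s.fmx.begin(), s.fmx.end(), 0.0);
  std::fill(s.fmy.begin(), s.fmy.end(), 0.0);
  if (tension) tension->assign(s.nseg, 0.0);

  // filament extensional springs
  int g = 0;
  for (int f = 0; f < s.nf; ++f) {
    int fb = s.fil_first[f];
    for (int q = 0; q < s.fil_len[f] - 1; ++q, ++g) {
      int a = fb + q, b = fb + q + 1;
      double dx = s.bx[b] - s.bx[a], dy = s.by[b] - s.by[a];
      double l = std::sqrt(dx * dx + dy * dy);
      if (l < 1e-9) continue;
      double t = p.k_seg * (l - p.rest_seg);
      if (tension) (*tension)[g] = t;
      double fx = t * dx / l, fy = t * dy / l;
      s.fbx[a] += fx; s.fby[a] += fy;
      s.fbx[b] -= fx; s.fby[b] -= fy;
    }
  }

  // filament bending (discrete WLC, kb = kappa / l0)
  double kb = p.kappa_fil / p.rest_seg;
  for (int f = 0; f < s.nf; ++f) {
    int fb = s.fil_first[f];
    for (int q = 1; q < s.fil_len[f] - 1; ++q) {
      int i0 = fb + q - 1, i1 = fb + q, i2 = fb + q + 1;
      double r1x = s.bx[i1] - s.bx[i0], r1y = s.by[i1] - s.by[i0];
      double r2x = s.bx[i2] - s.bx[i1], r2y = s.by[i2] - s.by[i1];
      double l1 = std::sqrt(r1x * r1x + r1y * r1y);
      double l2 = std::sqrt(r2x * r2x + r2y * r2y);
      if (l1 < 1e-9 || l2 < 1e-9) continue;
      double e1x = r1x / l1, e1y = r1y / l1, e2x = r2x / l2, e2y = r2y / l2;
      double c = e1x * e2x + e1y * e2y;
      double f0x = -kb * (e2x - c * e1x) / l1, f0y = -kb * (e2y - c * e1y) / l1;
      double f2x = kb * (e1x - c * e2x) / l2, f2y = kb * (e1y - c * e2y) / l2;
      s.fbx[i0] += f0x; s.fby[i0] += f0y;
      s.fbx[i2] += f2x; s.fby[i2] += f2y;
      s.fbx[i1] -= f0x + f2x; s.fby[i1] -= f0y + f2y;
    }
  }

  // motor backbones: springs + hinges
  double kbm = p.kappa_back / p.rest_back;
  for (int mI = 0; mI < s.nm; ++mI) {
    int b0 = 4 * mI;
    for (int q = 0; q < 3; ++q) {
      int a = b0 + q, b = b0 + q + 1;
      double dx = s.mx[b] - s.mx[a], dy = s.my[b] - s.my[a];
      double l = std::sqrt(dx * dx + dy * dy);
      if (l < 1e-9) continue;
      double t = p.k_back * (l - p.rest_back);
      double fx = t * dx / l, fy = t * dy / l;
      s.fmx[a] += fx; s.fmy[a] += fy;
      s.fmx[b] -= fx; s.fmy[b] -= fy;
    }
    for (int q = 1; q < 3; ++q) {
      int i0 = b0 + q - 1, i1 = b0 + q, i2 = b0 + q + 1;
      double r1x = s.mx[i1] - s.mx[i0], r1y = s.my[i1] - s.my[i0];
      double r2x = s.mx[i2] - s.mx[i1], r2y = s.my[i2] - s.my[i1];
      double l1 = std::sqrt(r1x * r1x + r1y * r1y);
      double l2 = std::sqrt(r2x * r2x + r2y * r2y);
      if (l1 < 1e-9 || l2 < 1e-9) continue;
      double e1x = r1x / l1, e1y = r1y / l1, e2x = r2x / l2, e2y = r2y / l2;
      double c = e1x * e2x + e1y * e2y;
      double f0x = -kbm * (e2x - c * e1x) / l1, f0y = -kbm * (e2y - c * e1y) / l1;
      double f2x = kbm * (e1x - c * e2x) / l2, f2y = kbm * (e1y - c * e2y) / l2;
      s.fmx[i0] += f0x; s.fmy[i0] += f0y;
      s.fmx[i2] += f2x; s.fmy[i2] += f2y;
      s.fmx[i1] -= f0x + f2x; s.fmy[i1] -= f0y + f2y;
    }
  }

  // motor arm linker springs (node <-> attachment point on the segment);
  // the reaction on the filament is shared between the two segment beads
  for (int a = 0; a < s.narm; ++a) {
    if (!s.arm_bound[a]) continue;
    int f = s.arm_fil[a], q = s.arm_seg[a];
    int fb = s.fil_first[f];
    int i1 = fb + q, i2 = fb + q + 1;
    double w = s.arm_off[a] / p.rest_seg;
    if (w < 0) w = 0; if (w > 1) w = 1;
    double hx = (1 - w) * s.bx[i1] + w * s.bx[i2];
    double hy = (1 - w) * s.by[i1] + w * s.by[i2];
    int nd = arm_node(a);
    double fx = p.k_arm * (hx - s.mx[nd]);  // force on the node, toward head
    double fy = p.k_arm * (hy - s.my[nd]);
    s.fmx[nd] += fx; s.fmy[nd] += fy;
    s.fbx[i1] -= (1 - w) * fx; s.fby[i1] -= (1 - w) * fy;
    s.fbx[i2] -= w * fx; s.fby[i2] -= w * fy;
  }
}

void kinetics(State& s, const Params& p, const CellList& cl, bool try_bind,
              double bind_dt) {
  double pr_on = 1.0 - std::exp(-p.k_on * bind_dt);
  // per-motor activation flag (centre of the backbone inside the disc?)
  std::vector<char> inside_m(s.nm);
  for (int mI = 0; mI < s.nm; ++mI) {
    double cx = 0, cy = 0;
    for (int q = 0; q < 4; ++q) { cx += s.mx[4 * mI + q]; cy += s.my[4 * mI + q]; }
    cx *= 0.25; cy *= 0.25;
    double ddx = cx - p.act_x, ddy = cy - p.act_y;
    inside_m[mI] = (ddx * ddx + ddy * ddy) <= p.act_r * p.act_r;
  }
  for (int a = 0; a < s.narm; ++a) {
    int nd = arm_node(a);
    int mI = nd / 4;
    bool inside = inside_m[mI];

    if (s.arm_bound[a]) {
      int f = s.arm_fil[a], q = s.arm_seg[a];
      int fb = s.fil_first[f];
      int i1 = fb + q, i2 = fb + q + 1;
      double w = s.arm_off[a] / p.rest_seg;
      double hx = (1 - w) * s.bx[i1] + w * s.bx[i2];
      double hy = (1 - w) * s.by[i1] + w * s.by[i2];
      double sx = p.k_arm * (s.mx[nd] - hx);  // spring force on the head
      double sy = p.k_arm * (s.my[nd] - hy);
      double fmag = std::sqrt(sx * sx + sy * sy);
      // unbinding
      double koff = inside ? p.k0 * std::exp(-fmag / p.f0) : p.k_off_out;
      if (unif_rand() < 1.0 - std::exp(-koff * p.dt)) {
        s.arm_bound[a] = 0;
        continue;
      }
      // stepping toward the barbed end (bead index increasing)
      double dxs = s.bx[i2] - s.bx[i1], dys = s.by[i2] - s.by[i1];
      double l = std::sqrt(dxs * dxs + dys * dys);
      if (l > 1e-9) {
        double load = -(sx * dxs + sy * dys) / l;  // opposing the step
        if (load < 0) load = 0;
        double v = p.v0 * std::max(0.0, 1.0 - load / p.f_stall);
        if (v > 0 && unif_rand() < v * p.dt / p.step_nm) {
          s.arm_off[a] += p.step_nm;
          if (s.arm_off[a] > p.rest_seg) {
            s.arm_off[a] -= p.rest_seg;
            s.arm_seg[a] += 1;
            if (s.arm_seg[a] >= s.fil_len[f] - 1) s.arm_bound[a] = 0;  // ran off the end
          }
        }
      }
    } else {
      if (!try_bind) continue;
      // binding: nearest segment within the capture radius
      double px = s.mx[nd], py = s.my[nd];
      int cxi = std::min(cl.ncx - 1, std::max(0, (int)((px - cl.x0) / cl.cell)));
      int cyi = std::min(cl.ncy - 1, std::max(0, (int)((py - cl.y0) / cl.cell)));
      double best = p.capture * p.capture;
      int bestf = -1, bestq = -1; double bestoff = 0;
      for (int oy = -1; oy <= 1; ++oy) {
        for (int ox = -1; ox <= 1; ++ox) {
          int gx = cxi + ox, gy = cyi + oy;
          if (gx < 0 || gy < 0 || gx >= cl.ncx || gy >= cl.ncy) continue;
          for (int gseg : cl.cells[(size_t)gy * cl.ncx + gx]) {
            int f, q; seg_lookup(s, gseg, f, q);
            int fb = s.fil_first[f];
            double ax = s.bx[fb + q], ay = s.by[fb + q];
            double bxx = s.bx[fb + q + 1], byy = s.by[fb + q + 1];
            double ex = bxx - ax, ey = byy - ay;
            double l2 = ex * ex + ey * ey;
            if (l2 < 1e-12) continue;
            double t = ((px - ax) * ex + (py - ay) * ey) / l2;
            if (t < 0) t = 0; if (t > 1) t = 1;
            double qx = ax + t * ex - px, qy = ay + t * ey - py;
            double d2 = qx * qx + qy * qy;
            if (d2 < best) {
              best = d2; bestf = f; bestq = q;
              bestoff = t * std::sqrt(l2);
            }
          }
        }
      }
      if (bestf >= 0 && unif_rand() < pr_on) {
        s.arm_bound[a] = 1;
        s.arm_fil[a] = bestf;
        s.arm_seg[a] = bestq;
        // snap to the 7-nm binding-site lattice
        double off = p.step_nm * std::floor(bestoff / p.step_nm + 0.5);
        if (off > p.rest_seg) off = p.rest_seg;
        s.arm_off[a] = off;
      }
    }
  }
}

State unpack(const List& st) {
  State s;
  NumericMatrix bp = st["bead_pos"];
  s.nb = bp.nrow();
  s.bx.resize(s.nb); s.by.resize(s.nb);
  for (int i = 0; i < s.nb; ++i) { s.bx[i] = bp(i, 0); s.by[i] = bp(i, 1); }
  s.fbx.assign(s.nb, 0); s.fby.assign(s.nb, 0);
  IntegerVector ff = st["fil_first"], fl = st["fil_len"];
  s.nf = ff.size();
  s.fil_first.resize(s.nf); s.fil_len.resize(s.nf); s.seg_first.resize(s.nf);
  int g = 0;
  for (int f = 0; f < s.nf; ++f) {
    s.fil_first[f] = ff[f] - 1;
    s.fil_len[f] = fl[f];
    s.seg_first[f] = g;
    g += fl[f] - 1;
  }
  s.nseg = g;
  LogicalVector an = st["anchored"];
  s.anchored.resize(s.nb);
  for (int i = 0; i < s.nb; ++i) s.anchored[i] = an[i];
  NumericMatrix mp = st["mot_pos"];
  int nmn = mp.nrow();
  s.nm = nmn / 4;
  s.mx.resize(nmn); s.my.resize(nmn);
  for (int i = 0; i < nmn; ++i) { s.mx[i] = mp(i, 0); s.my[i] = mp(i, 1); }
  s.fmx.assign(nmn, 0); s.fmy.assign(nmn, 0);
  NumericMatrix am = st["arms"];
  s.narm = am.nrow();
  s.arm_bound.resize(s.narm); s.arm_fil.resize(s.narm);
  s.arm_seg.resize(s.narm); s.arm_off.resize(s.narm);
  for (int a = 0; a < s.narm; ++a) {
    s.arm_bound[a] = (int)am(a, 0);
    s.arm_fil[a] = (int)am(a, 1) - 1;
    s.arm_seg[a] = (int)am(a, 2) - 1;
    s.arm_off[a] = am(a, 3);
  }
  return s;
}

List pack_state(const State& s) {
  NumericMatrix bp(s.nb, 2), mp(4 * s.nm, 2), am(s.narm, 4);
  for (int i = 0; i < s.nb; ++i) { bp(i, 0) = s.bx[i]; bp(i, 1) = s.by[i]; }
  for (int i = 0; i < 4 * s.nm; ++i) { mp(i, 0) = s.mx[i]; mp(i, 1) = s.my[i]; }
  for (int a = 0; a < s.narm; ++a) {
    am(a, 0) = s.arm_bound[a];
    am(a, 1) = s.arm_fil[a] + 1;
    am(a, 2) = s.arm_seg[a] + 1;
    am(a, 3) = s.arm_off[a];
  }
  return List::create(_["bead_pos"] = bp, _["mot_pos"] = mp, _["arms"] = am);
}

}  // namespace

// [[Rcpp::export]]
List abm_simulate_cpp(List state, List params, int n_steps, int snap_every) {
  Params p = read_params(params);
  State s = unpack(state);
  CellList cl;
  cl.build(s, p.capture);

  int nsnap = snap_every > 0 ? n_steps / snap_every + 1 : 0;
  NumericVector snaps_bead(snap_every > 0 ? (R_xlen_t)s.nb * 2 * nsnap : 0);
  NumericVector snaps_mot(snap_every > 0 ? (R_xlen_t)4 * s.nm * 2 * nsnap : 0);
  NumericMatrix snap_tension(snap_every > 0 ? s.nseg : 0, nsnap);
  IntegerMatrix snap_bound(snap_every > 0 ? s.narm : 0, nsnap);
  IntegerVector snap_steps(nsnap);

  std::vector<double> tension;
  int ks = 0;
  double max_move2_limit = p.rest_seg * p.rest_seg;

  auto record = [&](int step) {
    compute_forces(s, p, &tension);
    for (int i = 0; i < s.nb; ++i) {
      snaps_bead[(R_xlen_t)ks * 2 * s.nb + i] = s.bx[i];
      snaps_bead[(R_xlen_t)ks * 2 * s.nb + s.nb + i] = s.by[i];
    }
    for (int i = 0; i < 4 * s.nm; ++i) {
      snaps_mot[(R_xlen_t)ks * 8 * s.nm + i] = s.mx[i];
      snaps_mot[(R_xlen_t)ks * 8 * s.nm + 4 * s.nm + i] = s.my[i];
    }
    for (int g = 0; g < s.nseg; ++g) snap_tension(g, ks) = tension[g];
    for (int a = 0; a < s.narm; ++a) snap_bound(a, ks) = s.arm_bound[a];
    snap_steps[ks] = step;
    ++ks;
  };

  double noise_amp_b = p.noise_kbt > 0 ? std::sqrt(2.0 * p.noise_kbt * p.dt / p.gamma_bead) : 0.0;
  double noise_amp_m = p.noise_kbt > 0 ? std::sqrt(2.0 * p.noise_kbt * p.dt / p.gamma_mot) : 0.0;

  for (int k = 0; k < n_steps; ++k) {
    if (snap_every > 0 && k % snap_every == 0 && ks < nsnap) record(k);
    if (p.rebuild_every > 0 && k % p.rebuild_every == 0 && k > 0) cl.build(s, p.capture);
    compute_forces(s, p, nullptr);
    double max2 = 0;
    for (int i = 0; i < s.nb; ++i) {
      if (s.anchored[i]) continue;
      double dx = p.dt * s.fbx[i] / p.gamma_bead;
      double dy = p.dt * s.fby[i] / p.gamma_bead;
      if (noise_amp_b > 0) { dx += noise_amp_b * norm_rand(); dy += noise_amp_b * norm_rand(); }
      double m2 = dx * dx + dy * dy;
      if (m2 > max2) max2 = m2;
      s.bx[i] += dx; s.by[i] += dy;
    }
    for (int i = 0; i < 4 * s.nm; ++i) {
      double dx = p.dt * s.fmx[i] / p.gamma_mot;
      double dy = p.dt * s.fmy[i] / p.gamma_mot;
      if (noise_amp_m > 0) { dx += noise_amp_m * norm_rand(); dy += noise_amp_m * norm_rand(); }
      double m2 = dx * dx + dy * dy;
      if (m2 > max2) max2 = m2;
      s.mx[i] += dx; s.my[i] += dy;
    }
    if (max2 > max_move2_limit) {
      stop("step-size violation at step %d: a bead moved more than one segment length; reduce dt or stiffness", k + 1);
    }
    // binding searches run at the neighbour-list cadence (displacements per
    // interval are far below the capture radius); the on-rate is integrated
    // over the same interval so the binding statistics are unchanged
    bool try_bind = p.rebuild_every <= 1 || k % p.rebuild_every == 0;
    kinetics(s, p, cl, try_bind, p.dt * std::max(1, p.rebuild_every));
  }
  if (snap_every > 0 && ks < nsnap) record(n_steps);

  List out = pack_state(s);
  if (snap_every > 0) {
    snaps_bead.attr("dim") = IntegerVector::create(s.nb, 2, nsnap);
    snaps_mot.attr("dim") = IntegerVector::create(4 * s.nm, 2, nsnap);
    out["snap_bead"] = snaps_bead;
    out["snap_mot"] = snaps_mot;
    out["snap_tension"] = snap_tension;
    out["snap_bound"] = snap_bound;
    out["snap_steps"] = snap_steps;
  }
  return out;
}

// [[Rcpp::export]]
List abm_forces_cpp(List state, List params) {
  Params p = read_params(params);
  State s = unpack(state);
  std::vector<double> tension;
  compute_forces(s, p, &tension);
  NumericMatrix fb(s.nb, 2), fm(4 * s.nm, 2);
  for (int i = 0; i < s.nb; ++i) { fb(i, 0) = s.fbx[i]; fb(i, 1) = s.fby[i]; }
  for (int i = 0; i < 4 * s.nm; ++i) { fm(i, 0) = s.fmx[i]; fm(i, 1) = s.fmy[i]; }
  return List::create(_["f_bead"] = fb, _["f_mot"] = fm,
                      _["tension"] = NumericVector(tension.begin(), tension.end()));
}
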