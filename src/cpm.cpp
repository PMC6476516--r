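#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Cellular Potts model of a single chemotaxing cell.
//
// Grid labels: 1 = cell, 0 = medium. Energy u = alpha*L + lambda*(A-A0)^2
// with L the cell-medium boundary edge count (4-adjacency) times the
// lattice spacing and A the site count times ell^2. A copy attempt that
// would change the target site's label is accepted with probability
// exp(-(du - w)) when du - w > 0 and 1 otherwise, where w = dx . p is the
// polarization bias (dx = center-of-mass change in um).
//
// Simple connectivity of the cell (one component, no holes) is enforced by
// only accepting flips of digitally "simple" points, using the standard
// (4, 8) connectivity pair: the cell is 4-connected, the medium
// 8-connected. A single-site flip preserves the topology of both phases
// iff the flipped site is simple, which is decided from its 8-neighborhood
// via a precomputed 256-entry table.
//
// An update step consists of S = W*H attempts at uniformly random
// (site, neighbour) pairs. Only attempts whose two labels differ do
// anything, and those are exactly the attempts that pick a cell-medium
// boundary edge. Two equivalent execution modes are provided:
//   exhaustive - the literal loop over all S attempts;
//   event      - between boundary-crossing attempts the crossing
//                probability 2E/(nneigh*W*H) is constant (E changes only
//                when a flip is accepted), so the number of intervening
//                no-ops is geometric; the engine draws the gap, jumps to
//                the next effective attempt, and picks a boundary edge
//                uniformly from an incrementally maintained edge list.
// The event mode samples the same process exactly, with run time set by
// the cell's boundary length instead of the domain size.

namespace {

const double NM_TO_MOLEC_PER_UM3 = 0.60221409; // 1 nM in molecules/um^3

// 8-neighborhood offsets, bit order used for the simple-point table
const int NB8X[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
const int NB8Y[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
// indices within NB8 that are 4-neighbors of the center
const bool NB8_IS4[8] = {false, true, false, true, true, false, true, false};

inline bool ring_adj(int i, int j, bool eight) {
  int dx = NB8X[i] - NB8X[j], dy = NB8Y[i] - NB8Y[j];
  int ax = dx < 0 ? -dx : dx, ay = dy < 0 ? -dy : dy;
  if (eight) return (ax <= 1 && ay <= 1);
  return (ax + ay == 1);
}

// connected components of the marked ring sites; optionally only those
// containing a 4-neighbor of the center
int ring_components(const bool in[8], bool eight, bool touch4) {
  int comp[8];
  for (int i = 0; i < 8; ++i) comp[i] = in[i] ? i : -1;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int i = 0; i < 8; ++i) {
      if (comp[i] < 0) continue;
      for (int j = 0; j < 8; ++j) {
        if (comp[j] < 0 || !ring_adj(i, j, eight)) continue;
        int m = comp[i] < comp[j] ? comp[i] : comp[j];
        if (comp[i] != m || comp[j] != m) {
          comp[i] = comp[j] = m;
          changed = true;
        }
      }
    }
  }
  int count = 0;
  for (int i = 0; i < 8; ++i) {
    if (comp[i] == i) {
      if (touch4) {
        bool ok = false;
        for (int j = 0; j < 8; ++j)
          if (comp[j] == i && NB8_IS4[j]) ok = true;
        if (!ok) continue;
      }
      ++count;
    }
  }
  return count;
}

struct SimpleTable {
  unsigned char t[256];
  SimpleTable() {
    for (int cfg = 0; cfg < 256; ++cfg) {
      bool cell[8], med[8];
      for (int i = 0; i < 8; ++i) {
        cell[i] = (cfg >> i) & 1;
        med[i] = !cell[i];
      }
      int t4 = ring_components(cell, false, true); // cell: 4-connectivity
      int t8 = ring_components(med, true, false);  // medium: 8-connectivity
      t[cfg] = (t4 == 1 && t8 == 1) ? 1 : 0;
    }
  }
};
const SimpleTable SIMPLE;

// attempt-adjacency offsets; first 4 are the von Neumann neighbours
const int DXA[8] = {1, -1, 0, 0, 1, 1, -1, -1};
const int DYA[8] = {0, 0, 1, -1, 1, -1, 1, -1};
// canonical positive directions for edge ids: (1,0),(0,1),(1,1),(1,-1)
const int PDX[4] = {1, 0, 1, 1};
const int PDY[4] = {0, 1, 1, -1};

struct Engine {
  int W, H;
  std::vector<int> label;        // W*H, row index = x, col = y
  std::vector<int> sites;        // linear indices of cell sites
  std::vector<int> site_pos;     // W*H, index into `sites` or -1
  double sumx, sumy;             // sums of site x/y indices
  double ell, alpha, lambda, A0, conc, grad, Nrec, eps, eta, r, tau;
  int margin, nneigh, npos;
  bool event_mode;
  double px, py;                 // polarization vector
  double cx, cy;                 // domain-center index
  std::vector<double> ni;        // scratch: per-site detected counts
  std::vector<int> elist;        // boundary-edge ids (event mode)
  std::vector<int> epos;         // edge id -> index in elist, or -1

  int idx(int x, int y) const { return y * W + x; }

  double com_x() const { return (sumx / sites.size() - cx) * ell; }
  double com_y() const { return (sumy / sites.size() - cy) * ell; }

  void add_site(int id) {
    site_pos[id] = sites.size();
    sites.push_back(id);
    label[id] = 1;
    sumx += id % W;
    sumy += id / W;
  }

  void remove_site(int id) {
    int k = site_pos[id];
    int last = sites.back();
    sites[k] = last;
    site_pos[last] = k;
    sites.pop_back();
    site_pos[id] = -1;
    label[id] = 0;
    sumx -= id % W;
    sumy -= id / W;
  }

  // ---- boundary-edge list (event mode) -------------------------------
  // edge between site a=(x,y) and its positive-direction neighbour d
  int edge_id(int x, int y, int d) const { return (idx(x, y)) * npos + d; }

  bool edge_crossing(int x, int y, int d) const {
    int nx = x + PDX[d], ny = y + PDY[d];
    if (nx < 0 || nx >= W || ny < 0 || ny >= H) return false;
    return label[idx(x, y)] != label[idx(nx, ny)];
  }

  void edge_update(int x, int y, int d) {
    int id = edge_id(x, y, d);
    bool crossing = edge_crossing(x, y, d);
    int pos = epos[id];
    if (crossing && pos < 0) {
      epos[id] = elist.size();
      elist.push_back(id);
    } else if (!crossing && pos >= 0) {
      int last = elist.back();
      elist[pos] = last;
      epos[last] = pos;
      elist.pop_back();
      epos[id] = -1;
    }
  }

  void init_edges() {
    elist.clear();
    epos.assign((size_t)W * H * npos, -1);
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x)
        for (int d = 0; d < npos; ++d)
          edge_update(x, y, d);
  }

  // --------------------------------------------------------------------

  unsigned neighborhood_cfg(int x, int y) const {
    unsigned cfg = 0;
    for (int i = 0; i < 8; ++i) {
      int nx = x + NB8X[i], ny = y + NB8Y[i];
      if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue; // off-grid=medium
      if (label[idx(nx, ny)]) cfg |= (1u << i);
    }
    return cfg;
  }

  int cell_4neighbors(int x, int y) const {
    int k = 0;
    for (int d = 0; d < 4; ++d) {
      int nx = x + DXA[d], ny = y + DYA[d];
      if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
      k += label[idx(nx, ny)];
    }
    return k;
  }

  // process an attempt that proposes copying label ls onto target (tx, ty);
  // returns true if the flip was accepted
  bool effective_attempt(int tx, int ty, int ls) {
    int t = idx(tx, ty), lt = label[t];
    if (ls == lt) return false;
    if (ls == 1 &&
        (tx < margin || tx >= W - margin || ty < margin || ty >= H - margin))
      stop("domain too small: cell reached the boundary margin");
    if (!SIMPLE.t[neighborhood_cfg(tx, ty)]) return false;
    int n = sites.size();
    if (lt == 1 && n <= 1) return false;
    int k4 = cell_4neighbors(tx, ty);
    int dE = (lt == 0) ? (4 - 2 * k4) : (2 * k4 - 4);
    int dA = (lt == 0) ? 1 : -1;
    double ell2 = ell * ell;
    double A = n * ell2;
    double du = alpha * dE * ell +
      lambda * ((A + dA * ell2 - A0) * (A + dA * ell2 - A0) -
                (A - A0) * (A - A0));
    double sx_um = (tx - cx) * ell, sy_um = (ty - cy) * ell;
    double comx = com_x(), comy = com_y();
    double dcx, dcy;
    if (lt == 0) {
      dcx = (sx_um - comx) / (n + 1);
      dcy = (sy_um - comy) / (n + 1);
    } else {
      dcx = (comx - sx_um) / (n - 1);
      dcy = (comy - sy_um) / (n - 1);
    }
    double w = dcx * px + dcy * py;
    double dd = du - w;
    if (dd > 0 && unif_rand() >= std::exp(-dd)) return false;
    if (lt == 0) add_site(t); else remove_site(t);
    return true;
  }

  // literal attempt: uniform site, uniform neighbour
  void attempt_exhaustive() {
    int s = (int)(unif_rand() * (W * H));
    if (s >= W * H) s = W * H - 1;
    int d = (int)(unif_rand() * nneigh);
    if (d >= nneigh) d = nneigh - 1;
    int sx = s % W, sy = s / W;
    int tx = sx + DXA[d], ty = sy + DYA[d];
    if (tx < 0 || tx >= W || ty < 0 || ty >= H) return;
    effective_attempt(tx, ty, label[s]);
  }

  // S attempts, jumping over the no-ops with geometric gaps
  void attempts_event(long S) {
    long remaining = S;
    while (remaining > 0) {
      double q = 2.0 * elist.size() / ((double)nneigh * W * H);
      double gap = R::rgeom(q); // no-ops before the next crossing attempt
      if (gap + 1 > remaining) break;
      remaining -= (long)gap + 1;
      int e = (int)(unif_rand() * elist.size());
      if (e >= (int)elist.size()) e = elist.size() - 1;
      int id = elist[e];
      int d = id % npos;
      int a = id / npos;
      int ax = a % W, ay = a / W;
      int bx = ax + PDX[d], by = ay + PDY[d];
      // direction: which endpoint is the copy source
      bool a_is_source = unif_rand() < 0.5;
      int sx = a_is_source ? ax : bx, sy = a_is_source ? ay : by;
      int tx = a_is_source ? bx : ax, ty = a_is_source ? by : ay;
      if (effective_attempt(tx, ty, label[idx(sx, sy)])) {
        // refresh edges around the flipped target
        for (int k = 0; k < npos; ++k) {
          edge_update(tx, ty, k);
          int ux = tx - PDX[k], uy = ty - PDY[k];
          if (ux >= 0 && ux < W && uy >= 0 && uy < H) edge_update(ux, uy, k);
        }
      }
    }
  }

  // Poisson receptor/ligand sampling; returns sensing vector q
  void sense(double &qx, double &qy) {
    int n = sites.size();
    ni.resize(n);
    double comx = com_x(), comy = com_y();
    double mean_rec = Nrec / n;
    double nbar = 0.0;
    for (int k = 0; k < n; ++k) {
      int id = sites[k];
      double x_um = (id % W - cx) * ell;
      double mu = (conc + grad * x_um / 1000.0) * NM_TO_MOLEC_PER_UM3 *
                  ell * ell * ell;
      if (mu < 0) mu = 0;
      double rec = R::rpois(mean_rec);
      double lig = R::rpois(mu);
      ni[k] = rec < lig ? rec : lig;
      nbar += ni[k];
    }
    nbar /= n;
    qx = qy = 0.0;
    for (int k = 0; k < n; ++k) {
      int id = sites[k];
      double rx = (id % W - cx) * ell - comx;
      double ry = (id / W - cy) * ell - comy;
      double nr = std::sqrt(rx * rx + ry * ry);
      if (nr == 0) continue; // site at the center of mass contributes 0
      qx += (ni[k] - nbar) * rx / nr;
      qy += (ni[k] - nbar) * ry / nr;
    }
    qx /= n;
    qy /= n;
  }

  // one update step: S = W*H attempts, then sensing + polarization update
  void step() {
    double com0x = com_x(), com0y = com_y();
    long S = (long)W * H;
    if (event_mode) {
      attempts_event(S);
    } else {
      for (long a = 0; a < S; ++a) attempt_exhaustive();
    }
    double dxs = com_x() - com0x, dys = com_y() - com0y;
    double qx = 0.0, qy = 0.0;
    if (eps != 0.0) sense(qx, qy);
    double nrm = std::sqrt(dxs * dxs + dys * dys);
    double ux = 0.0, uy = 0.0;
    if (nrm > 0) { ux = dxs / nrm; uy = dys / nrm; } // else skip eta term
    px += r * tau * (-px + eta * ux + eps * qx);
    py += r * tau * (-py + eta * uy + eps * qy);
  }
};

Engine make_engine(const IntegerMatrix &grid, double p_x, double p_y,
                   double ell, double alpha, double lambda, double A0,
                   double conc, double grad, double Nrec, double eps,
                   double eta, double r, double tau, int margin,
                   int neighborhood, bool event_mode) {
  Engine e;
  e.W = grid.nrow();
  e.H = grid.ncol();
  e.label.assign(e.W * e.H, 0);
  e.site_pos.assign(e.W * e.H, -1);
  e.sumx = e.sumy = 0.0;
  for (int y = 0; y < e.H; ++y)
    for (int x = 0; x < e.W; ++x)
      if (grid(x, y)) {
        int id = y * e.W + x;
        e.site_pos[id] = e.sites.size();
        e.sites.push_back(id);
        e.label[id] = 1;
        e.sumx += x;
        e.sumy += y;
      }
  if (e.sites.empty()) stop("cell is empty");
  e.ell = ell; e.alpha = alpha; e.lambda = lambda; e.A0 = A0;
  e.conc = conc; e.grad = grad; e.Nrec = Nrec; e.eps = eps; e.eta = eta;
  e.r = r; e.tau = tau; e.margin = margin;
  e.nneigh = (neighborhood == 8) ? 8 : 4;
  e.npos = e.nneigh / 2;
  e.event_mode = event_mode;
  e.px = p_x; e.py = p_y;
  e.cx = (e.W - 1) / 2.0;
  e.cy = (e.H - 1) / 2.0;
  if (event_mode) e.init_edges();
  return e;
}

} // namespace

// [[Rcpp::export]]
List cpm_run_cpp(IntegerMatrix grid, NumericVector p_vec, int n_steps,
                 int record_every, double ell, double alpha, double lambda,
                 double A0, double conc, double grad, double Nrec,
                 double eps, double eta, double r, double tau, int margin,
                 int neighborhood, bool event_mode) {
  Engine e = make_engine(grid, p_vec[0], p_vec[1], ell, alpha, lambda, A0,
                         conc, grad, Nrec, eps, eta, r, tau, margin,
                         neighborhood, event_mode);
  int n_rec = (record_every > 0) ? n_steps / record_every : 0;
  NumericMatrix path(n_rec + 1, 2);
  path(0, 0) = e.com_x();
  path(0, 1) = e.com_y();
  NumericVector areas(n_steps);
  int rec = 1;
  for (int s = 0; s < n_steps; ++s) {
    e.step();
    areas[s] = e.sites.size() * ell * ell;
    if (record_every > 0 && (s + 1) % record_every == 0) {
      path(rec, 0) = e.com_x();
      path(rec, 1) = e.com_y();
      ++rec;
    }
  }
  IntegerMatrix out_grid(e.W, e.H);
  for (int y = 0; y < e.H; ++y)
    for (int x = 0; x < e.W; ++x)
      out_grid(x, y) = e.label[y * e.W + x];
  return List::create(_["path"] = path,
                      _["grid"] = out_grid,
                      _["p_vec"] = NumericVector::create(e.px, e.py),
                      _["com_um"] = NumericVector::create(e.com_x(),
                                                          e.com_y()),
                      _["area_um2"] = areas);
}

// Repeated draws of the sensing sample for a fixed cell configuration.
// Returns the sensing vectors (n_draws x 2) plus the per-site detected
// counts of the last draw and the site unit vectors r_hat.
// [[Rcpp::export]]
List cpm_sense_cpp(IntegerMatrix grid, double ell, double conc, double grad,
                   double Nrec, int n_draws) {
  Engine e = make_engine(grid, 0, 0, ell, 0, 0, 0, conc, grad, Nrec, 1, 0,
                         0, 0, 0, 4, false);
  NumericMatrix q(n_draws, 2);
  for (int i = 0; i < n_draws; ++i) {
    double qx, qy;
    e.sense(qx, qy);
    q(i, 0) = qx;
    q(i, 1) = qy;
  }
  int n = e.sites.size();
  NumericVector counts(n);
  NumericMatrix rhat(n, 2), site_um(n, 2);
  double comx = e.com_x(), comy = e.com_y(), nbar = 0.0;
  for (int k = 0; k < n; ++k) {
    counts[k] = e.ni[k];
    nbar += e.ni[k];
    int id = e.sites[k];
    double rx = (id % e.W - e.cx) * ell - comx;
    double ry = (id / e.W - e.cy) * ell - comy;
    site_um(k, 0) = (id % e.W - e.cx) * ell;
    site_um(k, 1) = (id / e.W - e.cy) * ell;
    double nr = std::sqrt(rx * rx + ry * ry);
    rhat(k, 0) = nr > 0 ? rx / nr : 0.0;
    rhat(k, 1) = nr > 0 ? ry / nr : 0.0;
  }
  return List::create(_["q"] = q, _["n_i"] = counts, _["n_bar"] = nbar / n,
                      _["r_hat"] = rhat, _["site_um"] = site_um);
}
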