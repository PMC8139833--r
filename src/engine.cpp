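// Compiled core: forcefield evaluation (cell-list and all-pairs paths),
// dynamic LAD-lamin bond updates, and the overdamped Langevin integrator.
// All quantities are in reduced units (sigma = k_BT = tau = 1 unless the
// caller says otherwise).  Chromatin bead types: 0 = non-LAD, 1 = LAD.
// Bond state: per-bead 0-based lamin index, or -1 for unbonded.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Par {
  double sigma;
  double eps_nn, eps_nl, eps_ll;  // chromatin pair LJ strength by type pair
  double chrom_cutoff;            // in absolute length units
  double ks, rest, kb;
  double Rc;                      // confinement radius; <= 0 means unconfined
  double eps_wall;
  double eps_lm, eps_ln;          // lamin LJ strength for LAD / non-LAD beads
  double cut_lm;                  // lamin LJ cutoff for LAD beads
  double kbond, ubond, rbond;
  double dt, gamma, kT;
  double trap_k;                  // external harmonic trap k*r^2 (diagnostics)
  int    noise;                   // 0 none, 1 gaussian, 2 uniform [-1,1]
  double max_disp;                // >0: cap per-step displacement (push-off)
  int    bond_every;
  bool   use_cells;
  double wca;                     // 2^(1/6) sigma
};

Par parse_par(const List& par) {
  Par p;
  p.sigma        = as<double>(par["sigma"]);
  NumericMatrix em = as<NumericMatrix>(par["eps_matrix"]);
  p.eps_nn = em(0, 0); p.eps_nl = em(0, 1); p.eps_ll = em(1, 1);
  p.chrom_cutoff = as<double>(par["chrom_cutoff"]);
  p.ks   = as<double>(par["ks"]);
  p.rest = as<double>(par["rest"]);
  p.kb   = as<double>(par["kb"]);
  p.Rc   = as<double>(par["Rc"]);
  p.eps_wall = as<double>(par["eps_wall"]);
  p.eps_lm = as<double>(par["eps_lm"]);
  p.eps_ln = as<double>(par["eps_ln"]);
  p.cut_lm = as<double>(par["cut_lm"]);
  p.kbond = as<double>(par["kbond"]);
  p.ubond = as<double>(par["ubond"]);
  p.rbond = as<double>(par["rbond"]);
  p.dt    = as<double>(par["dt"]);
  p.gamma = as<double>(par["gamma"]);
  p.kT    = as<double>(par["kT"]);
  p.trap_k = as<double>(par["trap_k"]);
  p.noise  = as<int>(par["noise"]);
  p.max_disp = as<double>(par["max_disp"]);
  p.bond_every = as<int>(par["bond_every"]);
  p.use_cells  = as<bool>(par["use_cells"]);
  p.wca = std::pow(2.0, 1.0 / 6.0) * p.sigma;
  return p;
}

// truncated-and-shifted LJ energy; force is the unshifted derivative
inline double lj_shift(double eps, double sigma, double cutoff) {
  double s6 = std::pow(sigma / cutoff, 6.0);
  return 4.0 * eps * (s6 * s6 - s6);
}

// adds LJ pair energy/scalar force factor; returns energy, sets fr such that
// the force on i is fr * (xi - xj)
inline double lj_pair_ef(double r2, double eps, double sigma, double shift,
                         double* fr) {
  double sr2 = sigma * sigma / r2;
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  *fr = 24.0 * eps * (2.0 * sr12 - sr6) / r2;
  return 4.0 * eps * (sr12 - sr6) - shift;
}

struct CellList {
  double lo[3];
  double cs[3];
  int nc[3];
  std::vector<int> head, nxt;

  void build(const std::vector<double>& x, int n, double cutoff) {
    double hi[3];
    for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double v = x[3 * i + d];
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    for (int d = 0; d < 3; ++d) {
      double span = std::max(hi[d] - lo[d], 1e-9);
      nc[d] = std::max(1, (int)std::floor(span / cutoff));
      // hard cap to bound memory for pathological spreads
      if (nc[d] > 512) nc[d] = 512;
      cs[d] = span / nc[d] * (1.0 + 1e-12);
    }
    head.assign((size_t)nc[0] * nc[1] * nc[2], -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(&x[3 * i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  inline int idx3(int ix, int iy, int iz) const {
    return (ix * nc[1] + iy) * nc[2] + iz;
  }

  inline int cell_of(const double* p) const {
    int ix = std::min(nc[0] - 1, std::max(0, (int)((p[0] - lo[0]) / cs[0])));
    int iy = std::min(nc[1] - 1, std::max(0, (int)((p[1] - lo[1]) / cs[1])));
    int iz = std::min(nc[2] - 1, std::max(0, (int)((p[2] - lo[2]) / cs[2])));
    return idx3(ix, iy, iz);
  }

  inline void cell_coords(const double* p, int* ic) const {
    ic[0] = std::min(nc[0] - 1, std::max(0, (int)((p[0] - lo[0]) / cs[0])));
    ic[1] = std::min(nc[1] - 1, std::max(0, (int)((p[1] - lo[1]) / cs[1])));
    ic[2] = std::min(nc[2] - 1, std::max(0, (int)((p[2] - lo[2]) / cs[2])));
  }
};

// energy term indices
enum { E_STRETCH = 0, E_BEND, E_CHROM, E_WALL, E_LAMIN, E_BOND, E_TRAP, NTERM };

class System {
public:
  int n;                       // chromatin beads
  int m;                       // lamin beads
  std::vector<double> x;       // 3n chromatin positions
  std::vector<double> lam;     // 3m lamin positions
  std::vector<int> type;       // 0 non-LAD, 1 LAD
  std::vector<int> bondable;   // 0/1
  std::vector<int> bond;       // lamin index or -1
  Par p;
  CellList ccl, lcl;
  double lam_cut;              // query radius for lamin neighbours
  bool lam_cl_built = false;

  // pair LJ tables indexed by type_i + type_j (0,1,2)
  double peps[3], pshift[3], pcut2;

  void init_tables() {
    peps[0] = p.eps_nn; peps[1] = p.eps_nl; peps[2] = p.eps_ll;
    for (int k = 0; k < 3; ++k)
      pshift[k] = lj_shift(peps[k], p.sigma, p.chrom_cutoff);
    pcut2 = p.chrom_cutoff * p.chrom_cutoff;
    lam_cut = std::max(std::max(p.cut_lm, p.rbond), p.wca);
  }

  void build_lamin_cl() {
    if (m > 0) { lcl.build(lam, m, lam_cut); lam_cl_built = true; }
  }

  inline double dist2(int i, const double* q) const {
    double dx = x[3 * i] - q[0], dy = x[3 * i + 1] - q[1],
           dz = x[3 * i + 2] - q[2];
    return dx * dx + dy * dy + dz * dz;
  }

  // ---- force/energy evaluation -------------------------------------------
  template <bool withE>
  void compute(std::vector<double>& f, double* e) {
    std::fill(f.begin(), f.end(), 0.0);
    if (withE) std::fill(e, e + NTERM, 0.0);

    bonded_terms<withE>(f, e);
    chrom_pairs<withE>(f, e);
    if (p.Rc > 0.0) wall_term<withE>(f, e);
    if (p.Rc > 0.0 && m > 0) lamin_terms<withE>(f, e);
    if (p.trap_k > 0.0) trap_term<withE>(f, e);
  }

  template <bool withE>
  void bonded_terms(std::vector<double>& f, double* e) {
    // stretching springs
    for (int i = 0; i + 1 < n; ++i) {
      double d[3], r2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        d[k] = x[3 * (i + 1) + k] - x[3 * i + k];
        r2 += d[k] * d[k];
      }
      double r = std::sqrt(r2);
      if (r < 1e-12) stop("singular-angle: coincident consecutive beads");
      double dev = r - p.rest;
      if (withE) e[E_STRETCH] += p.ks * dev * dev;
      double fr = 2.0 * p.ks * dev / r;   // force on i along +d
      for (int k = 0; k < 3; ++k) {
        f[3 * i + k]       += fr * d[k];
        f[3 * (i + 1) + k] -= fr * d[k];
      }
    }
    // bending
    if (p.kb != 0.0) {
      for (int i = 1; i + 1 < n; ++i) {
        double b1[3], b2[3], l1 = 0.0, l2 = 0.0, dot = 0.0;
        for (int k = 0; k < 3; ++k) {
          b1[k] = x[3 * i + k] - x[3 * (i - 1) + k];
          b2[k] = x[3 * (i + 1) + k] - x[3 * i + k];
          l1 += b1[k] * b1[k];
          l2 += b2[k] * b2[k];
          dot += b1[k] * b2[k];
        }
        l1 = std::sqrt(l1); l2 = std::sqrt(l2);
        if (l1 < 1e-12 || l2 < 1e-12)
          stop("singular-angle: coincident consecutive beads");
        double c = dot / (l1 * l2);
        if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
        if (withE) e[E_BEND] += p.kb * (1.0 - c);
        // F_{i-1} = -kb (u2 - c u1)/l1 ; F_{i+1} = kb (u1 - c u2)/l2
        for (int k = 0; k < 3; ++k) {
          double u1 = b1[k] / l1, u2 = b2[k] / l2;
          double fm = -p.kb * (u2 - c * u1) / l1;
          double fp =  p.kb * (u1 - c * u2) / l2;
          f[3 * (i - 1) + k] += fm;
          f[3 * (i + 1) + k] += fp;
          f[3 * i + k]       -= fm + fp;
        }
      }
    }
  }

  template <bool withE>
  inline void chrom_pair_one(int i, int j, std::vector<double>& f, double* e) {
    double d[3], r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      d[k] = x[3 * i + k] - x[3 * j + k];
      r2 += d[k] * d[k];
    }
    if (r2 >= pcut2) return;
    if (r2 < 1e-24) stop("singular-overlap: beads at zero distance");
    int t = type[i] + type[j];
    if (peps[t] == 0.0) return;
    double fr;
    double en = lj_pair_ef(r2, peps[t], p.sigma, pshift[t], &fr);
    if (withE) e[E_CHROM] += en;
    for (int k = 0; k < 3; ++k) {
      f[3 * i + k] += fr * d[k];
      f[3 * j + k] -= fr * d[k];
    }
  }

  template <bool withE>
  void chrom_pairs(std::vector<double>& f, double* e) {
    if (!p.use_cells) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          chrom_pair_one<withE>(i, j, f, e);
      return;
    }
    ccl.build(x, n, p.chrom_cutoff);
    int ic[3];
    for (int i = 0; i < n; ++i) {
      ccl.cell_coords(&x[3 * i], ic);
      for (int ax = std::max(0, ic[0] - 1); ax <= std::min(ccl.nc[0] - 1, ic[0] + 1); ++ax)
        for (int ay = std::max(0, ic[1] - 1); ay <= std::min(ccl.nc[1] - 1, ic[1] + 1); ++ay)
          for (int az = std::max(0, ic[2] - 1); az <= std::min(ccl.nc[2] - 1, ic[2] + 1); ++az)
            for (int j = ccl.head[ccl.idx3(ax, ay, az)]; j >= 0; j = ccl.nxt[j])
              if (j > i) chrom_pair_one<withE>(i, j, f, e);
    }
  }

  template <bool withE>
  void wall_term(std::vector<double>& f, double* e) {
    double wshift = p.eps_wall;  // shifted so E = 0 at the 2^(1/6) cutoff
    for (int i = 0; i < n; ++i) {
      double r2 = 0.0;
      for (int k = 0; k < 3; ++k) r2 += x[3 * i + k] * x[3 * i + k];
      double r = std::sqrt(r2);
      double gap = p.Rc - r;
      if (gap <= 0.0) stop("escaped-bead: bead outside the confinement sphere");
      if (gap >= p.wca) continue;
      double fr;  // here fr*(gap vector) convention unused; use scalar form
      double en = lj_pair_ef(gap * gap, p.eps_wall, p.sigma, -wshift, &fr);
      if (withE) e[E_WALL] += en;
      // dE/dgap = -fr*gap ; F = (dE/dgap) * rhat  (inward for repulsion)
      double fs = -fr * gap / std::max(r, 1e-12);
      for (int k = 0; k < 3; ++k) f[3 * i + k] += fs * x[3 * i + k];
    }
  }

  template <bool withE>
  void lamin_terms(std::vector<double>& f, double* e) {
    double shift_lm = lj_shift(p.eps_lm, p.sigma, p.cut_lm);
    double shift_ln = lj_shift(p.eps_ln, p.sigma, p.wca);
    double cut2_lm = p.cut_lm * p.cut_lm, cut2_ln = p.wca * p.wca;
    double inner = p.Rc - lam_cut;  // beads closer in see no lamin bead
    for (int i = 0; i < n; ++i) {
      double r2c = 0.0;
      for (int k = 0; k < 3; ++k) r2c += x[3 * i + k] * x[3 * i + k];
      if (r2c < inner * inner && inner > 0.0) continue;
      bool lad = type[i] == 1;
      double eps = lad ? p.eps_lm : p.eps_ln;
      double cut2 = lad ? cut2_lm : cut2_ln;
      double shift = lad ? shift_lm : shift_ln;
      if (eps != 0.0) {
        if (p.use_cells && lam_cl_built) {
          int ic[3];
          lcl.cell_coords(&x[3 * i], ic);
          for (int ax = std::max(0, ic[0] - 1); ax <= std::min(lcl.nc[0] - 1, ic[0] + 1); ++ax)
            for (int ay = std::max(0, ic[1] - 1); ay <= std::min(lcl.nc[1] - 1, ic[1] + 1); ++ay)
              for (int az = std::max(0, ic[2] - 1); az <= std::min(lcl.nc[2] - 1, ic[2] + 1); ++az)
                for (int j = lcl.head[lcl.idx3(ax, ay, az)]; j >= 0; j = lcl.nxt[j])
                  lamin_lj_one<withE>(i, j, eps, cut2, shift, f, e);
        } else {
          for (int j = 0; j < m; ++j)
            lamin_lj_one<withE>(i, j, eps, cut2, shift, f, e);
        }
      }
    }
    // bond springs (independent of distance; active wherever the bead is)
    for (int i = 0; i < n; ++i) {
      int b = bond[i];
      if (b < 0) continue;
      double d[3], r2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        d[k] = x[3 * i + k] - lam[3 * b + k];
        r2 += d[k] * d[k];
      }
      double r = std::sqrt(r2);
      double dev = r - p.sigma;
      if (withE)
        e[E_BOND] += p.kbond * dev * dev
                   - p.kbond * (p.rbond - p.sigma) * (p.rbond - p.sigma);
      double fr = -2.0 * p.kbond * dev / std::max(r, 1e-12);
      for (int k = 0; k < 3; ++k) f[3 * i + k] += fr * d[k];
    }
  }

  template <bool withE>
  inline void lamin_lj_one(int i, int j, double eps, double cut2, double shift,
                           std::vector<double>& f, double* e) {
    double d[3], r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      d[k] = x[3 * i + k] - lam[3 * j + k];
      r2 += d[k] * d[k];
    }
    if (r2 >= cut2) return;
    if (r2 < 1e-24) stop("singular-overlap: bead on top of a lamin bead");
    double fr;
    double en = lj_pair_ef(r2, eps, p.sigma, shift, &fr);
    if (withE) e[E_LAMIN] += en;
    for (int k = 0; k < 3; ++k) f[3 * i + k] += fr * d[k];
  }

  template <bool withE>
  void trap_term(std::vector<double>& f, double* e) {
    for (int i = 0; i < n; ++i) {
      double r2 = 0.0;
      for (int k = 0; k < 3; ++k) r2 += x[3 * i + k] * x[3 * i + k];
      if (withE) e[E_TRAP] += p.trap_k * r2;
      for (int k = 0; k < 3; ++k) f[3 * i + k] -= 2.0 * p.trap_k * x[3 * i + k];
    }
  }

  // ---- dynamic bonds ------------------------------------------------------
  // breaking pass: a bond stretched beyond rbond breaks with P = exp(-U/kT);
  // formation pass: every unbonded, bondable LAD bead binds its nearest lamin
  // bead within rbond (ties -> lowest lamin index).
  void update_bonds(long* trials, long* breaks, long* forms) {
    if (m == 0) return;
    double pbreak = std::exp(-p.ubond / p.kT);
    double rb2 = p.rbond * p.rbond;
    for (int i = 0; i < n; ++i) {
      int b = bond[i];
      if (b < 0) continue;
      if (dist2(i, &lam[3 * b]) > rb2) {
        if (trials) ++(*trials);
        if (unif_rand() < pbreak) {
          bond[i] = -1;
          if (breaks) ++(*breaks);
        }
      }
    }
    double inner = p.Rc - p.rbond;
    for (int i = 0; i < n; ++i) {
      if (bond[i] >= 0 || !bondable[i]) continue;
      double r2c = 0.0;
      for (int k = 0; k < 3; ++k) r2c += x[3 * i + k] * x[3 * i + k];
      if (inner > 0.0 && r2c < inner * inner) continue;
      double best = rb2;
      int bestj = -1;
      if (p.use_cells && lam_cl_built) {
        int ic[3];
        lcl.cell_coords(&x[3 * i], ic);
        for (int ax = std::max(0, ic[0] - 1); ax <= std::min(lcl.nc[0] - 1, ic[0] + 1); ++ax)
          for (int ay = std::max(0, ic[1] - 1); ay <= std::min(lcl.nc[1] - 1, ic[1] + 1); ++ay)
            for (int az = std::max(0, ic[2] - 1); az <= std::min(lcl.nc[2] - 1, ic[2] + 1); ++az)
              for (int j = lcl.head[lcl.idx3(ax, ay, az)]; j >= 0; j = lcl.nxt[j]) {
                double d2 = dist2(i, &lam[3 * j]);
                if (d2 < best || (d2 == best && bestj >= 0 && j < bestj)) {
                  best = d2; bestj = j;
                }
              }
      } else {
        for (int j = 0; j < m; ++j) {
          double d2 = dist2(i, &lam[3 * j]);
          if (d2 < best || (d2 == best && bestj >= 0 && j < bestj)) {
            best = d2; bestj = j;
          }
        }
      }
      if (bestj >= 0) {
        bond[i] = bestj;
        if (forms) ++(*forms);
      }
    }
  }

  // ---- integrator ---------------------------------------------------------
  // r(t+dt) = r(t) - dt/gamma * grad E + sqrt(6 kT dt/gamma) xi, with xi
  // either uniform [-1,1] (the literal prefactor) or gaussian with matching
  // variance 2 kT dt/gamma (the default).
  long n_capped = 0;  // displacement-limiter activations

  void step_once(std::vector<double>& f, int step_no) {
    double mob = p.dt / p.gamma;
    double sd_g = std::sqrt(2.0 * p.kT * p.dt / p.gamma);
    double amp_u = std::sqrt(6.0 * p.kT * p.dt / p.gamma);
    double lim2 = 0.25 * p.sigma * p.sigma;
    for (int i = 0; i < n; ++i) {
      double dx[3];
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double nz = 0.0;
        if (p.noise == 1) nz = norm_rand() * sd_g;
        else if (p.noise == 2) nz = (2.0 * unif_rand() - 1.0) * amp_u;
        dx[k] = mob * f[3 * i + k] + nz;
        d2 += dx[k] * dx[k];
      }
      if (p.max_disp > 0.0) {
        if (d2 > p.max_disp * p.max_disp) {
          double sc = p.max_disp / std::sqrt(d2);
          for (int k = 0; k < 3; ++k) dx[k] *= sc;
          ++n_capped;
        }
      } else if (d2 > lim2) {
        double fmag = std::sqrt(f[3 * i] * f[3 * i] +
                                f[3 * i + 1] * f[3 * i + 1] +
                                f[3 * i + 2] * f[3 * i + 2]);
        stop("unstable-timestep: displacement > sigma/2 at step %d (bead %d, |disp| %.3g, |force| %.3g)",
             step_no, i + 1, std::sqrt(d2), fmag);
      }
      for (int k = 0; k < 3; ++k) x[3 * i + k] += dx[k];
    }
  }

  double rg2() const {
    double com[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) com[k] += x[3 * i + k];
    for (int k = 0; k < 3; ++k) com[k] /= n;
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        double d = x[3 * i + k] - com[k];
        s += d * d;
      }
    return s / n;
  }

  int bond_count() const {
    int c = 0;
    for (int i = 0; i < n; ++i) if (bond[i] >= 0) ++c;
    return c;
  }
};

System make_system(const NumericMatrix& pos, const IntegerVector& type,
                   const IntegerVector& bondable, const IntegerVector& bond,
                   const NumericMatrix& lam, const List& par) {
  System s;
  s.n = pos.nrow();
  s.m = lam.nrow();
  s.p = parse_par(par);
  s.x.resize(3 * s.n);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) s.x[3 * i + k] = pos(i, k);
  s.lam.resize(3 * s.m);
  for (int j = 0; j < s.m; ++j)
    for (int k = 0; k < 3; ++k) s.lam[3 * j + k] = lam(j, k);
  s.type = std::vector<int>(type.begin(), type.end());
  s.bondable = std::vector<int>(bondable.begin(), bondable.end());
  s.bond = std::vector<int>(bond.begin(), bond.end());
  if ((int)s.bond.size() != s.n) stop("corrupted-state: bond vector length");
  for (int i = 0; i < s.n; ++i) {
    if (s.bond[i] >= s.m) stop("corrupted-state: bond to nonexistent lamin bead");
    if (s.bond[i] >= 0 && !s.bondable[i])
      stop("corrupted-state: bond on a non-bondable bead");
  }
  s.init_tables();
  s.build_lamin_cl();
  return s;
}

NumericVector energy_vector(const double* e) {
  NumericVector out(NTERM + 1);
  double tot = 0.0;
  for (int k = 0; k < NTERM; ++k) { out[k] = e[k]; tot += e[k]; }
  out[NTERM] = tot;
  out.attr("names") = CharacterVector::create(
      "stretch", "bend", "chrom_lj", "wall", "lamin_lj", "bond", "trap",
      "total");
  return out;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_energy(NumericMatrix pos, IntegerVector type,
                         IntegerVector bondable, IntegerVector bond,
                         NumericMatrix lam, List par) {
  System s = make_system(pos, type, bondable, bond, lam, par);
  std::vector<double> f(3 * s.n);
  double e[NTERM];
  s.compute<true>(f, e);
  return energy_vector(e);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, IntegerVector type,
                         IntegerVector bondable, IntegerVector bond,
                         NumericMatrix lam, List par) {
  System s = make_system(pos, type, bondable, bond, lam, par);
  std::vector<double> f(3 * s.n);
  double e[NTERM];
  s.compute<false>(f, e);
  NumericMatrix out(s.n, 3);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = f[3 * i + k];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_update_bonds(NumericMatrix pos, IntegerVector type,
                               IntegerVector bondable, IntegerVector bond,
                               NumericMatrix lam, List par) {
  System s = make_system(pos, type, bondable, bond, lam, par);
  s.update_bonds(nullptr, nullptr, nullptr);
  return IntegerVector(s.bond.begin(), s.bond.end());
}

// Repeats the bond-update pass n_iter times on a frozen configuration,
// restoring the initial bond set before each pass; returns the number of
// break attempts (bonds found beyond rbond) and realized breaks.
// [[Rcpp::export]]
NumericVector cpp_break_trials(NumericMatrix pos, IntegerVector type,
                               IntegerVector bondable, IntegerVector bond,
                               NumericMatrix lam, List par, int n_iter) {
  System s = make_system(pos, type, bondable, bond, lam, par);
  std::vector<int> bond0 = s.bond;
  long trials = 0, breaks = 0, forms = 0;
  for (int it = 0; it < n_iter; ++it) {
    s.bond = bond0;
    s.update_bonds(&trials, &breaks, &forms);
  }
  return NumericVector::create(Named("trials") = (double)trials,
                               Named("breaks") = (double)breaks);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, IntegerVector type, IntegerVector bondable,
             IntegerVector bond, NumericMatrix lam, List par,
             int n_steps, int sample_every, bool record_frames) {
  System s = make_system(pos, type, bondable, bond, lam, par);
  std::vector<double> f(3 * s.n);
  double e[NTERM];

  int nframes = n_steps / sample_every + 1;
  List frames(record_frames ? nframes : 0);
  IntegerVector frame_steps(nframes), bond_counts(nframes);
  NumericVector rg(nframes);
  NumericMatrix energies(nframes, NTERM + 1);
  long n_break = 0, n_form = 0, n_trials = 0;

  int fi = 0;
  auto record = [&](int step_no) {
    s.compute<true>(f, e);
    double tot = 0.0;
    for (int k = 0; k < NTERM; ++k) { energies(fi, k) = e[k]; tot += e[k]; }
    energies(fi, NTERM) = tot;
    frame_steps[fi] = step_no;
    bond_counts[fi] = s.bond_count();
    rg[fi] = std::sqrt(s.rg2());
    if (record_frames) {
      NumericMatrix fr(s.n, 3);
      for (int i = 0; i < s.n; ++i)
        for (int k = 0; k < 3; ++k) fr(i, k) = s.x[3 * i + k];
      frames[fi] = fr;
    }
    ++fi;
  };

  record(0);
  for (int step = 1; step <= n_steps; ++step) {
    s.compute<false>(f, e);
    s.step_once(f, step);
    if (s.m > 0 && step % s.p.bond_every == 0)
      s.update_bonds(&n_trials, &n_break, &n_form);
    if (step % sample_every == 0) record(step);
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix final_pos(s.n, 3);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) final_pos(i, k) = s.x[3 * i + k];
  colnames(energies) = CharacterVector::create(
      "stretch", "bend", "chrom_lj", "wall", "lamin_lj", "bond", "trap",
      "total");

  return List::create(
      Named("positions") = final_pos,
      Named("bond") = IntegerVector(s.bond.begin(), s.bond.end()),
      Named("frames") = frames,
      Named("frame_steps") = frame_steps,
      Named("bond_counts") = bond_counts,
      Named("rg") = rg,
      Named("energies") = energies,
      Named("n_break") = (double)n_break,
      Named("n_form") = (double)n_form,
      Named("n_break_attempts") = (double)n_trials,
      Named("n_capped") = (double)s.n_capped);
}
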