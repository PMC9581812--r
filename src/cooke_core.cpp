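// Core numerics for the Cooke-model simulator: pair potentials, cell-list
// neighbor search, energy/force evaluation, steepest-descent minimization,
// BAOAB Langevin integration, and single-linkage clustering.
//
// Unit system throughout: length nm, energy kcal/mol, mass amu, temperature K.
// The derived internal time unit is sqrt(amu nm^2 / (kcal/mol)) = 488.8821 fs;
// all user-facing times (fs) are converted at entry.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <random>

using namespace Rcpp;

#ifdef __GNUC__
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif

static const double POW216 = 1.1224620483093730; // 2^(1/6)
static const double KB_KCAL = 0.0019872041;      // kcal/mol/K
static const double TIME_UNIT_FS = 488.8821;     // sqrt(amu nm^2/(kcal/mol)) in fs

// ---------------------------------------------------------------------------
// Force-field parameter record (mirrors the R-level ff_params() list)
// ---------------------------------------------------------------------------
struct FF {
  double sigma, eps;
  double bHH, bHT, bTT;
  double wc;          // attraction width for eligible hydrophobic pairs
  double kbond, rinf; // FENE
  double kbend, r0bend;
  double kelastic;
  double rmin_frac;   // overlap floor on pair distances, fraction of b
};

static FF ff_from_list(const List& p) {
  FF f;
  f.sigma     = as<double>(p["sigma"]);
  f.eps       = as<double>(p["epsilon"]);
  f.bHH       = as<double>(p["b_HH"]);
  f.bHT       = as<double>(p["b_HT"]);
  f.bTT       = as<double>(p["b_TT"]);
  f.wc        = as<double>(p["w_c"]);
  f.kbond     = as<double>(p["k_bond"]);
  f.rinf      = as<double>(p["r_inf"]);
  f.kbend     = as<double>(p["k_bend"]);
  f.r0bend    = as<double>(p["r_bend0"]);
  f.kelastic  = as<double>(p["k_elastic"]);
  f.rmin_frac = as<double>(p["r_min_frac"]);
  return f;
}

// bead_class: 0 = H (hydrophilic), 1 = T (hydrophobic)
// mol_kind:   0 = lipid, 1 = peptide
static inline double pair_b(const FF& ff, int ci, int cj) {
  if (ci == 1 && cj == 1) return ff.bTT;
  if (ci == 0 && cj == 0) return ff.bHH;
  return ff.bHT;
}

// w_c = sigma for hydrophobic-hydrophobic pairs involving at least one lipid
// bead; 0 otherwise (in particular peptide-peptide attraction is zero).
static inline double pair_wc(const FF& ff, int ci, int cj, int ki, int kj) {
  if (ci == 1 && cj == 1 && !(ki == 1 && kj == 1)) return ff.wc;
  return 0.0;
}

// Nonbonded pair energy and force magnitude (fmag = -dV/dr; positive repels).
// The repulsive WCA branch clamps r at rmin_frac*b as an overflow guard for
// heavily overlapped starting configurations; inside the floor the energy is
// held constant and the (repulsive) force frozen at its floor value.
static inline void pair_ef(double r, double b, double wcp, const FF& ff,
                           double& e, double& fmag) {
  e = 0.0; fmag = 0.0;
  const double rc = POW216 * b;
  double reff = r;
  const double rfloor = ff.rmin_frac * b;
  if (reff < rfloor) reff = rfloor;
  if (reff <= rc) {
    double sr2 = (b * b) / (reff * reff);
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    e += 4.0 * ff.eps * (sr12 - sr6 + 0.25);
    fmag += 4.0 * ff.eps * (12.0 * sr12 - 6.0 * sr6) / reff;
  }
  if (wcp > 0.0) {
    if (r < rc) {
      e += -ff.eps;
    } else if (r <= rc + wcp) {
      double arg = M_PI * (r - rc) / (2.0 * wcp);
      double c = std::cos(arg), s = std::sin(arg);
      e += -ff.eps * c * c;
      fmag += -ff.eps * M_PI / wcp * c * s;
    }
  }
}

static inline double min_image(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

// ---------------------------------------------------------------------------
// Neighbor search: cell-list pair enumeration within a list cutoff
// ---------------------------------------------------------------------------
static void build_pairs(const std::vector<double>& x,
                        const std::vector<double>& y,
                        const std::vector<double>& z,
                        double box, double rlist,
                        std::vector<std::pair<int,int> >& pairs,
                        bool force_brute = false) {
  const int n = (int)x.size();
  pairs.clear();
  const double rl2 = rlist * rlist;
  int nc = (int)std::floor(box / rlist);
  if (force_brute || nc < 3 || n < 32) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = min_image(x[i] - x[j], box);
        double dy = min_image(y[i] - y[j], box);
        double dz = min_image(z[i] - z[j], box);
        if (dx * dx + dy * dy + dz * dz <= rl2) pairs.push_back(std::make_pair(i, j));
      }
    return;
  }
  const double cw = box / nc;
  const int ncells = nc * nc * nc;
  std::vector<int> head(ncells, -1), nxt(n, -1);
  std::vector<int> cellof(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i] - box * std::floor(x[i] / box);
    double yi = y[i] - box * std::floor(y[i] / box);
    double zi = z[i] - box * std::floor(z[i] / box);
    int cx = std::min(nc - 1, (int)(xi / cw));
    int cy = std::min(nc - 1, (int)(yi / cw));
    int cz = std::min(nc - 1, (int)(zi / cw));
    int c = (cx * nc + cy) * nc + cz;
    cellof[i] = c;
    nxt[i] = head[c];
    head[c] = i;
  }
  // half stencil: same cell (i<j) + 13 forward neighbor cells
  static const int off[13][3] = {
    {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
    {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
  };
  for (int cx = 0; cx < nc; ++cx)
    for (int cy = 0; cy < nc; ++cy)
      for (int cz = 0; cz < nc; ++cz) {
        int c = (cx * nc + cy) * nc + cz;
        for (int i = head[c]; i >= 0; i = nxt[i])
          for (int j = nxt[i]; j >= 0; j = nxt[j]) {
            double dx = min_image(x[i] - x[j], box);
            double dy = min_image(y[i] - y[j], box);
            double dz = min_image(z[i] - z[j], box);
            if (dx * dx + dy * dy + dz * dz <= rl2)
              pairs.push_back(std::make_pair(std::min(i, j), std::max(i, j)));
          }
        for (int k = 0; k < 13; ++k) {
          int dx_ = (cx + off[k][0] + nc) % nc;
          int dy_ = (cy + off[k][1] + nc) % nc;
          int dz_ = (cz + off[k][2] + nc) % nc;
          int c2 = (dx_ * nc + dy_) * nc + dz_;
          if (c2 == c) continue;
          for (int i = head[c]; i >= 0; i = nxt[i])
            for (int j = head[c2]; j >= 0; j = nxt[j]) {
              double dx = min_image(x[i] - x[j], box);
              double dy = min_image(y[i] - y[j], box);
              double dz = min_image(z[i] - z[j], box);
              if (dx * dx + dy * dy + dz * dz <= rl2)
                pairs.push_back(std::make_pair(std::min(i, j), std::max(i, j)));
            }
        }
      }
  // With nc == 3 or 4 the wrapped stencil can visit a cell pair twice.
  if (nc < 5) {
    std::sort(pairs.begin(), pairs.end());
    pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
  }
}

// ---------------------------------------------------------------------------
// Topology arrays shared by the evaluators
// ---------------------------------------------------------------------------
struct Topo {
  std::vector<int> cls, kind;
  std::vector<int> fi, fj;               // FENE bonds
  std::vector<int> hi, hj;               // harmonic head-tail2 bonds
  std::vector<double> hr0;
  std::vector<int> ei, ej;               // elastic-network bonds
  std::vector<double> er0;
  // Nonbonded exclusions: elastic-network partners do not also interact
  // through the pair potential (their separation is pinned at the reference
  // geometry by the stiff network). FENE- and harmonically-bonded lipid
  // beads keep their pair repulsion, the usual WCA+FENE construction.
  std::vector<std::vector<int> > excl;
  bool excluded(int i, int j) const {
    const std::vector<int>& e = excl[i];
    return std::binary_search(e.begin(), e.end(), j);
  }
};

static Topo topo_from_args(IntegerVector cls, IntegerVector kind,
                           IntegerMatrix fene, IntegerMatrix harm,
                           NumericVector harm_r0, IntegerMatrix elas,
                           NumericVector elas_r0) {
  Topo t;
  int n = cls.size();
  t.cls.resize(n); t.kind.resize(n);
  for (int i = 0; i < n; ++i) { t.cls[i] = cls[i]; t.kind[i] = kind[i]; }
  for (int b = 0; b < fene.nrow(); ++b) {
    t.fi.push_back(fene(b, 0) - 1); t.fj.push_back(fene(b, 1) - 1);
  }
  for (int b = 0; b < harm.nrow(); ++b) {
    t.hi.push_back(harm(b, 0) - 1); t.hj.push_back(harm(b, 1) - 1);
    t.hr0.push_back(harm_r0[b]);
  }
  for (int b = 0; b < elas.nrow(); ++b) {
    t.ei.push_back(elas(b, 0) - 1); t.ej.push_back(elas(b, 1) - 1);
    t.er0.push_back(elas_r0[b]);
  }
  t.excl.resize(n);
  for (size_t b = 0; b < t.ei.size(); ++b) {
    t.excl[t.ei[b]].push_back(t.ej[b]);
    t.excl[t.ej[b]].push_back(t.ei[b]);
  }
  for (int i = 0; i < n; ++i) std::sort(t.excl[i].begin(), t.excl[i].end());
  return t;
}

struct EnergyParts {
  double pair, fene, bend, elastic;
  double total() const { return pair + fene + bend + elastic; }
};

// Evaluate all terms; accumulate forces. `soft` replaces the FENE divergence
// by a linear continuation beyond 0.97 r_inf (used by the minimizer, which
// must survive arbitrary overlapped input); in hard mode overextension is a
// fatal instability.
static EnergyParts eval_all(const std::vector<double>& x,
                            const std::vector<double>& y,
                            const std::vector<double>& z,
                            double box, const Topo& t, const FF& ff,
                            const std::vector<std::pair<int,int> >& pairs,
                            std::vector<double>& fx, std::vector<double>& fy,
                            std::vector<double>& fz, bool soft) {
  EnergyParts ep; ep.pair = ep.fene = ep.bend = ep.elastic = 0.0;
  const int n = (int)x.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  for (size_t p = 0; p < pairs.size(); ++p) {
    int i = pairs[p].first, j = pairs[p].second;
    if (t.excluded(i, j)) continue;
    double dx = min_image(x[i] - x[j], box);
    double dy = min_image(y[i] - y[j], box);
    double dz = min_image(z[i] - z[j], box);
    double r2 = dx * dx + dy * dy + dz * dz;
    double b = pair_b(ff, t.cls[i], t.cls[j]);
    double wcp = pair_wc(ff, t.cls[i], t.cls[j], t.kind[i], t.kind[j]);
    double rcut = POW216 * b + wcp;
    if (r2 > rcut * rcut) continue;
    double r = std::sqrt(r2);
    double e, fmag;
    pair_ef(r, b, wcp, ff, e, fmag);
    ep.pair += e;
    if (r > 1e-12) {
      double fr = fmag / r;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
  }
  const double rinf2 = ff.rinf * ff.rinf;
  const double rsoft = 0.97 * ff.rinf;
  for (size_t b = 0; b < t.fi.size(); ++b) {
    int i = t.fi[b], j = t.fj[b];
    double dx = min_image(x[i] - x[j], box);
    double dy = min_image(y[i] - y[j], box);
    double dz = min_image(z[i] - z[j], box);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double e, fmag;
    if (r >= ff.rinf && !soft) {
      stop("FENE bond %d-%d overextended: r = %.4f nm >= r_inf = %.4f nm "
           "(fatal instability)", i + 1, j + 1, r, ff.rinf);
    }
    if (soft && r > rsoft) {
      // linear continuation: V(rsoft) + V'(rsoft) (r - rsoft)
      double u = 1.0 - (rsoft * rsoft) / rinf2;
      double e0 = -0.5 * ff.kbond * rinf2 * std::log(u);
      double f0 = ff.kbond * rsoft / u; // dV/dr at rsoft
      e = e0 + f0 * (r - rsoft);
      fmag = -f0;
    } else {
      double u = 1.0 - r * r / rinf2;
      e = -0.5 * ff.kbond * rinf2 * std::log(u);
      fmag = -ff.kbond * r / u;
    }
    ep.fene += e;
    if (r > 1e-12) {
      double fr = fmag / r;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
  }
  for (size_t b = 0; b < t.hi.size(); ++b) {
    int i = t.hi[b], j = t.hj[b];
    double dx = min_image(x[i] - x[j], box);
    double dy = min_image(y[i] - y[j], box);
    double dz = min_image(z[i] - z[j], box);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - t.hr0[b];
    ep.bend += 0.5 * ff.kbend * d * d;
    if (r > 1e-12) {
      double fr = -ff.kbend * d / r;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
  }
  for (size_t b = 0; b < t.ei.size(); ++b) {
    int i = t.ei[b], j = t.ej[b];
    double dx = min_image(x[i] - x[j], box);
    double dy = min_image(y[i] - y[j], box);
    double dz = min_image(z[i] - z[j], box);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - t.er0[b];
    ep.elastic += 0.5 * ff.kelastic * d * d;
    if (r > 1e-12) {
      double fr = -ff.kelastic * d / r;
      fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
      fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
    }
  }
  (void)n;
  return ep;
}

static double max_pair_cutoff(const FF& ff) {
  double bmax = std::max(ff.bHH, std::max(ff.bHT, ff.bTT));
  return POW216 * bmax + ff.wc;
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, double box,
                       IntegerVector cls, IntegerVector kind,
                       IntegerMatrix fene, IntegerMatrix harm,
                       NumericVector harm_r0, IntegerMatrix elas,
                       NumericVector elas_r0, List ffl,
                       bool brute, bool soft) {
  FF ff = ff_from_list(ffl);
  Topo t = topo_from_args(cls, kind, fene, harm, harm_r0, elas, elas_r0);
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
  std::vector<std::pair<int,int> > pairs;
  build_pairs(x, y, z, box, max_pair_cutoff(ff), pairs, brute);
  EnergyParts ep = eval_all(x, y, z, box, t, ff, pairs, fx, fy, fz, soft);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) { F(i,0) = fx[i]; F(i,1) = fy[i]; F(i,2) = fz[i]; }
  return List::create(_["energy"] = ep.total(), _["forces"] = F,
                      _["pair"] = ep.pair, _["fene"] = ep.fene,
                      _["bend"] = ep.bend, _["elastic"] = ep.elastic);
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, double box, double rlist,
                                 bool brute) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
  std::vector<std::pair<int,int> > pairs;
  build_pairs(x, y, z, box, rlist, pairs, brute);
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); ++p) {
    out(p, 0) = pairs[p].first + 1;
    out(p, 1) = pairs[p].second + 1;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, double box,
                  IntegerVector cls, IntegerVector kind,
                  IntegerMatrix fene, IntegerMatrix harm,
                  NumericVector harm_r0, IntegerMatrix elas,
                  NumericVector elas_r0, List ffl,
                  int max_steps, double ftol, double max_disp) {
  FF ff = ff_from_list(ffl);
  Topo t = topo_from_args(cls, kind, fene, harm, harm_r0, elas, elas_r0);
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  std::vector<double> xt(n), yt(n), zt(n), ft1(n), ft2(n), ft3(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
  const double rlist = max_pair_cutoff(ff) + 0.3;
  std::vector<std::pair<int,int> > pairs;
  build_pairs(x, y, z, box, rlist, pairs);
  double e = eval_all(x, y, z, box, t, ff, pairs, fx, fy, fz, true).total();
  if (!std::isfinite(e)) stop("minimize: initial energy is not finite");
  double alpha = 1e-4;
  int steps = 0;
  bool converged = false;
  for (steps = 0; steps < max_steps; ++steps) {
    double fmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double f2 = fx[i]*fx[i] + fy[i]*fy[i] + fz[i]*fz[i];
      if (f2 > fmax) fmax = f2;
    }
    fmax = std::sqrt(fmax);
    if (fmax < ftol) { converged = true; break; }
    bool accepted = false;
    for (int tries = 0; tries < 40 && !accepted; ++tries) {
      for (int i = 0; i < n; ++i) {
        double dx = alpha * fx[i], dy = alpha * fy[i], dz = alpha * fz[i];
        double dm = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (dm > max_disp) { double s = max_disp / dm; dx *= s; dy *= s; dz *= s; }
        xt[i] = x[i] + dx; yt[i] = y[i] + dy; zt[i] = z[i] + dz;
      }
      build_pairs(xt, yt, zt, box, rlist, pairs);
      double et = eval_all(xt, yt, zt, box, t, ff, pairs, ft1, ft2, ft3, true).total();
      if (std::isfinite(et) && et <= e) {
        x.swap(xt); y.swap(yt); z.swap(zt);
        fx.swap(ft1); fy.swap(ft2); fz.swap(ft3);
        e = et;
        alpha = std::min(alpha * 1.2, 0.05);
        accepted = true;
      } else {
        alpha *= 0.5;
      }
    }
    if (!accepted) { converged = true; break; } // line search exhausted: at a minimum
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i,0) = x[i]; out(i,1) = y[i]; out(i,2) = z[i]; }
  return List::create(_["positions"] = out, _["energy"] = e,
                      _["steps"] = steps, _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Production integrator internals: a typed Verlet pair list (per-pair
// diameter, attraction width, and cutoffs resolved once at build time, with
// per-type list radii so e.g. attraction-free peptide-peptide pairs are only
// kept within their much shorter WCA range) and a branch-free minimum image.
// ---------------------------------------------------------------------------

static inline double min_image_fast(double d, double box, double invbox) {
  return d - box * (double)(long long)(d * invbox + std::copysign(0.5, d));
}

struct TypedPairs {
  std::vector<int> pi, pj;
  std::vector<double> b, wc, rcut2;
};

// Enumerate candidate pairs with the global list radius, then keep each at
// its own type-resolved radius (interaction cutoff + skin).
static void build_typed_pairs(const std::vector<double>& x,
                              const std::vector<double>& y,
                              const std::vector<double>& z,
                              double box, const Topo& t, const FF& ff,
                              double skin, TypedPairs& tp) {
  static std::vector<std::pair<int,int> > cand;
  build_pairs(x, y, z, box, max_pair_cutoff(ff) + skin, cand);
  tp.pi.clear(); tp.pj.clear(); tp.b.clear(); tp.wc.clear(); tp.rcut2.clear();
  const double invbox = 1.0 / box;
  for (size_t p = 0; p < cand.size(); ++p) {
    int i = cand[p].first, j = cand[p].second;
    if (t.excluded(i, j)) continue;
    double b = pair_b(ff, t.cls[i], t.cls[j]);
    double wcp = pair_wc(ff, t.cls[i], t.cls[j], t.kind[i], t.kind[j]);
    double rcut = POW216 * b + wcp;
    double rl = rcut + skin;
    double dx = min_image_fast(x[i] - x[j], box, invbox);
    double dy = min_image_fast(y[i] - y[j], box, invbox);
    double dz = min_image_fast(z[i] - z[j], box, invbox);
    if (dx * dx + dy * dy + dz * dz > rl * rl) continue;
    tp.pi.push_back(i); tp.pj.push_back(j);
    tp.b.push_back(b); tp.wc.push_back(wcp); tp.rcut2.push_back(rcut * rcut);
  }
}

// Make every molecule whole: BFS over the bond graph, shifting each newly
// reached bead by the lattice vector that minimizes its bond length. With
// whole molecules and unwrapped positions the bonded terms need no minimum
// image in the hot loop (nonbonded pairs still use it).
static void make_whole(std::vector<double>& x, std::vector<double>& y,
                       std::vector<double>& z, double box, const Topo& t) {
  const int n = (int)x.size();
  std::vector<std::vector<int> > adj(n);
  for (size_t b = 0; b < t.fi.size(); ++b) {
    adj[t.fi[b]].push_back(t.fj[b]); adj[t.fj[b]].push_back(t.fi[b]);
  }
  for (size_t b = 0; b < t.hi.size(); ++b) {
    adj[t.hi[b]].push_back(t.hj[b]); adj[t.hj[b]].push_back(t.hi[b]);
  }
  for (size_t b = 0; b < t.ei.size(); ++b) {
    adj[t.ei[b]].push_back(t.ej[b]); adj[t.ej[b]].push_back(t.ei[b]);
  }
  std::vector<char> seen(n, 0);
  std::vector<int> queue;
  for (int s = 0; s < n; ++s) {
    if (seen[s]) continue;
    seen[s] = 1;
    queue.clear();
    queue.push_back(s);
    for (size_t q = 0; q < queue.size(); ++q) {
      int i = queue[q];
      for (size_t a = 0; a < adj[i].size(); ++a) {
        int j = adj[i][a];
        if (seen[j]) continue;
        seen[j] = 1;
        x[j] = x[i] + min_image(x[j] - x[i], box);
        y[j] = y[i] + min_image(y[j] - y[i], box);
        z[j] = z[i] + min_image(z[j] - z[i], box);
        queue.push_back(j);
      }
    }
  }
}

// Hot-loop evaluator over a typed pair list; returns potential energy.
static double eval_typed(const std::vector<double>& x,
                         const std::vector<double>& y,
                         const std::vector<double>& z,
                         double box, const Topo& t, const FF& ff,
                         const TypedPairs& tp,
                         std::vector<double>& fx, std::vector<double>& fy,
                         std::vector<double>& fz) {
  const double invbox = 1.0 / box;
  double pe = 0.0;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  const size_t np = tp.pi.size();
  for (size_t p = 0; p < np; ++p) {
    const int i = tp.pi[p], j = tp.pj[p];
    double dx = min_image_fast(x[i] - x[j], box, invbox);
    double dy = min_image_fast(y[i] - y[j], box, invbox);
    double dz = min_image_fast(z[i] - z[j], box, invbox);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > tp.rcut2[p] || r2 < 1e-12) continue;
    double r = std::sqrt(r2);
    double e, fmag;
    pair_ef(r, tp.b[p], tp.wc[p], ff, e, fmag);
    pe += e;
    double fr = fmag / r;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  }
  // bonded terms: positions are unwrapped and molecules whole, so plain
  // coordinate differences are the physical bond vectors
  const double rinf2 = ff.rinf * ff.rinf;
  for (size_t b = 0; b < t.fi.size(); ++b) {
    int i = t.fi[b], j = t.fj[b];
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rinf2)
      stop("FENE bond %d-%d overextended: r = %.4f nm >= r_inf = %.4f nm "
           "(fatal instability)", i + 1, j + 1, std::sqrt(r2), ff.rinf);
    double u = 1.0 - r2 / rinf2;
    pe += -0.5 * ff.kbond * rinf2 * std::log(u);
    double fr = -ff.kbond / u;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  }
  for (size_t b = 0; b < t.hi.size(); ++b) {
    int i = t.hi[b], j = t.hj[b];
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - t.hr0[b];
    pe += 0.5 * ff.kbend * d * d;
    double fr = -ff.kbend * d / r;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  }
  const int ne = (int)t.ei.size();
  const int* RESTRICT ei = t.ei.data();
  const int* RESTRICT ej = t.ej.data();
  const double* RESTRICT er0 = t.er0.data();
  for (int b = 0; b < ne; ++b) {
    int i = ei[b], j = ej[b];
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = r - er0[b];
    pe += 0.5 * ff.kelastic * d * d;
    double fr = -ff.kelastic * d / r;
    fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
    fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
  }
  return pe;
}

// Deterministic Gaussian stream: mt19937_64 (fully specified by the C++
// standard) feeding a Marsaglia-Tsang 128-layer ziggurat, so same seed =>
// bit-identical trajectories at a fraction of the Box-Muller cost.
struct GaussRNG {
  std::mt19937_64 eng;
  uint32_t kn[129];
  double wn[128], fn[128];
  explicit GaussRNG(uint64_t seed) : eng(seed) {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  double unif() { return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double operator()() {
    const double r = 3.442619855899;
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)eng();
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t ahz = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < kn[iz]) return hz * wn[iz];
      if (iz == 0) { // tail
        double xx, yy;
        do {
          xx = -std::log(unif()) / r;
          yy = -std::log(unif());
        } while (yy + yy < xx * xx);
        return (hz > 0) ? r + xx : -(r + xx);
      }
      double x = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, NumericMatrix vel, double box,
                      IntegerVector cls, IntegerVector kind,
                      IntegerMatrix fene, IntegerMatrix harm,
                      NumericVector harm_r0, IntegerMatrix elas,
                      NumericVector elas_r0, List ffl,
                      double mass, double dt_fs, double friction_ps,
                      double temp_K, double n_steps_d, int snap_every,
                      double seed, bool thermostat, double skin) {
  FF ff = ff_from_list(ffl);
  Topo t = topo_from_args(cls, kind, fene, harm, harm_r0, elas, elas_r0);
  const int n = pos.nrow();
  const long long n_steps = (long long)n_steps_d;
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n), fx(n), fy(n), fz(n);
  std::vector<double> x0(n), y0(n), z0(n); // positions at last list build
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2);
    vx[i] = vel(i,0); vy[i] = vel(i,1); vz[i] = vel(i,2);
  }
  const double dt = dt_fs / TIME_UNIT_FS;
  const double gamma = thermostat ? friction_ps * (TIME_UNIT_FS / 1000.0) : 0.0;
  const double kT = KB_KCAL * temp_K;
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) * std::sqrt(kT / mass);
  GaussRNG rng((uint64_t)seed);

  make_whole(x, y, z, box, t);
  TypedPairs tp;
  build_typed_pairs(x, y, z, box, t, ff, skin, tp);
  x0 = x; y0 = y; z0 = z;
  double pe = eval_typed(x, y, z, box, t, ff, tp, fx, fy, fz);

  const long long n_snap = (snap_every > 0) ? n_steps / snap_every : 0;
  List frames(n_snap);
  NumericVector snap_pe(n_snap), snap_ke(n_snap), snap_step(n_snap);
  long long isnap = 0;
  const double half_dt = 0.5 * dt;
  const double skin_half2 = 0.25 * skin * skin;

  for (long long step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n; ++i) { // B
      vx[i] += half_dt * fx[i] / mass;
      vy[i] += half_dt * fy[i] / mass;
      vz[i] += half_dt * fz[i] / mass;
      x[i] += half_dt * vx[i]; // A
      y[i] += half_dt * vy[i];
      z[i] += half_dt * vz[i];
    }
    if (thermostat) { // O
      for (int i = 0; i < n; ++i) {
        vx[i] = c1 * vx[i] + c2 * rng();
        vy[i] = c1 * vy[i] + c2 * rng();
        vz[i] = c1 * vz[i] + c2 * rng();
      }
    }
    for (int i = 0; i < n; ++i) { // A
      x[i] += half_dt * vx[i];
      y[i] += half_dt * vy[i];
      z[i] += half_dt * vz[i];
    }
    // rebuild pair list when any bead moved more than skin/2 since build
    double dmax2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - x0[i], dy = y[i] - y0[i], dz = z[i] - z0[i];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > dmax2) dmax2 = d2;
    }
    if (dmax2 > skin_half2) {
      build_typed_pairs(x, y, z, box, t, ff, skin, tp);
      x0 = x; y0 = y; z0 = z;
    }
    pe = eval_typed(x, y, z, box, t, ff, tp, fx, fy, fz);
    for (int i = 0; i < n; ++i) { // B
      vx[i] += half_dt * fx[i] / mass;
      vy[i] += half_dt * fy[i] / mass;
      vz[i] += half_dt * fz[i] / mass;
    }
    if (snap_every > 0 && (step + 1) % snap_every == 0) {
      if (!std::isfinite(x[0]) || !std::isfinite(pe))
        stop("run_langevin: non-finite state at step %ld", (long)(step + 1));
      NumericMatrix fr(n, 3);
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        fr(i,0) = x[i] - box * std::floor(x[i] / box);
        fr(i,1) = y[i] - box * std::floor(y[i] / box);
        fr(i,2) = z[i] - box * std::floor(z[i] / box);
        ke += 0.5 * mass * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
      }
      frames[isnap] = fr;
      snap_pe[isnap] = pe;
      snap_ke[isnap] = ke;
      snap_step[isnap] = (double)(step + 1);
      ++isnap;
      Rcpp::checkUserInterrupt();
    }
  }
  NumericMatrix P(n, 3), V(n, 3);
  for (int i = 0; i < n; ++i) {
    P(i,0) = x[i] - box * std::floor(x[i] / box);
    P(i,1) = y[i] - box * std::floor(y[i] / box);
    P(i,2) = z[i] - box * std::floor(z[i] / box);
    V(i,0) = vx[i]; V(i,1) = vy[i]; V(i,2) = vz[i];
  }
  return List::create(_["frames"] = frames, _["snap_pe"] = snap_pe,
                      _["snap_ke"] = snap_ke, _["snap_step"] = snap_step,
                      _["positions"] = P, _["velocities"] = V);
}

// ---------------------------------------------------------------------------
// Single-linkage clustering of selected beads (union-find over the contact
// graph at `cutoff` under minimum image). Returns 1-based component labels.
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
  return i;
}

// [[Rcpp::export]]
IntegerVector cpp_cluster(NumericMatrix pos, double box, double cutoff,
                          bool brute) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
  std::vector<std::pair<int,int> > pairs;
  build_pairs(x, y, z, box, cutoff, pairs, brute);
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (size_t p = 0; p < pairs.size(); ++p) {
    int a = uf_find(parent, pairs[p].first);
    int b = uf_find(parent, pairs[p].second);
    if (a != b) parent[a] = b;
  }
  IntegerVector lab(n);
  std::vector<int> remap(n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find(parent, i);
    if (remap[r] < 0) remap[r] = next++;
    lab[i] = remap[r] + 1;
  }
  return lab;
}
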