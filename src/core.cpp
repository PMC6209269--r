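// Core particle kernels: force-shifted LJ pair potential, FENE bonds,
// three-body bending, energy decomposition, velocity-Verlet NVT/NVE
// integration (Nose-Hoover and Langevin/BAOAB), contact counting, and a
// discrete worm-like-chain sampler.  All quantities in reduced units
// (epsilon, sigma, kB = 1).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <unordered_set>
#include <sstream>
using namespace Rcpp;

// ---------------------------------------------------------------- potentials

static inline double ulj(double r, double eps, double s) {
  double sr = s / r;
  double sr6 = sr * sr * sr; sr6 *= sr6;
  double sr12 = sr6 * sr6;
  return 4.0 * eps * (sr12 - sr6);
}

// dU_LJ/dr
static inline double dulj(double r, double eps, double s) {
  double sr = s / r;
  double sr6 = sr * sr * sr; sr6 *= sr6;
  double sr12 = sr6 * sr6;
  return 4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / r;
}

// force-shifted LJ: U(r) = ULJ(r) - ULJ(rc) - (r - rc) ULJ'(rc) for r < rc,
// zero at and beyond the cutoff.  fr is the radial force -dU/dr.
static inline void pair_ef(double r, double eps, double s, double rc,
                           double ulj_rc, double dulj_rc,
                           double &e, double &fr) {
  if (r >= rc) { e = 0.0; fr = 0.0; return; }
  e  = ulj(r, eps, s) - ulj_rc - (r - rc) * dulj_rc;
  fr = -(dulj(r, eps, s) - dulj_rc);
}

static inline void fene_ef(double r, double kf, double r0, double rs,
                           double &e, double &fr, bool &ok) {
  double x = (r - rs) / r0;
  if (x * x >= 1.0 || r < rs) { ok = false; e = R_PosInf; fr = 0.0; return; }
  ok = true;
  e  = -0.5 * kf * r0 * r0 * std::log(1.0 - x * x);
  fr = -kf * (r - rs) / (1.0 - x * x);
}

// [[Rcpp::export]]
List cpp_pair_ef(NumericVector r, double eps, double sigma, double rcut) {
  int n = r.size();
  NumericVector e(n), f(n);
  double ulj_rc = ulj(rcut, eps, sigma), dulj_rc = dulj(rcut, eps, sigma);
  for (int i = 0; i < n; ++i) {
    if (!(r[i] > 0.0)) stop("invalid geometry: pair distance must be > 0");
    pair_ef(r[i], eps, sigma, rcut, ulj_rc, dulj_rc, e[i], f[i]);
  }
  return List::create(_["energy"] = e, _["force"] = f);
}

// [[Rcpp::export]]
List cpp_fene_ef(NumericVector r, double k_fene, double r0_fene, double r_shift) {
  int n = r.size();
  NumericVector e(n), f(n);
  for (int i = 0; i < n; ++i) {
    bool ok;
    fene_ef(r[i], k_fene, r0_fene, r_shift, e[i], f[i], ok);
    if (!ok) stop("bond overextension: r = %f outside FENE domain [%f, %f)",
                  r[i], r_shift, r_shift + r0_fene);
  }
  return List::create(_["energy"] = e, _["force"] = f);
}

// bending energy k(1 + cos theta) with theta the interior angle at the
// central bead j; returns energy and the exact negative gradient on i, j, k.
static inline double bend_ef(const double *ri, const double *rj, const double *rk,
                             double kb,
                             double *fi, double *fj, double *fk, bool &ok) {
  double u1[3], u2[3];
  for (int d = 0; d < 3; ++d) { u1[d] = ri[d] - rj[d]; u2[d] = rk[d] - rj[d]; }
  double n1 = std::sqrt(u1[0]*u1[0] + u1[1]*u1[1] + u1[2]*u1[2]);
  double n2 = std::sqrt(u2[0]*u2[0] + u2[1]*u2[1] + u2[2]*u2[2]);
  if (n1 <= 0.0 || n2 <= 0.0) { ok = false; return R_PosInf; }
  ok = true;
  double dot = u1[0]*u2[0] + u1[1]*u2[1] + u1[2]*u2[2];
  double c = dot / (n1 * n2);
  if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
  double e = kb * (1.0 + c);
  // dE/dcos(theta) = kb; gradients of cos(theta)
  for (int d = 0; d < 3; ++d) {
    double dci = u2[d] / (n1 * n2) - c * u1[d] / (n1 * n1);
    double dck = u1[d] / (n1 * n2) - c * u2[d] / (n2 * n2);
    fi[d] = -kb * dci;
    fk[d] = -kb * dck;
    fj[d] = -(fi[d] + fk[d]);
  }
  return e;
}

// [[Rcpp::export]]
List cpp_bend_ef(NumericVector ri, NumericVector rj, NumericVector rk, double k_bend) {
  double fi[3], fj[3], fk[3];
  bool ok;
  double e = bend_ef(REAL(ri), REAL(rj), REAL(rk), k_bend, fi, fj, fk, ok);
  if (!ok) stop("invalid geometry: coincident beads in angle triple");
  return List::create(_["energy"] = e,
                      _["f_i"] = NumericVector(fi, fi + 3),
                      _["f_j"] = NumericVector(fj, fj + 3),
                      _["f_k"] = NumericVector(fk, fk + 3));
}

// ------------------------------------------------------------- system state

struct Params {
  double eps, sigma, rc, kf, r0, rs, kbend, mass, dt;
  double ulj_rc, dulj_rc;
  bool exclude_bonded;
};

struct EB { double inter, intra, fene, bend; EB() : inter(0), intra(0), fene(0), bend(0) {} };

static inline double minimg(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

static inline int64_t pkey(int i, int j, int n) {
  return (int64_t)i * (int64_t)n + (int64_t)j;
}

// Exclusion set of directly bonded (1-2) pairs, keys with i < j.
static std::unordered_set<int64_t> build_excl(const IntegerMatrix &bonds, int n) {
  std::unordered_set<int64_t> ex;
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    if (i > j) std::swap(i, j);
    ex.insert(pkey(i, j, n));
  }
  return ex;
}

// Gather candidate pair list (i<j, r < rc) via cell list; periodic cubic box.
// Bead-centric sweep (cost ~ n * occupancy, not n_cells^3).  Falls back to
// caller's brute force when the box is too small for >=3 cells per side.
static bool cell_pairs(const double *px, const double *py, const double *pz,
                       int n, double box, double rc,
                       std::vector<std::pair<int,int> > &out) {
  int nc = (int)std::floor(box / rc);
  if (nc < 3) return false;
  if (nc > 200) nc = 200;
  double cw = box / nc;
  std::vector<int> head((size_t)nc * nc * nc, -1), nxt(n, -1), cell(n);
  for (int i = 0; i < n; ++i) {
    double wx = px[i] - box * std::floor(px[i] / box);
    double wy = py[i] - box * std::floor(py[i] / box);
    double wz = pz[i] - box * std::floor(pz[i] / box);
    int ix = (int)(wx / cw); if (ix >= nc) ix = nc - 1;
    int iy = (int)(wy / cw); if (iy >= nc) iy = nc - 1;
    int iz = (int)(wz / cw); if (iz >= nc) iz = nc - 1;
    int c = (ix * nc + iy) * nc + iz;
    cell[i] = c;
    nxt[i] = head[c]; head[c] = i;
  }
  double rc2 = rc * rc;
  for (int i = 0; i < n; ++i) {
    int c = cell[i];
    int iz = c % nc, iy = (c / nc) % nc, ix = c / (nc * nc);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int jx = (ix + dx + nc) % nc, jy = (iy + dy + nc) % nc,
              jz = (iz + dz + nc) % nc;
          int c2 = (jx * nc + jy) * nc + jz;
          for (int j = head[c2]; j >= 0; j = nxt[j]) {
            if (j <= i) continue;          // each unordered pair once
            double ddx = minimg(px[i] - px[j], box);
            double ddy = minimg(py[i] - py[j], box);
            double ddz = minimg(pz[i] - pz[j], box);
            if (ddx*ddx + ddy*ddy + ddz*ddz < rc2)
              out.push_back(std::make_pair(i, j));
          }
        }
  }
  // with nc == 3 the wrapped neighbor offsets revisit cells; dedupe
  if (nc == 3) {
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
  }
  return true;
}

// Full force + energy evaluation.  Fills f (3n), returns energies in eb.
// ok=false with msg set on FENE overextension.
static bool eval_all(const double *px, const double *py, const double *pz,
                     int n, double box, bool periodic,
                     const IntegerMatrix &bonds, const IntegerMatrix &angles,
                     const int *cid, const Params &P,
                     const std::unordered_set<int64_t> &excl,
                     bool force_brute, bool sort_pairs,
                     double *fx, double *fy, double *fz,
                     EB &eb, std::string &msg) {
  for (int i = 0; i < n; ++i) { fx[i] = fy[i] = fz[i] = 0.0; }
  eb = EB();
  // --- nonbonded pairs
  std::vector<std::pair<int,int> > pl;
  bool have_cells = false;
  if (!force_brute && periodic)
    have_cells = cell_pairs(px, py, pz, n, box, P.rc, pl);
  if (have_cells && sort_pairs) std::sort(pl.begin(), pl.end());
  double e, fr;
  if (have_cells) {
    for (size_t k = 0; k < pl.size(); ++k) {
      int i = pl[k].first, j = pl[k].second;
      if (excl.count(pkey(i, j, n))) continue;
      double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
      dx = minimg(dx, box); dy = minimg(dy, box); dz = minimg(dz, box);
      double r2 = dx*dx + dy*dy + dz*dz;
      double r = std::sqrt(r2);
      if (r >= P.rc) continue;
      pair_ef(r, P.eps, P.sigma, P.rc, P.ulj_rc, P.dulj_rc, e, fr);
      if (cid[i] == cid[j]) eb.intra += e; else eb.inter += e;
      double s = fr / r;
      fx[i] += s * dx; fy[i] += s * dy; fz[i] += s * dz;
      fx[j] -= s * dx; fy[j] -= s * dy; fz[j] -= s * dz;
    }
  } else {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (excl.count(pkey(i, j, n))) continue;
        double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
        if (periodic) { dx = minimg(dx, box); dy = minimg(dy, box); dz = minimg(dz, box); }
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 >= P.rc * P.rc) continue;
        double r = std::sqrt(r2);
        pair_ef(r, P.eps, P.sigma, P.rc, P.ulj_rc, P.dulj_rc, e, fr);
        if (cid[i] == cid[j]) eb.intra += e; else eb.inter += e;
        double s = fr / r;
        fx[i] += s * dx; fy[i] += s * dy; fz[i] += s * dz;
        fx[j] -= s * dx; fy[j] -= s * dy; fz[j] -= s * dz;
      }
  }
  // --- FENE bonds
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
    if (periodic) { dx = minimg(dx, box); dy = minimg(dy, box); dz = minimg(dz, box); }
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    bool ok;
    fene_ef(r, P.kf, P.r0, P.rs, e, fr, ok);
    if (!ok) {
      std::ostringstream ss;
      ss << "bond overextension between beads " << (i + 1) << " and " << (j + 1)
         << " (r = " << r << ")";
      msg = ss.str();
      return false;
    }
    eb.fene += e;
    double s = fr / r;
    fx[i] += s * dx; fy[i] += s * dy; fz[i] += s * dz;
    fx[j] -= s * dx; fy[j] -= s * dy; fz[j] -= s * dz;
  }
  // --- angles (chains are short against the box; positions are unwrapped,
  // so no minimum image inside a triple)
  double fi[3], fj[3], fk[3];
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);
    double ri[3] = { px[i], py[i], pz[i] };
    double rj[3] = { px[j], py[j], pz[j] };
    double rk[3] = { px[k], py[k], pz[k] };
    bool ok;
    double eb_ = bend_ef(ri, rj, rk, P.kbend, fi, fj, fk, ok);
    if (!ok) { msg = "coincident beads in angle triple"; return false; }
    eb.bend += eb_;
    fx[i] += fi[0]; fy[i] += fi[1]; fz[i] += fi[2];
    fx[j] += fj[0]; fy[j] += fj[1]; fz[j] += fj[2];
    fx[k] += fk[0]; fy[k] += fk[1]; fz[k] += fk[2];
  }
  return true;
}

static Params unpack(List p) {
  Params P;
  P.eps = p["epsilon"]; P.sigma = p["sigma"]; P.rc = p["r_cut"];
  P.kf = p["k_fene"]; P.r0 = p["r0_fene"]; P.rs = p["r_shift"];
  P.kbend = p["k_bend"]; P.mass = p["mass"]; P.dt = p["dt"];
  P.ulj_rc = ulj(P.rc, P.eps, P.sigma);
  P.dulj_rc = dulj(P.rc, P.eps, P.sigma);
  P.exclude_bonded = p.containsElementNamed("exclude_bonded_pairs") ?
    as<bool>(p["exclude_bonded_pairs"]) : false;
  return P;
}

// method: 0 auto (cells when available, pairs sorted into brute order),
//         1 brute force O(n^2)
// [[Rcpp::export]]
List cpp_energies(NumericMatrix pos, Nullable<NumericMatrix> vel,
                  double box, bool periodic,
                  IntegerMatrix bonds, IntegerMatrix angles, IntegerVector cid,
                  List params, int method) {
  int n = pos.nrow();
  Params P = unpack(params);
  std::vector<double> px(n), py(n), pz(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2); }
  std::unordered_set<int64_t> excl;
  if (P.exclude_bonded) excl = build_excl(bonds, n);
  EB eb; std::string msg;
  bool ok = eval_all(px.data(), py.data(), pz.data(), n, box, periodic,
                     bonds, angles, cid.begin(), P, excl,
                     method == 1, true, fx.data(), fy.data(), fz.data(), eb, msg);
  if (!ok) stop(msg);
  double ekin = 0.0;
  if (vel.isNotNull()) {
    NumericMatrix v(vel);
    for (int i = 0; i < n; ++i)
      ekin += 0.5 * P.mass * (v(i,0)*v(i,0) + v(i,1)*v(i,1) + v(i,2)*v(i,2));
  }
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) { F(i,0) = fx[i]; F(i,1) = fy[i]; F(i,2) = fz[i]; }
  return List::create(_["e_pair_inter"] = eb.inter, _["e_pair_intra"] = eb.intra,
                      _["e_fene"] = eb.fene, _["e_bend"] = eb.bend,
                      _["e_kin"] = ekin, _["forces"] = F);
}

// ------------------------------------------------------------- MD integrator

// thermostat: 0 = none (NVE), 1 = Nose-Hoover, 2 = Langevin (BAOAB)
// Target temperature at step s (1-based): max(T_end, T0 - Trate*s); Trate = 0
// holds T0.  Samples energies every sample_every steps (and at step 0);
// stores positions every traj_every steps when traj_every > 0.
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, double box, bool periodic,
                IntegerMatrix bonds, IntegerMatrix angles, IntegerVector cid,
                List params, int thermostat,
                double T0, double Trate, double Tend, double coupling,
                int n_steps, int sample_every, int traj_every, double xi0) {
  int n = pos.nrow();
  Params P = unpack(params);
  double dt = P.dt, m = P.mass;
  std::vector<double> px(n), py(n), pz(n), vx(n), vy(n), vz(n),
                      fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2);
    vx[i] = vel(i,0); vy[i] = vel(i,1); vz[i] = vel(i,2);
  }
  std::unordered_set<int64_t> excl;
  if (P.exclude_bonded) excl = build_excl(bonds, n);
  EB eb; std::string msg;
  if (!eval_all(px.data(), py.data(), pz.data(), n, box, periodic, bonds, angles,
                cid.begin(), P, excl, false, false,
                fx.data(), fy.data(), fz.data(), eb, msg))
    stop("integration failure at step 0: %s", msg);

  int g = 3 * n;                       // kinetic degrees of freedom
  double xi = xi0;
  RNGScope rng;                        // Langevin noise from R's RNG

  int n_samples = n_steps / std::max(sample_every, 1) + 1;
  NumericMatrix samp(n_samples, 9);
  CharacterVector sampnm = CharacterVector::create(
    "step", "T_target", "e_pair_inter", "e_pair_intra", "e_fene", "e_bend",
    "e_kin", "t_kin", "e_total");
  int srow = 0;
  List traj;
  std::vector<NumericMatrix> frames;

  double ekin = 0.0;
  for (int i = 0; i < n; ++i)
    ekin += 0.5 * m * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
  double Tt = T0;
  samp(srow, 0) = 0; samp(srow, 1) = Tt;
  samp(srow, 2) = eb.inter; samp(srow, 3) = eb.intra;
  samp(srow, 4) = eb.fene; samp(srow, 5) = eb.bend;
  samp(srow, 6) = ekin; samp(srow, 7) = 2.0 * ekin / g;
  samp(srow, 8) = eb.inter + eb.intra + eb.fene + eb.bend + ekin;
  ++srow;

  double c1 = 0.0, gamma = 0.0;
  if (thermostat == 2) { gamma = 1.0 / coupling; c1 = std::exp(-gamma * dt); }

  for (int s = 1; s <= n_steps; ++s) {
    Tt = T0 - Trate * s;
    if (Tt < Tend) Tt = Tend;
    if (thermostat == 1) {
      // explicit single Nose-Hoover chain around velocity Verlet
      double Q = g * Tt * coupling * coupling;
      double K = 0.0;
      for (int i = 0; i < n; ++i)
        K += 0.5 * m * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
      xi += 0.5 * dt * (2.0 * K - g * Tt) / Q;
      double sc = std::exp(-xi * 0.5 * dt);
      for (int i = 0; i < n; ++i) { vx[i] *= sc; vy[i] *= sc; vz[i] *= sc; }
      for (int i = 0; i < n; ++i) {
        vx[i] += 0.5 * dt * fx[i] / m; vy[i] += 0.5 * dt * fy[i] / m; vz[i] += 0.5 * dt * fz[i] / m;
        px[i] += dt * vx[i]; py[i] += dt * vy[i]; pz[i] += dt * vz[i];
      }
      if (!eval_all(px.data(), py.data(), pz.data(), n, box, periodic, bonds, angles,
                    cid.begin(), P, excl, false, false,
                    fx.data(), fy.data(), fz.data(), eb, msg))
        stop("integration failure at step %d: %s", s, msg);
      for (int i = 0; i < n; ++i) {
        vx[i] += 0.5 * dt * fx[i] / m; vy[i] += 0.5 * dt * fy[i] / m; vz[i] += 0.5 * dt * fz[i] / m;
      }
      K = 0.0;
      for (int i = 0; i < n; ++i)
        K += 0.5 * m * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
      sc = std::exp(-xi * 0.5 * dt);
      for (int i = 0; i < n; ++i) { vx[i] *= sc; vy[i] *= sc; vz[i] *= sc; }
      K *= sc * sc;
      xi += 0.5 * dt * (2.0 * K - g * Tt) / Q;
    } else if (thermostat == 2) {
      // BAOAB splitting
      double c2 = std::sqrt((1.0 - c1 * c1) * Tt / m);
      for (int i = 0; i < n; ++i) {
        vx[i] += 0.5 * dt * fx[i] / m; vy[i] += 0.5 * dt * fy[i] / m; vz[i] += 0.5 * dt * fz[i] / m;
        px[i] += 0.5 * dt * vx[i]; py[i] += 0.5 * dt * vy[i]; pz[i] += 0.5 * dt * vz[i];
      }
      for (int i = 0; i < n; ++i) {
        vx[i] = c1 * vx[i] + c2 * norm_rand();
        vy[i] = c1 * vy[i] + c2 * norm_rand();
        vz[i] = c1 * vz[i] + c2 * norm_rand();
        px[i] += 0.5 * dt * vx[i]; py[i] += 0.5 * dt * vy[i]; pz[i] += 0.5 * dt * vz[i];
      }
      if (!eval_all(px.data(), py.data(), pz.data(), n, box, periodic, bonds, angles,
                    cid.begin(), P, excl, false, false,
                    fx.data(), fy.data(), fz.data(), eb, msg))
        stop("integration failure at step %d: %s", s, msg);
      for (int i = 0; i < n; ++i) {
        vx[i] += 0.5 * dt * fx[i] / m; vy[i] += 0.5 * dt * fy[i] / m; vz[i] += 0.5 * dt * fz[i] / m;
      }
    } else {
      // NVE velocity Verlet
      for (int i = 0; i < n; ++i) {
        vx[i] += 0.5 * dt * fx[i] / m; vy[i] += 0.5 * dt * fy[i] / m; vz[i] += 0.5 * dt * fz[i] / m;
        px[i] += dt * vx[i]; py[i] += dt * vy[i]; pz[i] += dt * vz[i];
      }
      if (!eval_all(px.data(), py.data(), pz.data(), n, box, periodic, bonds, angles,
                    cid.begin(), P, excl, false, false,
                    fx.data(), fy.data(), fz.data(), eb, msg))
        stop("integration failure at step %d: %s", s, msg);
      for (int i = 0; i < n; ++i) {
        vx[i] += 0.5 * dt * fx[i] / m; vy[i] += 0.5 * dt * fy[i] / m; vz[i] += 0.5 * dt * fz[i] / m;
      }
    }
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(px[i]) || !std::isfinite(py[i]) || !std::isfinite(pz[i]))
        stop("integration failure at step %d: non-finite coordinate (bead %d)", s, i + 1);

    if (sample_every > 0 && s % sample_every == 0 && srow < n_samples) {
      ekin = 0.0;
      for (int i = 0; i < n; ++i)
        ekin += 0.5 * m * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
      samp(srow, 0) = s; samp(srow, 1) = Tt;
      samp(srow, 2) = eb.inter; samp(srow, 3) = eb.intra;
      samp(srow, 4) = eb.fene; samp(srow, 5) = eb.bend;
      samp(srow, 6) = ekin; samp(srow, 7) = 2.0 * ekin / g;
      samp(srow, 8) = eb.inter + eb.intra + eb.fene + eb.bend + ekin;
      ++srow;
    }
    if (traj_every > 0 && s % traj_every == 0) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) { fr(i,0) = px[i]; fr(i,1) = py[i]; fr(i,2) = pz[i]; }
      frames.push_back(fr);
    }
  }
  NumericMatrix samp_out(srow, 9);
  for (int r = 0; r < srow; ++r)
    for (int c = 0; c < 9; ++c) samp_out(r, c) = samp(r, c);
  colnames(samp_out) = sampnm;
  NumericMatrix pout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i) {
    pout(i,0) = px[i]; pout(i,1) = py[i]; pout(i,2) = pz[i];
    vout(i,0) = vx[i]; vout(i,1) = vy[i]; vout(i,2) = vz[i];
  }
  List traj_out(frames.size());
  for (size_t k = 0; k < frames.size(); ++k) traj_out[k] = frames[k];
  return List::create(_["positions"] = pout, _["velocities"] = vout,
                      _["samples"] = samp_out, _["trajectory"] = traj_out,
                      _["xi"] = xi);
}

// --------------------------------------------------------- contact counting

// Counts interchain bead pairs within r_contact; returns a (nc x nc) count
// matrix over chain ids (1-based in cid).
// [[Rcpp::export]]
NumericMatrix cpp_contact_counts(NumericMatrix pos, double box, bool periodic,
                                 IntegerVector cid, double r_contact) {
  int n = pos.nrow();
  int nc = 0;
  for (int i = 0; i < n; ++i) nc = std::max(nc, cid[i]);
  NumericMatrix cnt(nc, nc);
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2); }
  std::vector<std::pair<int,int> > pl;
  bool cells = periodic && cell_pairs(px.data(), py.data(), pz.data(), n, box,
                                      r_contact, pl);
  double r2c = r_contact * r_contact;
  if (cells) {
    for (size_t k = 0; k < pl.size(); ++k) {
      int i = pl[k].first, j = pl[k].second;
      if (cid[i] == cid[j]) continue;
      int a = cid[i] - 1, b = cid[j] - 1;
      cnt(std::min(a,b), std::max(a,b)) += 1.0;
    }
  } else {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (cid[i] == cid[j]) continue;
        double dx = px[i]-px[j], dy = py[i]-py[j], dz = pz[i]-pz[j];
        if (periodic) { dx = minimg(dx,box); dy = minimg(dy,box); dz = minimg(dz,box); }
        if (dx*dx + dy*dy + dz*dz < r2c) {
          int a = cid[i] - 1, b = cid[j] - 1;
          cnt(std::min(a,b), std::max(a,b)) += 1.0;
        }
      }
  }
  for (int a = 0; a < nc; ++a)
    for (int b = a + 1; b < nc; ++b) cnt(b, a) = cnt(a, b);
  return cnt;
}

// Minimum distance from candidate bead set to already placed beads (brute).
// [[Rcpp::export]]
double cpp_min_cross_dist(NumericMatrix cand, NumericMatrix placed,
                          double box, bool periodic) {
  double best = R_PosInf;
  for (int i = 0; i < cand.nrow(); ++i)
    for (int j = 0; j < placed.nrow(); ++j) {
      double dx = cand(i,0) - placed(j,0);
      double dy = cand(i,1) - placed(j,1);
      double dz = cand(i,2) - placed(j,2);
      if (periodic) { dx = minimg(dx,box); dy = minimg(dy,box); dz = minimg(dz,box); }
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

// ------------------------------------------------------------- WLC sampler

// Chains with independent interior angles theta from the Boltzmann density
// ~ exp(-K (1 + cos theta)) sin(theta) (K = k_bend / T), uniform torsions,
// unit bonds.  Inverse-CDF in u = cos(theta); bond-bond correlation is -u.
// Returns n_chains stacked (n_bonds+1) x 3 blocks.
// [[Rcpp::export]]
NumericMatrix cpp_wlc_positions(int n_chains, int n_bonds, double K) {
  RNGScope rng;
  int L = n_bonds + 1;
  NumericMatrix out(n_chains * L, 3);
  double em = -std::expm1(-2.0 * K);       // 1 - exp(-2K)
  for (int c = 0; c < n_chains; ++c) {
    double x = 0, y = 0, z = 0;
    double tx = 0, ty = 0, tz = 1;         // current bond direction
    int base = c * L;
    out(base, 0) = x; out(base, 1) = y; out(base, 2) = z;
    x += tx; y += ty; z += tz;
    out(base + 1, 0) = x; out(base + 1, 1) = y; out(base + 1, 2) = z;
    for (int b = 1; b < n_bonds; ++b) {
      double v = unif_rand();
      double u;                            // cos(interior angle)
      if (K < 1e-12) u = 2.0 * v - 1.0;
      else           u = -1.0 - std::log1p(-v * em) / K;
      if (u > 1.0) u = 1.0; if (u < -1.0) u = -1.0;
      double cg = -u;                      // cos of bond-direction turn
      double sg = std::sqrt(std::max(0.0, 1.0 - cg * cg));
      double phi = 2.0 * M_PI * unif_rand();
      // orthonormal frame around t
      double ax = 0, ay = 0, az = 0;
      if (std::fabs(tx) < 0.9) ax = 1; else ay = 1;
      double n1x = ty * az - tz * ay, n1y = tz * ax - tx * az, n1z = tx * ay - ty * ax;
      double nn = std::sqrt(n1x*n1x + n1y*n1y + n1z*n1z);
      n1x /= nn; n1y /= nn; n1z /= nn;
      double n2x = ty * n1z - tz * n1y, n2y = tz * n1x - tx * n1z, n2z = tx * n1y - ty * n1x;
      double wx = std::cos(phi) * n1x + std::sin(phi) * n2x;
      double wy = std::cos(phi) * n1y + std::sin(phi) * n2y;
      double wz = std::cos(phi) * n1z + std::sin(phi) * n2z;
      tx = cg * tx + sg * wx; ty = cg * ty + sg * wy; tz = cg * tz + sg * wz;
      double tn = std::sqrt(tx*tx + ty*ty + tz*tz);
      tx /= tn; ty /= tn; tz /= tn;
      x += tx; y += ty; z += tz;
      out(base + b + 1, 0) = x; out(base + b + 1, 1) = y; out(base + b + 1, 2) = z;
    }
  }
  return out;
}
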