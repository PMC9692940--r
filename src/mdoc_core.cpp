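// MD core: minimal classical force field with analytic gradients, NMR
// pseudo-forces on exponentially time-averaged observables, and a
// velocity-Verlet integrator with Berendsen weak-coupling thermostat.
//
// Units: A, fs, amu, e; energies kcal/mol; forces kcal mol^-1 A^-1.
// All index matrices arriving from R are 0-based.

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KCAL_TO_INTERNAL = 4.184e-4; // amu A^2 fs^-2 per kcal/mol
static const double KB_KCAL = 1.987204259e-3;    // kcal mol^-1 K^-1

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator*(double s, const V3& a) { return V3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

static inline V3 getrow(const NumericMatrix& m, int i) {
  return V3(m(i, 0), m(i, 1), m(i, 2));
}
static inline void addrow(NumericMatrix& m, int i, const V3& v) {
  m(i, 0) += v.x; m(i, 1) += v.y; m(i, 2) += v.z;
}

// ---------------------------------------------------------------------------
// dihedral angle (radians, IUPAC sign: positive = clockwise far bond viewed
// j->k) and its gradient w.r.t. the four atom positions
static double dihedral_grad(const NumericMatrix& pos, int i, int j, int k, int l,
                            V3 g[4], bool want_grad) {
  V3 b1 = getrow(pos, j) - getrow(pos, i);
  V3 b2 = getrow(pos, k) - getrow(pos, j);
  V3 b3 = getrow(pos, l) - getrow(pos, k);
  V3 n1 = cross(b1, b2);
  V3 n2 = cross(b2, b3);
  double nb = norm(b2);
  double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
  if (n1sq < 1e-18 || n2sq < 1e-18)
    stop("undefined torsion: collinear atoms");
  double phi = std::atan2(nb * dot(b1, n2), dot(n1, n2));
  if (want_grad) {
    V3 gi = (-nb / n1sq) * n1;
    V3 gl = (nb / n2sq) * n2;
    double S = dot(b1, b2) / (nb * nb);
    double T = dot(b3, b2) / (nb * nb);
    V3 gj = (-1.0 - S) * gi + T * gl;
    V3 gk = S * gi + (-1.0 - T) * gl;
    g[0] = gi; g[1] = gj; g[2] = gk; g[3] = gl;
  }
  return phi;
}

// [[Rcpp::export]]
List cpp_dihedral(NumericMatrix pos, IntegerVector quad0) {
  V3 g[4];
  double phi = dihedral_grad(pos, quad0[0], quad0[1], quad0[2], quad0[3], g, true);
  NumericMatrix grad(4, 3);
  for (int a = 0; a < 4; ++a) { grad(a, 0) = g[a].x; grad(a, 1) = g[a].y; grad(a, 2) = g[a].z; }
  return List::create(_["phi"] = phi, _["grad"] = grad);
}

// ---------------------------------------------------------------------------
// physical force field
// ff: list(bond_idx, bond_k, bond_r0, angle_idx, angle_k, angle_theta0,
//          tors_idx, tors_v, tors_n, tors_phase, nb_idx, nb_a, nb_b, nb_qq)
static void ff_eval(const NumericMatrix& pos, const List& ff,
                    NumericMatrix& force, double breakdown[5]) {
  for (int c = 0; c < 5; ++c) breakdown[c] = 0.0;

  IntegerMatrix bidx = ff["bond_idx"];
  NumericVector bk = ff["bond_k"], br0 = ff["bond_r0"];
  for (int t = 0; t < bidx.nrow(); ++t) {
    int i = bidx(t, 0), j = bidx(t, 1);
    V3 d = getrow(pos, j) - getrow(pos, i);
    double r = norm(d);
    if (r < 1e-8) stop("singular geometry: coincident bonded atoms");
    double dr = r - br0[t];
    breakdown[0] += bk[t] * dr * dr;
    double f = -2.0 * bk[t] * dr / r; // dE/dr along d, applied to j
    addrow(force, j, f * d);
    addrow(force, i, (-f) * d);
  }

  IntegerMatrix aidx = ff["angle_idx"];
  NumericVector ak = ff["angle_k"], ath0 = ff["angle_theta0"];
  for (int t = 0; t < aidx.nrow(); ++t) {
    int i = aidx(t, 0), j = aidx(t, 1), k = aidx(t, 2);
    V3 u = getrow(pos, i) - getrow(pos, j);
    V3 v = getrow(pos, k) - getrow(pos, j);
    double nu = norm(u), nv = norm(v);
    double cs = dot(u, v) / (nu * nv);
    cs = std::max(-1.0, std::min(1.0, cs));
    double th = std::acos(cs);
    double sn = std::sqrt(std::max(1.0 - cs * cs, 1e-14));
    double dth = th - ath0[t];
    breakdown[1] += ak[t] * dth * dth;
    double pref = -2.0 * ak[t] * dth; // force = -dE/dtheta * dtheta/dx
    V3 uh = (1.0 / nu) * u, vh = (1.0 / nv) * v;
    V3 gi = (1.0 / (nu * sn)) * (cs * uh - vh); // dtheta/dri
    V3 gk = (1.0 / (nv * sn)) * (cs * vh - uh);
    addrow(force, i, pref * gi);
    addrow(force, k, pref * gk);
    addrow(force, j, (-pref) * gi + (-pref) * gk);
  }

  IntegerMatrix tidx = ff["tors_idx"];
  NumericVector tv = ff["tors_v"], tph = ff["tors_phase"];
  IntegerVector tn = ff["tors_n"];
  for (int t = 0; t < tidx.nrow(); ++t) {
    V3 g[4];
    double phi = dihedral_grad(pos, tidx(t, 0), tidx(t, 1), tidx(t, 2), tidx(t, 3), g, true);
    breakdown[2] += tv[t] * (1.0 + std::cos(tn[t] * phi - tph[t]));
    double dEdphi = -tv[t] * tn[t] * std::sin(tn[t] * phi - tph[t]);
    for (int a = 0; a < 4; ++a) addrow(force, tidx(t, a), (-dEdphi) * g[a]);
  }

  IntegerMatrix nidx = ff["nb_idx"];
  NumericVector na = ff["nb_a"], nbv = ff["nb_b"], nqq = ff["nb_qq"];
  for (int t = 0; t < nidx.nrow(); ++t) {
    int i = nidx(t, 0), j = nidx(t, 1);
    V3 d = getrow(pos, j) - getrow(pos, i);
    double r2 = dot(d, d);
    if (r2 < 1e-12) stop("singular geometry: overlapping nonbonded atoms");
    double r = std::sqrt(r2);
    double ir2 = 1.0 / r2, ir6 = ir2 * ir2 * ir2, ir12 = ir6 * ir6;
    double elj = na[t] * ir12 - nbv[t] * ir6;
    double ecoul = nqq[t] / r;
    breakdown[3] += elj;
    breakdown[4] += ecoul;
    // dE/dr: lj: (-12A/r^13 + 6B/r^7); coul: -qq/r^2
    double dEdr = (-12.0 * na[t] * ir12 + 6.0 * nbv[t] * ir6) / r - nqq[t] * ir2;
    double f = -dEdr / r; // applied to j along d
    addrow(force, j, f * d);
    addrow(force, i, (-f) * d);
  }
}

// [[Rcpp::export]]
List cpp_ff_energy_forces(NumericMatrix pos, List ff) {
  NumericMatrix force(pos.nrow(), 3);
  double br[5];
  ff_eval(pos, ff, force, br);
  NumericVector breakdown = NumericVector::create(
    _["bond"] = br[0], _["angle"] = br[1], _["torsion"] = br[2],
    _["lj"] = br[3], _["coulomb"] = br[4]);
  return List::create(_["energy"] = br[0] + br[1] + br[2] + br[3] + br[4],
                      _["forces"] = force, _["breakdown"] = breakdown);
}

// ---------------------------------------------------------------------------
// dipolar tensor of a pair: D = (coef/r^3) * (3 e e^T - I)/2, coef in Hz A^3
static void dip_tensor(const V3& d, double r, double coef, double D[3][3]) {
  double e[3] = { d.x / r, d.y / r, d.z / r };
  double c = coef / (r * r * r);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      D[a][b] = 0.5 * c * (3.0 * e[a] * e[b] - (a == b ? 1.0 : 0.0));
}

// scale a set of per-atom force contributions so no atom exceeds fcap
// (kcal mol^-1 A^-1); fcap <= 0 disables the cap
static void add_capped(NumericMatrix& force, const int* atoms, V3* f, int na,
                       double fcap) {
  double scale = 1.0;
  if (fcap > 0.0) {
    double mx = 0.0;
    for (int a = 0; a < na; ++a) mx = std::max(mx, norm(f[a]));
    if (mx > fcap) scale = fcap / mx;
  }
  for (int a = 0; a < na; ++a) addrow(force, atoms[a], scale * f[a]);
}

// pseudo-energy/force of one tensorial (RDC) restraint given the memory
// average; gradient flows only through the current-step term (1-lambda)*D(t).
// E = w * sum_ab (avg_ab - target_ab)^2
static double rdc_pseudo(const NumericMatrix& pos, int i, int j, double coef,
                         const double avg[3][3], const double tgt[3][3],
                         double w, double oml, NumericMatrix& force,
                         double fcap = 0.0) {
  V3 dv = getrow(pos, j) - getrow(pos, i);
  double r = norm(dv);
  if (r < 1e-6) stop("singular geometry: coincident RDC pair");
  double e[3] = { dv.x / r, dv.y / r, dv.z / r };
  double c = coef / (r * r * r);
  double E = 0.0, G[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      double dev = avg[a][b] - tgt[a][b];
      E += w * dev * dev;
      G[a][b] = 2.0 * w * dev * oml; // dE/dD_ab(t)
    }
  // dD_ab/dx_j = -3 e_x D_ab / r + (3c/2r) [ (delta_ax - e_a e_x) e_b + e_a (delta_bx - e_b e_x) ]
  double fj[3] = {0, 0, 0};
  for (int x = 0; x < 3; ++x) {
    double acc = 0.0;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double Dab = 0.5 * c * (3.0 * e[a] * e[b] - (a == b ? 1.0 : 0.0));
        double dD = -3.0 * e[x] * Dab / r +
          (1.5 * c / r) * (((a == x ? 1.0 : 0.0) - e[a] * e[x]) * e[b] +
                           e[a] * ((b == x ? 1.0 : 0.0) - e[b] * e[x]));
        acc += G[a][b] * dD;
      }
    fj[x] = -acc;
  }
  int atoms[2] = { j, i };
  V3 fv[2] = { V3(fj[0], fj[1], fj[2]), V3(-fj[0], -fj[1], -fj[2]) };
  add_capped(force, atoms, fv, 2, fcap);
  return E;
}

// flat-bottom excess: zero within +/- halfwidth, linear distance beyond
static inline double flat_excess(double dev, double halfwidth) {
  if (dev > halfwidth) return dev - halfwidth;
  if (dev < -halfwidth) return dev + halfwidth;
  return 0.0;
}

// NOE pseudo term: E = w * u(r_eff - r_exp)^2 with r_eff = <r^-6>^(-1/6)
static double noe_pseudo(const NumericMatrix& pos, int i, int j, double avg_r6,
                         double rexp, double err, double w, double oml,
                         NumericMatrix& force, double fcap = 0.0) {
  V3 dv = getrow(pos, j) - getrow(pos, i);
  double r = norm(dv);
  if (r < 1e-6) stop("singular geometry: coincident NOE pair");
  double reff = std::pow(avg_r6, -1.0 / 6.0);
  double u = flat_excess(reff - rexp, err);
  double E = w * u * u;
  if (u != 0.0) {
    double dE_dm = 2.0 * w * u * (-1.0 / 6.0) * std::pow(avg_r6, -7.0 / 6.0);
    double ds_dr = -6.0 * std::pow(r, -7.0);
    double pref = -dE_dm * oml * ds_dr / r; // force on j along dv
    int atoms[2] = { j, i };
    V3 fv[2] = { pref * dv, (-pref) * dv };
    add_capped(force, atoms, fv, 2, fcap);
  }
  return E;
}

struct KarplusSpec {
  double p1, p2, p3, p4, p5, p6rad;
  std::vector<double> dchi, xi;
};

static double karplus_eval(const KarplusSpec& ks, double phi, double* dJdphi) {
  double c = std::cos(phi);
  double J = ks.p1 * c * c + ks.p2 * c + ks.p3;
  double dJ = -2.0 * ks.p1 * c * std::sin(phi) - ks.p2 * std::sin(phi);
  for (size_t s = 0; s < ks.dchi.size(); ++s) {
    double arg = ks.xi[s] * phi + ks.p6rad * std::fabs(ks.dchi[s]);
    double ca = std::cos(arg);
    J += ks.dchi[s] * (ks.p4 + ks.p5 * ca * ca);
    dJ += -ks.dchi[s] * ks.p5 * 2.0 * ca * std::sin(arg) * ks.xi[s];
  }
  if (dJdphi) *dJdphi = dJ;
  return J;
}

// 3J pseudo term: E = w * u(<J> - Jexp)^2, chain through Karplus and dihedral
static double j_pseudo(const NumericMatrix& pos, const int q[4],
                       const KarplusSpec& ks, double avgJ, double jexp,
                       double err, double w, double oml, NumericMatrix& force,
                       double fcap = 0.0) {
  double u = flat_excess(avgJ - jexp, err);
  double E = w * u * u;
  if (u != 0.0) {
    V3 g[4];
    double phi = dihedral_grad(pos, q[0], q[1], q[2], q[3], g, true);
    double dJ;
    karplus_eval(ks, phi, &dJ);
    double pref = -2.0 * w * u * oml * dJ;
    V3 fv[4];
    for (int a = 0; a < 4; ++a) fv[a] = pref * g[a];
    add_capped(force, q, fv, 4, fcap);
  }
  return E;
}

// single-evaluation wrappers for unit tests -------------------------------

// [[Rcpp::export]]
List cpp_pseudo_rdc(NumericMatrix pos, IntegerVector pair0, double coef,
                    NumericMatrix avg, NumericMatrix target, double w, double oml) {
  NumericMatrix force(pos.nrow(), 3);
  double A[3][3], T[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) { A[a][b] = avg(a, b); T[a][b] = target(a, b); }
  double E = rdc_pseudo(pos, pair0[0], pair0[1], coef, A, T, w, oml, force);
  return List::create(_["energy"] = E, _["forces"] = force);
}

// [[Rcpp::export]]
List cpp_pseudo_noe(NumericMatrix pos, IntegerVector pair0, double avg_r6,
                    double rexp, double err, double w, double oml) {
  NumericMatrix force(pos.nrow(), 3);
  double E = noe_pseudo(pos, pair0[0], pair0[1], avg_r6, rexp, err, w, oml, force);
  return List::create(_["energy"] = E, _["forces"] = force);
}

// [[Rcpp::export]]
List cpp_pseudo_j(NumericMatrix pos, IntegerVector quad0, List karplus,
                  double avgJ, double jexp, double err, double w, double oml) {
  NumericMatrix force(pos.nrow(), 3);
  KarplusSpec ks;
  ks.p1 = karplus["p1"]; ks.p2 = karplus["p2"]; ks.p3 = karplus["p3"];
  ks.p4 = karplus["p4"]; ks.p5 = karplus["p5"];
  ks.p6rad = as<double>(karplus["p6"]) * M_PI / 180.0;
  ks.dchi = as<std::vector<double> >(karplus["dchi"]);
  ks.xi = as<std::vector<double> >(karplus["xi"]);
  int q[4] = { quad0[0], quad0[1], quad0[2], quad0[3] };
  double E = j_pseudo(pos, q, ks, avgJ, jexp, err, w, oml, force);
  return List::create(_["energy"] = E, _["forces"] = force);
}

// [[Rcpp::export]]
double cpp_karplus(List karplus, double phi_rad) {
  KarplusSpec ks;
  ks.p1 = karplus["p1"]; ks.p2 = karplus["p2"]; ks.p3 = karplus["p3"];
  ks.p4 = karplus["p4"]; ks.p5 = karplus["p5"];
  ks.p6rad = as<double>(karplus["p6"]) * M_PI / 180.0;
  ks.dchi = as<std::vector<double> >(karplus["dchi"]);
  ks.xi = as<std::vector<double> >(karplus["xi"]);
  return karplus_eval(ks, phi_rad, 0);
}

// ---------------------------------------------------------------------------
// full MD run
//
// restraints: list(
//   rdc = list(idx m x 2, coef m, target m x 9 (row-major), weight m),
//   noe = list(idx m x 2, rexp, err, weight),
//   j3  = list(idx m x 4, jexp, err, weight, p1..p6 per restraint,
//              sub_ptr (m+1 offsets), sub_dchi, sub_xi))
// config: list(dt, nsteps, temperature, tau_t, snap_every, tau_mem,
//              ramp_steps, field_axis)
//
// Memory accumulators start from the observables of the initial structure.

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                List ff, List restraints, List config) {
  int n = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0);
  double dt = config["dt"];
  int nsteps = config["nsteps"];
  double T0 = config["temperature"];
  double tau_t = config["tau_t"];
  int snap_every = config["snap_every"];
  double tau_mem = config["tau_mem"];
  int ramp_steps = config["ramp_steps"];
  double fcap = config["force_cap"];
  NumericVector faxis = config["field_axis"];
  double lambda = std::exp(-dt / tau_mem);
  double oml = 1.0 - lambda;

  // unpack restraints
  List rrdc = restraints["rdc"], rnoe = restraints["noe"], rj = restraints["j3"];
  IntegerMatrix rdc_idx = rrdc["idx"];
  NumericVector rdc_coef = rrdc["coef"], rdc_w = rrdc["weight"];
  NumericMatrix rdc_tgt = rrdc["target"];
  int n_rdc = rdc_idx.nrow();
  std::vector<std::array<std::array<double, 3>, 3> > rdc_avg(n_rdc);

  IntegerMatrix noe_idx = rnoe["idx"];
  NumericVector noe_rexp = rnoe["rexp"], noe_err = rnoe["err"], noe_w = rnoe["weight"];
  int n_noe = noe_idx.nrow();
  std::vector<double> noe_avg(n_noe);

  IntegerMatrix j_idx = rj["idx"];
  NumericVector j_exp = rj["jexp"], j_err = rj["err"], j_w = rj["weight"];
  NumericVector jp1 = rj["p1"], jp2 = rj["p2"], jp3 = rj["p3"],
    jp4 = rj["p4"], jp5 = rj["p5"], jp6 = rj["p6"];
  IntegerVector sub_ptr = rj["sub_ptr"];
  NumericVector sub_dchi = rj["sub_dchi"], sub_xi = rj["sub_xi"];
  int n_j = j_idx.nrow();
  std::vector<KarplusSpec> jks(n_j);
  for (int t = 0; t < n_j; ++t) {
    jks[t].p1 = jp1[t]; jks[t].p2 = jp2[t]; jks[t].p3 = jp3[t];
    jks[t].p4 = jp4[t]; jks[t].p5 = jp5[t];
    jks[t].p6rad = jp6[t] * M_PI / 180.0;
    for (int s = sub_ptr[t]; s < sub_ptr[t + 1]; ++s) {
      jks[t].dchi.push_back(sub_dchi[s]);
      jks[t].xi.push_back(sub_xi[s]);
    }
  }
  std::vector<double> j_avg(n_j);

  // initialize memory averages from the start structure
  for (int t = 0; t < n_rdc; ++t) {
    V3 dv = getrow(pos, rdc_idx(t, 1)) - getrow(pos, rdc_idx(t, 0));
    double D[3][3];
    dip_tensor(dv, norm(dv), rdc_coef[t], D);
    for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) rdc_avg[t][a][b] = D[a][b];
  }
  for (int t = 0; t < n_noe; ++t) {
    V3 dv = getrow(pos, noe_idx(t, 1)) - getrow(pos, noe_idx(t, 0));
    noe_avg[t] = std::pow(norm(dv), -6.0);
  }
  for (int t = 0; t < n_j; ++t) {
    V3 g[4];
    double phi = dihedral_grad(pos, j_idx(t, 0), j_idx(t, 1), j_idx(t, 2), j_idx(t, 3), g, false);
    j_avg[t] = karplus_eval(jks[t], phi, 0);
  }

  int n_snap = nsteps / snap_every;
  NumericVector traj(n_snap * n * 3);
  traj.attr("dim") = IntegerVector::create(n_snap, n, 3);
  NumericVector snap_time(n_snap);
  int n_diag_cols = 6;
  NumericMatrix diag(n_snap, n_diag_cols);
  colnames(diag) = CharacterVector::create("temperature", "e_pot", "e_kin",
                                           "e_pseudo_rdc", "e_pseudo_noe", "e_pseudo_j");
  NumericMatrix obs_rdc(n_snap, n_rdc), obs_noe(n_snap, n_noe), obs_j(n_snap, n_j);
  double bx = faxis[0], by = faxis[1], bz = faxis[2];

  NumericMatrix force(n, 3);
  double br[5];
  double e_rdc = 0, e_noe = 0, e_j = 0;
  double tsum = 0.0;
  int ndof = std::max(3 * n - 3, 1);

  // evaluates all forces at current pos; updates memory averages when advance=true
  auto eval_forces = [&](int step, bool advance) {
    std::fill(force.begin(), force.end(), 0.0);
    ff_eval(pos, ff, force, br);
    double ramp = ramp_steps > 0 ? std::min(1.0, (double)step / ramp_steps) : 1.0;
    e_rdc = e_noe = e_j = 0.0;
    for (int t = 0; t < n_rdc; ++t) {
      int i = rdc_idx(t, 0), j = rdc_idx(t, 1);
      V3 dv = getrow(pos, j) - getrow(pos, i);
      double D[3][3];
      dip_tensor(dv, norm(dv), rdc_coef[t], D);
      if (advance)
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b)
            rdc_avg[t][a][b] = oml * D[a][b] + lambda * rdc_avg[t][a][b];
      double A[3][3], Tg[3][3];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          A[a][b] = rdc_avg[t][a][b];
          Tg[a][b] = rdc_tgt(t, 3 * a + b);
        }
      e_rdc += rdc_pseudo(pos, i, j, rdc_coef[t], A, Tg, ramp * rdc_w[t], oml, force, fcap);
    }
    for (int t = 0; t < n_noe; ++t) {
      int i = noe_idx(t, 0), j = noe_idx(t, 1);
      V3 dv = getrow(pos, j) - getrow(pos, i);
      double s = std::pow(norm(dv), -6.0);
      if (advance) noe_avg[t] = oml * s + lambda * noe_avg[t];
      e_noe += noe_pseudo(pos, i, j, noe_avg[t], noe_rexp[t], noe_err[t],
                          ramp * noe_w[t], oml, force, fcap);
    }
    for (int t = 0; t < n_j; ++t) {
      int q[4] = { j_idx(t, 0), j_idx(t, 1), j_idx(t, 2), j_idx(t, 3) };
      V3 g[4];
      double phi = dihedral_grad(pos, q[0], q[1], q[2], q[3], g, false);
      double Jc = karplus_eval(jks[t], phi, 0);
      if (advance) j_avg[t] = oml * Jc + lambda * j_avg[t];
      e_j += j_pseudo(pos, q, jks[t], j_avg[t], j_exp[t], j_err[t],
                      ramp * j_w[t], oml, force, fcap);
    }
  };

  eval_forces(0, false);
  int isnap = 0;
  for (int step = 1; step <= nsteps; ++step) {
    // velocity Verlet
    for (int a = 0; a < n; ++a) {
      double inv2m = 0.5 * dt * KCAL_TO_INTERNAL / mass[a];
      vel(a, 0) += inv2m * force(a, 0);
      vel(a, 1) += inv2m * force(a, 1);
      vel(a, 2) += inv2m * force(a, 2);
      pos(a, 0) += dt * vel(a, 0);
      pos(a, 1) += dt * vel(a, 1);
      pos(a, 2) += dt * vel(a, 2);
    }
    eval_forces(step, true);
    double ke_int = 0.0;
    for (int a = 0; a < n; ++a) {
      double inv2m = 0.5 * dt * KCAL_TO_INTERNAL / mass[a];
      vel(a, 0) += inv2m * force(a, 0);
      vel(a, 1) += inv2m * force(a, 1);
      vel(a, 2) += inv2m * force(a, 2);
      ke_int += 0.5 * mass[a] * (vel(a, 0) * vel(a, 0) + vel(a, 1) * vel(a, 1) +
                                 vel(a, 2) * vel(a, 2));
    }
    double ke_kcal = ke_int / KCAL_TO_INTERNAL;
    double T_inst = 2.0 * ke_kcal / (ndof * KB_KCAL);
    if (tau_t > 0.0 && T_inst > 1e-12) {
      double sc = std::sqrt(1.0 + (dt / tau_t) * (T0 / T_inst - 1.0));
      sc = std::max(0.8, std::min(1.25, sc));
      for (int a = 0; a < n; ++a) {
        vel(a, 0) *= sc; vel(a, 1) *= sc; vel(a, 2) *= sc;
      }
      ke_kcal *= sc * sc;
      T_inst *= sc * sc;
    }
    tsum += T_inst;
    if (!R_finite(ke_kcal)) stop("integration aborted: non-finite kinetic energy at step %d", step);

    if (step % snap_every == 0 && isnap < n_snap) {
      for (int a = 0; a < n; ++a) {
        traj[isnap + n_snap * a] = pos(a, 0);
        traj[isnap + n_snap * (a + n)] = pos(a, 1);
        traj[isnap + n_snap * (a + 2 * n)] = pos(a, 2);
      }
      snap_time[isnap] = step * dt;
      diag(isnap, 0) = T_inst;
      diag(isnap, 1) = br[0] + br[1] + br[2] + br[3] + br[4];
      diag(isnap, 2) = ke_kcal;
      diag(isnap, 3) = e_rdc;
      diag(isnap, 4) = e_noe;
      diag(isnap, 5) = e_j;
      for (int t = 0; t < n_rdc; ++t) {
        // field-direction component of the memory-averaged tensor
        double v = 0.0;
        double b[3] = { bx, by, bz };
        for (int a = 0; a < 3; ++a)
          for (int b2 = 0; b2 < 3; ++b2) v += b[a] * rdc_avg[t][a][b2] * b[b2];
        obs_rdc(isnap, t) = v;
      }
      for (int t = 0; t < n_noe; ++t) obs_noe(isnap, t) = std::pow(noe_avg[t], -1.0 / 6.0);
      for (int t = 0; t < n_j; ++t) obs_j(isnap, t) = j_avg[t];
      ++isnap;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["coords"] = traj, _["times"] = snap_time, _["diagnostics"] = diag,
    _["obs_rdc"] = obs_rdc, _["obs_noe"] = obs_noe, _["obs_j"] = obs_j,
    _["final_pos"] = pos, _["final_vel"] = vel,
    _["mean_temperature"] = tsum / nsteps);
}
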