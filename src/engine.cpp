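// Molecular-mechanics engine: reduced force field (harmonic bonds/angles,
// cosine torsions, LJ + shifted-force Coulomb with Verlet neighbour lists)
// and a velocity-Verlet integrator with single Nose-Hoover thermostat,
// optional Monte-Carlo volume moves (equilibration barostat) and a
// Gaussian-enveloped oscillating electric-field pulse train.
//
// Units: length A, energy kcal/mol, mass amu, charge e, time fs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

static const double ACC = 4.184e-4;     // (kcal/mol/A)/amu -> A/fs^2
static const double KB = 0.0019872042586;

struct Topology {
  int n;
  std::vector<double> mass, charge, eps, sig, lambda;
  std::vector<int> mol;
  std::vector<char> is_cb, is_ow, fmask;
  // bonds
  std::vector<int> bi, bj; std::vector<double> bk, br0;
  // angles
  std::vector<int> ai, aj, ak; std::vector<double> akf, ath0;
  // torsions
  std::vector<int> ti, tj, tk, tl; std::vector<double> tA, tn, td;
  // exclusions (includes 1-4), per-atom sorted
  std::vector<std::vector<int>> excl;
  // 1-4 pairs
  std::vector<int> p14i, p14j;
  double s14ee, s14lj;
  double cutoff, coulomb;
};

struct Field {
  bool on = false;
  double E0 = 0, sigma = 1000, interval = 35000, omega = 0, t0 = 0;
  int n_pulses = 0;
  double px = 0, py = 0, pz = 1;
};

static inline double min_image(double d, double L) {
  if (L > 0) d -= L * std::nearbyint(d / L);
  return d;
}

static Topology parse_top(const List& top) {
  Topology T;
  NumericVector mass = top["mass"], charge = top["charge"],
    eps = top["eps"], sig = top["sig"], lambda = top["lambda"];
  IntegerVector mol = top["mol"];
  LogicalVector is_cb = top["is_cb"], is_ow = top["is_ow"];
  T.n = mass.size();
  T.mass.assign(mass.begin(), mass.end());
  T.charge.assign(charge.begin(), charge.end());
  T.eps.assign(eps.begin(), eps.end());
  T.sig.assign(sig.begin(), sig.end());
  T.lambda.assign(lambda.begin(), lambda.end());
  T.mol.assign(mol.begin(), mol.end());
  T.is_cb.resize(T.n); T.is_ow.resize(T.n);
  for (int i = 0; i < T.n; ++i) { T.is_cb[i] = is_cb[i]; T.is_ow[i] = is_ow[i]; }
  IntegerMatrix B = top["bonds"];      // i j (0-based), cols 3,4 in k,r0
  NumericMatrix Bp = top["bond_par"];
  for (int r = 0; r < B.nrow(); ++r) {
    T.bi.push_back(B(r,0)); T.bj.push_back(B(r,1));
    T.bk.push_back(Bp(r,0)); T.br0.push_back(Bp(r,1));
  }
  IntegerMatrix A = top["angles"]; NumericMatrix Ap = top["angle_par"];
  for (int r = 0; r < A.nrow(); ++r) {
    T.ai.push_back(A(r,0)); T.aj.push_back(A(r,1)); T.ak.push_back(A(r,2));
    T.akf.push_back(Ap(r,0)); T.ath0.push_back(Ap(r,1));
  }
  IntegerMatrix D = top["torsions"]; NumericMatrix Dp = top["torsion_par"];
  for (int r = 0; r < D.nrow(); ++r) {
    T.ti.push_back(D(r,0)); T.tj.push_back(D(r,1));
    T.tk.push_back(D(r,2)); T.tl.push_back(D(r,3));
    T.tA.push_back(Dp(r,0)); T.tn.push_back(Dp(r,1)); T.td.push_back(Dp(r,2));
  }
  IntegerMatrix E = top["excl"];
  T.excl.resize(T.n);
  for (int r = 0; r < E.nrow(); ++r) {
    T.excl[E(r,0)].push_back(E(r,1));
    T.excl[E(r,1)].push_back(E(r,0));
  }
  for (auto& v : T.excl) std::sort(v.begin(), v.end());
  IntegerMatrix P = top["pair14"];
  for (int r = 0; r < P.nrow(); ++r) {
    T.p14i.push_back(P(r,0)); T.p14j.push_back(P(r,1));
  }
  NumericVector s14 = top["scale14"];
  T.s14ee = s14[0]; T.s14lj = s14[1];
  T.cutoff = as<double>(top["cutoff"]);
  T.coulomb = as<double>(top["coulomb"]);
  // field mask (atoms feeling the external field)
  LogicalVector fm = top["field_mask"];
  T.fmask.resize(T.n);
  for (int i = 0; i < T.n; ++i) T.fmask[i] = fm[i];
  return T;
}

static inline bool excluded(const Topology& T, int i, int j) {
  const std::vector<int>& e = T.excl[i];
  return std::binary_search(e.begin(), e.end(), j);
}

// ---------------- neighbour list ----------------
struct NbList {
  std::vector<int> pi, pj;
  std::vector<double> qq, eij4, sij2, fc, esh;
  std::vector<double> ref;   // positions at build time
  double skin = 2.0;
  void build(const Topology& T, const std::vector<double>& x, double L) {
    pi.clear(); pj.clear(); qq.clear(); eij4.clear(); sij2.clear();
    fc.clear(); esh.clear();
    double rc = T.cutoff + skin, rc2 = rc * rc;
    int n = T.n;
    // cell list for O(n) build
    if (L > 0 && L / rc >= 3) {
      int nc = (int)std::floor(L / rc);
      double cw = L / nc;
      std::vector<std::vector<int>> cells(nc * nc * nc);
      std::vector<int> ci(n), cj(n), ck(n);
      for (int i = 0; i < n; ++i) {
        double xx = x[3*i] - L * std::floor(x[3*i] / L);
        double yy = x[3*i+1] - L * std::floor(x[3*i+1] / L);
        double zz = x[3*i+2] - L * std::floor(x[3*i+2] / L);
        int a = std::min(nc-1, (int)(xx / cw));
        int b = std::min(nc-1, (int)(yy / cw));
        int c = std::min(nc-1, (int)(zz / cw));
        ci[i] = a; cj[i] = b; ck[i] = c;
        cells[(a*nc + b)*nc + c].push_back(i);
      }
      for (int i = 0; i < n; ++i) {
        for (int da = -1; da <= 1; ++da)
        for (int db = -1; db <= 1; ++db)
        for (int dc = -1; dc <= 1; ++dc) {
          int a = (ci[i] + da + nc) % nc;
          int b = (cj[i] + db + nc) % nc;
          int c = (ck[i] + dc + nc) % nc;
          for (int j : cells[(a*nc + b)*nc + c]) {
            if (j <= i) continue;
            double dx = min_image(x[3*i]-x[3*j], L);
            double dy = min_image(x[3*i+1]-x[3*j+1], L);
            double dz = min_image(x[3*i+2]-x[3*j+2], L);
            if (dx*dx + dy*dy + dz*dz < rc2 && !excluded(T, i, j))
              add_pair(T, i, j);
          }
        }
      }
    } else {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = min_image(x[3*i]-x[3*j], L);
          double dy = min_image(x[3*i+1]-x[3*j+1], L);
          double dz = min_image(x[3*i+2]-x[3*j+2], L);
          if (dx*dx + dy*dy + dz*dz < rc2 && !excluded(T, i, j))
            add_pair(T, i, j);
        }
    }
    ref = x;
  }
  void add_pair(const Topology& T, int i, int j) {
    pi.push_back(i); pj.push_back(j);
    qq.push_back(T.coulomb * T.charge[i] * T.charge[j]);
    double e = std::sqrt(T.eps[i] * T.eps[j]);
    // hydrophobicity scaling between side-chain CB carbons and water oxygen
    if ((T.is_cb[i] && T.is_ow[j]) || (T.is_ow[i] && T.is_cb[j]))
      e *= (T.is_cb[i] ? T.lambda[i] : T.lambda[j]);
    double s = 0.5 * (T.sig[i] + T.sig[j]);
    double rc = T.cutoff;
    double t = (s * s) / (rc * rc);
    double src6 = t * t * t, src12 = src6 * src6;
    eij4.push_back(4.0 * e);
    sij2.push_back(s * s);
    fc.push_back(e > 0 ? 24.0 * e * (2.0 * src12 - src6) / rc : 0.0);
    esh.push_back(e > 0 ? 4.0 * e * (src12 - src6) : 0.0);
  }
  bool stale(const std::vector<double>& x, double L) const {
    double lim = 0.25 * skin * skin;  // (skin/2)^2
    for (size_t i = 0; i < x.size(); i += 3) {
      double dx = min_image(x[i]-ref[i], L), dy = min_image(x[i+1]-ref[i+1], L),
             dz = min_image(x[i+2]-ref[i+2], L);
      if (dx*dx + dy*dy + dz*dz > lim) return true;
    }
    return false;
  }
};

// ---------------- energy and forces ----------------
struct EnergyTerms {
  double bond = 0, angle = 0, torsion = 0, lj = 0, coul = 0;
  double total() const { return bond + angle + torsion + lj + coul; }
};

static EnergyTerms compute_ef(const Topology& T, const std::vector<double>& x,
                              double L, NbList& nb, std::vector<double>& f,
                              bool use_nb_list = true) {
  EnergyTerms E;
  int n = T.n;
  f.assign(3 * n, 0.0);

  // bonds: E = k/2 (r - r0)^2
  for (size_t b = 0; b < T.bi.size(); ++b) {
    int i = T.bi[b], j = T.bj[b];
    double dx = min_image(x[3*i]-x[3*j], L);
    double dy = min_image(x[3*i+1]-x[3*j+1], L);
    double dz = min_image(x[3*i+2]-x[3*j+2], L);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - T.br0[b];
    E.bond += 0.5 * T.bk[b] * dr * dr;
    double fr = -T.bk[b] * dr / r;
    f[3*i] += fr*dx; f[3*i+1] += fr*dy; f[3*i+2] += fr*dz;
    f[3*j] -= fr*dx; f[3*j+1] -= fr*dy; f[3*j+2] -= fr*dz;
  }

  // angles: E = k/2 (theta - theta0)^2
  for (size_t a = 0; a < T.ai.size(); ++a) {
    int i = T.ai[a], j = T.aj[a], k = T.ak[a];
    double rij[3] = { min_image(x[3*i]-x[3*j], L), min_image(x[3*i+1]-x[3*j+1], L),
                      min_image(x[3*i+2]-x[3*j+2], L) };
    double rkj[3] = { min_image(x[3*k]-x[3*j], L), min_image(x[3*k+1]-x[3*j+1], L),
                      min_image(x[3*k+2]-x[3*j+2], L) };
    double r1 = std::sqrt(rij[0]*rij[0]+rij[1]*rij[1]+rij[2]*rij[2]);
    double r2 = std::sqrt(rkj[0]*rkj[0]+rkj[1]*rkj[1]+rkj[2]*rkj[2]);
    double cs = (rij[0]*rkj[0]+rij[1]*rkj[1]+rij[2]*rkj[2]) / (r1*r2);
    cs = std::max(-1.0, std::min(1.0, cs));
    double th = std::acos(cs);
    double dth = th - T.ath0[a];
    E.angle += 0.5 * T.akf[a] * dth * dth;
    double sn = std::sqrt(1.0 - cs*cs);
    if (sn < 1e-8) sn = 1e-8;
    double coef = T.akf[a] * dth / sn;
    for (int d = 0; d < 3; ++d) {
      double fi = coef * (rkj[d]/(r1*r2) - cs*rij[d]/(r1*r1));
      double fk = coef * (rij[d]/(r1*r2) - cs*rkj[d]/(r2*r2));
      f[3*i+d] += fi;
      f[3*k+d] += fk;
      f[3*j+d] -= fi + fk;
    }
  }

  // torsions: E = A (1 + cos(n phi - delta))
  for (size_t t = 0; t < T.ti.size(); ++t) {
    int i = T.ti[t], j = T.tj[t], k = T.tk[t], l = T.tl[t];
    double b1[3] = { min_image(x[3*j]-x[3*i], L), min_image(x[3*j+1]-x[3*i+1], L),
                     min_image(x[3*j+2]-x[3*i+2], L) };
    double b2[3] = { min_image(x[3*k]-x[3*j], L), min_image(x[3*k+1]-x[3*j+1], L),
                     min_image(x[3*k+2]-x[3*j+2], L) };
    double b3[3] = { min_image(x[3*l]-x[3*k], L), min_image(x[3*l+1]-x[3*k+1], L),
                     min_image(x[3*l+2]-x[3*k+2], L) };
    double n1[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                     b1[0]*b2[1]-b1[1]*b2[0] };
    double n2[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                     b2[0]*b3[1]-b2[1]*b3[0] };
    double n1s = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
    double n2s = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
    double b2n = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    if (n1s < 1e-12 || n2s < 1e-12) continue;
    double m1[3] = { n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2],
                     n1[0]*b2[1]-n1[1]*b2[0] };
    double xx = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    double yy = (m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2]) / b2n;
    // phi in the IUPAC sign convention (matches the R-side .dihedral)
    double phi_std = std::atan2(yy, xx);
    double phi = -phi_std;
    double arg = T.tn[t] * phi - T.td[t];
    E.torsion += T.tA[t] * (1.0 + std::cos(arg));
    // dE/dphi_std (the praxeolitic angle used by the force formulas)
    double dVdphi = T.tA[t] * T.tn[t] * std::sin(arg);
    // Blondel-Karplus gradients of phi_std w.r.t. the four positions
    double b1b2 = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (b2n*b2n);
    double b3b2 = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (b2n*b2n);
    double g1[3], g4[3], g2[3], g3[3];
    for (int d = 0; d < 3; ++d) {
      g1[d] =  b2n / n1s * n1[d];
      g4[d] = -b2n / n2s * n2[d];
    }
    for (int d = 0; d < 3; ++d) {
      g2[d] = -(1.0 + b1b2) * g1[d] + b3b2 * g4[d];
      g3[d] = b1b2 * g1[d] - (1.0 + b3b2) * g4[d];
    }
    for (int d = 0; d < 3; ++d) {
      f[3*i+d] -= dVdphi * g1[d];
      f[3*j+d] -= dVdphi * g2[d];
      f[3*k+d] -= dVdphi * g3[d];
      f[3*l+d] -= dVdphi * g4[d];
    }
  }

  // nonbonded: LJ shifted-potential, Coulomb shifted-force
  double rc = T.cutoff, rc2 = rc * rc;
  auto nbterm = [&](int i, int j, double qqij, double eij, double sij,
                    double see, double slj) {
    double dx = min_image(x[3*i]-x[3*j], L);
    double dy = min_image(x[3*i+1]-x[3*j+1], L);
    double dz = min_image(x[3*i+2]-x[3*j+2], L);
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= rc2) return;
    double r = std::sqrt(r2);
    double fr = 0.0;
    if (eij > 0) {
      // shifted-force LJ: zero energy and zero force at the cutoff
      double tt = sij * sij / r2;
      double sr6 = tt * tt * tt;
      double sr12 = sr6 * sr6;
      double tc = sij * sij / rc2;
      double src6 = tc * tc * tc;
      double src12 = src6 * src6;
      double fc = 24.0 * eij * (2.0 * src12 - src6) / rc;  // |F|(rc)
      E.lj += slj * 4.0 * eij * (sr12 - sr6 - (src12 - src6))
            + slj * fc * (r - rc);
      fr += slj * (24.0 * eij * (2.0 * sr12 - sr6) / r2 - fc / r);
    }
    if (qqij != 0) {
      // shifted-force: E = qq (1/r - 1/rc + (r - rc)/rc^2)
      E.coul += see * qqij * (1.0/r - 1.0/rc + (r - rc)/rc2);
      fr += see * qqij * (1.0/r2 - 1.0/rc2) / r;
    }
    f[3*i] += fr*dx; f[3*i+1] += fr*dy; f[3*i+2] += fr*dz;
    f[3*j] -= fr*dx; f[3*j+1] -= fr*dy; f[3*j+2] -= fr*dz;
  };

  if (use_nb_list) {
    const double rcinv = 1.0 / rc, rc2inv = 1.0 / rc2;
    for (size_t p = 0; p < nb.pi.size(); ++p) {
      int i = nb.pi[p], j = nb.pj[p];
      double dx = min_image(x[3*i]-x[3*j], L);
      double dy = min_image(x[3*i+1]-x[3*j+1], L);
      double dz = min_image(x[3*i+2]-x[3*j+2], L);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      double fr = 0.0;
      double e4 = nb.eij4[p];
      if (e4 > 0) {
        double t = nb.sij2[p] / r2;
        double sr6 = t * t * t, sr12 = sr6 * sr6;
        E.lj += e4 * (sr12 - sr6) - nb.esh[p] + nb.fc[p] * (r - rc);
        fr += 6.0 * e4 * (2.0 * sr12 - sr6) / r2 - nb.fc[p] / r;
      }
      double qqij = nb.qq[p];
      if (qqij != 0) {
        E.coul += qqij * (1.0/r - rcinv + (r - rc) * rc2inv);
        fr += qqij * (1.0/r2 - rc2inv) / r;
      }
      f[3*i] += fr*dx; f[3*i+1] += fr*dy; f[3*i+2] += fr*dz;
      f[3*j] -= fr*dx; f[3*j+1] -= fr*dy; f[3*j+2] -= fr*dz;
    }
  }
  // 1-4 scaled interactions
  for (size_t p = 0; p < T.p14i.size(); ++p) {
    int i = T.p14i[p], j = T.p14j[p];
    double e = std::sqrt(T.eps[i] * T.eps[j]);
    double s = 0.5 * (T.sig[i] + T.sig[j]);
    nbterm(i, j, T.coulomb * T.charge[i] * T.charge[j], e, s, T.s14ee, T.s14lj);
  }
  return E;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, List top, double box) {
  Topology T = parse_top(top);
  std::vector<double> x(3 * T.n);
  for (int i = 0; i < T.n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = pos(i, d);
  NbList nb;
  nb.build(T, x, box);
  std::vector<double> f;
  EnergyTerms E = compute_ef(T, x, box, nb, f);
  NumericMatrix F(T.n, 3);
  for (int i = 0; i < T.n; ++i)
    for (int d = 0; d < 3; ++d) F(i, d) = f[3*i+d];
  return List::create(
    _["energy"] = E.total(),
    _["terms"] = NumericVector::create(
      _["bond"] = E.bond, _["angle"] = E.angle, _["torsion"] = E.torsion,
      _["lj"] = E.lj, _["coulomb"] = E.coul),
    _["forces"] = F);
}

// field vector at time t (fs); returns scale factor E(t) (internal units)
static inline double field_scalar(const Field& F, double t) {
  if (!F.on || F.E0 == 0) return 0.0;
  double val = 0.0;
  double kf = std::floor((t - F.t0) / F.interval + 0.5);
  for (int dk = -1; dk <= 1; ++dk) {
    double k = kf + dk;
    if (k < 0 || k >= F.n_pulses) continue;
    double tc = F.t0 + k * F.interval;
    double u = (t - tc) / F.sigma;
    double env = std::exp(-0.5 * u * u);
    if (env < 1e-12) continue;
    val += F.E0 * env * std::cos(F.omega * (t - tc));
  }
  return val;
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, List top, double box,
                double dt, int nsteps, int out_stride, int ene_stride,
                List thermo, List field, bool store_vel, int seed) {
  Topology T = parse_top(top);
  int n = T.n;
  std::vector<double> x(3*n), v(3*n), f;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { x[3*i+d] = pos(i,d); v[3*i+d] = vel(i,d); }

  std::string ens = as<std::string>(thermo["ensemble"]);
  double T0 = as<double>(thermo["temperature"]);
  double tau = as<double>(thermo["tau"]);          // fs
  double P0 = as<double>(thermo["pressure"]);      // kcal/mol/A^3
  int baro_stride = as<int>(thermo["baro_stride"]);
  double L = box;
  bool nvt = (ens == "NVT" || ens == "NPT");
  bool npt = (ens == "NPT");
  int nf = 3 * n - 3;
  double Q = nf * KB * T0 * tau * tau;  // NH coupling mass
  double xi = 0.0;                      // NH velocity-like variable
  double xis = 0.0;                     // NH "position" (for conserved qty)

  Field F;
  F.on = as<bool>(field["on"]);
  if (F.on) {
    F.E0 = as<double>(field["E0"]);
    F.sigma = as<double>(field["sigma"]);
    F.interval = as<double>(field["interval"]);
    F.omega = as<double>(field["omega"]);
    F.t0 = as<double>(field["t0"]);
    F.n_pulses = as<int>(field["n_pulses"]);
    NumericVector p = field["pol"];
    F.px = p[0]; F.py = p[1]; F.pz = p[2];
  }
  std::vector<double> work(F.on ? std::max(F.n_pulses, 1) : 1, 0.0);

  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> runif(0.0, 1.0);

  NbList nb;
  nb.build(T, x, L);
  EnergyTerms E = compute_ef(T, x, L, nb, f);

  int nframes = nsteps / out_stride + 1;
  NumericMatrix frames(3 * n, nframes);
  NumericMatrix vels(store_vel ? 3 * n : 1, store_vel ? nframes : 1);
  NumericVector ftimes(nframes);
  int nrec = nsteps / ene_stride + 1;
  NumericMatrix elog(nrec, 8);  // t, Ekin, Epot, T, bond, nb(lj+coul), conserved, box
  int fidx = 0, eidx = 0;

  auto kinetic = [&]() {
    double ke = 0;
    for (int i = 0; i < n; ++i)
      ke += T.mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
    return 0.5 * ke / ACC;
  };

  auto record_frame = [&](double t) {
    for (int i = 0; i < 3*n; ++i) frames(i, fidx) = x[i];
    if (store_vel) for (int i = 0; i < 3*n; ++i) vels(i, fidx) = v[i];
    ftimes[fidx] = t;
    ++fidx;
  };
  auto record_energy = [&](double t) {
    double ke = kinetic();
    double cons = ke + E.total();
    if (nvt) cons += 0.5 * Q * xi * xi + nf * KB * T0 * xis;
    elog(eidx, 0) = t; elog(eidx, 1) = ke; elog(eidx, 2) = E.total();
    elog(eidx, 3) = 2.0 * ke / (nf * KB);
    elog(eidx, 4) = E.bond + E.angle + E.torsion;
    elog(eidx, 5) = E.lj + E.coul;
    elog(eidx, 6) = cons;
    elog(eidx, 7) = L;
    ++eidx;
  };

  // add field forces at time t; returns per-atom field force into ff
  auto add_field = [&](double t, std::vector<double>& ff) {
    double Es = field_scalar(F, t);
    if (Es == 0.0) return;
    for (int i = 0; i < n; ++i) {
      if (!T.fmask[i] || T.charge[i] == 0) continue;
      double fq = T.charge[i] * Es;
      ff[3*i]   += fq * F.px;
      ff[3*i+1] += fq * F.py;
      ff[3*i+2] += fq * F.pz;
    }
  };
  auto pulse_index = [&](double t) {
    int k = (int)std::floor((t - F.t0) / F.interval + 0.5);
    if (k < 0) k = 0;
    if (k >= F.n_pulses) k = F.n_pulses - 1;
    return k;
  };

  record_frame(0.0);
  record_energy(0.0);
  if (F.on) add_field(0.0, f);

  std::string status = "ok";
  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;

    if (nvt) {
      // half thermostat (Martyna-Tuckerman split, single NH)
      double ke = kinetic();
      double G = (2.0 * ke - nf * KB * T0) / Q;   // 1/fs^2
      xi += 0.25 * dt * G;
      double s = std::exp(-0.5 * dt * xi);
      for (int i = 0; i < 3*n; ++i) v[i] *= s;
      xis += 0.5 * dt * xi;
      ke *= s * s;
      G = (2.0 * ke - nf * KB * T0) / Q;
      xi += 0.25 * dt * G;
    }

    // velocity Verlet
    for (int i = 0; i < n; ++i) {
      double am = ACC / T.mass[i];
      v[3*i]   += 0.5 * dt * f[3*i] * am;
      v[3*i+1] += 0.5 * dt * f[3*i+1] * am;
      v[3*i+2] += 0.5 * dt * f[3*i+2] * am;
    }
    // field work accumulated with half-step velocities
    if (F.on && F.E0 != 0) {
      double Es = field_scalar(F, t);
      if (Es != 0.0) {
        double w = 0;
        for (int i = 0; i < n; ++i) {
          if (!T.fmask[i] || T.charge[i] == 0) continue;
          double fq = T.charge[i] * Es;
          w += fq * (F.px * v[3*i] + F.py * v[3*i+1] + F.pz * v[3*i+2]);
        }
        work[pulse_index(t)] += w * dt;
      }
    }
    for (int i = 0; i < 3*n; ++i) x[i] += dt * v[i];

    if (nb.stale(x, L)) nb.build(T, x, L);
    E = compute_ef(T, x, L, nb, f);
    add_field(t + dt, f);

    for (int i = 0; i < n; ++i) {
      double am = ACC / T.mass[i];
      v[3*i]   += 0.5 * dt * f[3*i] * am;
      v[3*i+1] += 0.5 * dt * f[3*i+1] * am;
      v[3*i+2] += 0.5 * dt * f[3*i+2] * am;
    }

    if (nvt) {
      double ke = kinetic();
      double G = (2.0 * ke - nf * KB * T0) / Q;
      xi += 0.25 * dt * G;
      double s = std::exp(-0.5 * dt * xi);
      for (int i = 0; i < 3*n; ++i) v[i] *= s;
      xis += 0.5 * dt * xi;
      ke *= s * s;
      G = (2.0 * ke - nf * KB * T0) / Q;
      xi += 0.25 * dt * G;
    }

    // MC volume move (equilibration barostat)
    if (npt && baro_stride > 0 && (step + 1) % baro_stride == 0 && L > 0) {
      double V = L * L * L;
      double lnV = std::log(V) + (runif(rng) - 0.5) * 0.002;
      double Vn = std::exp(lnV);
      double Ln = std::cbrt(Vn);
      double sc = Ln / L;
      // scale molecular centres of mass
      std::vector<double> xn(x);
      int nmol = 0;
      {
        std::vector<double> comx, comy, comz, m;
        std::vector<int> first;
        int cur = -1;
        for (int i = 0; i < n; ++i) {
          if (T.mol[i] != cur) { cur = T.mol[i]; comx.push_back(0); comy.push_back(0);
            comz.push_back(0); m.push_back(0); first.push_back(i); }
          int g = comx.size() - 1;
          comx[g] += T.mass[i] * x[3*i]; comy[g] += T.mass[i] * x[3*i+1];
          comz[g] += T.mass[i] * x[3*i+2]; m[g] += T.mass[i];
        }
        nmol = comx.size();
        cur = -1; int g = -1;
        for (int i = 0; i < n; ++i) {
          if (T.mol[i] != cur) { cur = T.mol[i]; ++g; }
          double cx = comx[g]/m[g], cy = comy[g]/m[g], cz = comz[g]/m[g];
          xn[3*i]   = x[3*i]   + (sc - 1.0) * cx;
          xn[3*i+1] = x[3*i+1] + (sc - 1.0) * cy;
          xn[3*i+2] = x[3*i+2] + (sc - 1.0) * cz;
        }
      }
      NbList nbn; nbn.skin = nb.skin;
      nbn.build(T, xn, Ln);
      std::vector<double> fn;
      EnergyTerms En = compute_ef(T, xn, Ln, nbn, fn);
      double dU = En.total() - E.total();
      double arg = -(dU + P0 * (Vn - V) - (nmol + 1) * KB * T0 * std::log(Vn / V)) / (KB * T0);
      if (std::log(runif(rng) + 1e-300) < arg) {
        x = xn; L = Ln; nb = nbn; f = fn; E = En;
        add_field(t + dt, f);
      }
    }

    if (!std::isfinite(E.total())) { status = "blowup"; break; }

    if ((step + 1) % out_stride == 0 && fidx < nframes) record_frame((step + 1) * dt);
    if ((step + 1) % ene_stride == 0 && eidx < nrec) record_energy((step + 1) * dt);
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix X(n, 3), V(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { X(i,d) = x[3*i+d]; V(i,d) = v[3*i+d]; }
  return List::create(
    _["frames"] = frames, _["vels"] = vels, _["times"] = ftimes,
    _["n_frames"] = fidx,
    _["elog"] = elog, _["n_elog"] = eidx,
    _["work"] = NumericVector(work.begin(), work.end()),
    _["pos"] = X, _["vel"] = V, _["box"] = L,
    _["status"] = status);
}
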