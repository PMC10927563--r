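// Coarse-grained single-chain engine: Wang-Frenkel + Debye-Hueckel +
// harmonic bonds, analytic forces, and a BAOAB Langevin integrator.
// Units: length A, energy kcal/mol, mass Da, time fs, charge e.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// 1 kcal/mol in Da * A^2 / fs^2
static const double KCAL = 4.184e-4;
// Boltzmann constant, kcal/mol/K
static const double KB = 0.0019872041;
// Coulomb constant e^2 * NA / (4 pi eps0), kcal*A/mol per e^2
static const double COULOMB_K = 332.06371;

struct FFTables {
  int n;
  std::vector<int> type;          // bead type index
  std::vector<double> charge;     // per bead, e
  std::vector<double> eps, sig, mu, nu;  // ntype x ntype flattened
  // precomputed per type pair: WF normalization, cutoff^2, sigma^(2mu),
  // rc^(2mu), and a flag for the common (mu = 2, nu = 1) fast path
  std::vector<double> alpha, rc2, sig2mu, rc2mu;
  std::vector<char> fast;
  int ntype;
  double bond_k, bond_r0;
  double dielectric, lambda_d, coulomb_cutoff;
  double box;
  double hard_floor;

  double pair_at(const std::vector<double>& m, int a, int b) const {
    return m[a * ntype + b];
  }

  void precompute() {
    int nt = ntype;
    alpha.assign(nt * nt, 0.0); rc2.assign(nt * nt, 0.0);
    sig2mu.assign(nt * nt, 0.0); rc2mu.assign(nt * nt, 0.0);
    fast.assign(nt * nt, 0);
    for (int k = 0; k < nt * nt; ++k) {
      double s = sig[k], m = mu[k], v = nu[k];
      if (s <= 0) continue;
      double rc = 3.0 * s;
      double rs = std::pow(rc / s, 2.0 * m);
      alpha[k] = 2.0 * v * rs *
        std::pow((1.0 + 2.0 * v) / (2.0 * v * (rs - 1.0)), 2.0 * v + 1.0);
      rc2[k] = rc * rc;
      sig2mu[k] = std::pow(s, 2.0 * m);
      rc2mu[k] = std::pow(rc, 2.0 * m);
      fast[k] = (m == 2.0 && v == 1.0) ? 1 : 0;
    }
  }
};

static inline double min_image(double d, double box) {
  if (box > 0) {
    while (d > 0.5 * box) d -= box;
    while (d < -0.5 * box) d += box;
  }
  return d;
}

// Wang-Frenkel with normalization alpha so that min depth is exactly -eps;
// vanishes identically at rc = 3*sigma.
static inline void wf_pair(double r, double eps, double sigma, double mu,
                           double nu, double& u, double& dudr) {
  double rc = 3.0 * sigma;
  if (r >= rc || eps == 0.0) { u = 0.0; dudr = 0.0; return; }
  double rs = std::pow(rc / sigma, 2.0 * mu);
  double alpha = 2.0 * nu * rs *
    std::pow((1.0 + 2.0 * nu) / (2.0 * nu * (rs - 1.0)), 2.0 * nu + 1.0);
  double A = std::pow(sigma / r, 2.0 * mu) - 1.0;
  double B = std::pow(rc / r, 2.0 * mu) - 1.0;
  double Bp = std::pow(B, 2.0 * nu);
  u = eps * alpha * A * Bp;
  double dA = -2.0 * mu * std::pow(sigma, 2.0 * mu) * std::pow(r, -2.0 * mu - 1.0);
  double dB = -2.0 * mu * std::pow(rc, 2.0 * mu) * std::pow(r, -2.0 * mu - 1.0);
  dudr = eps * alpha * (dA * Bp + A * 2.0 * nu * std::pow(B, 2.0 * nu - 1.0) * dB);
}

// Debye-Hueckel, energy-shifted to zero at the coulomb cutoff.
static inline void dh_pair(double r, double qq, double dielectric,
                           double lambda_d, double rc, double& u, double& dudr) {
  if (r >= rc || qq == 0.0) { u = 0.0; dudr = 0.0; return; }
  double pref = COULOMB_K * qq / dielectric;
  double e_r = pref * std::exp(-r / lambda_d) / r;
  double e_rc = pref * std::exp(-rc / lambda_d) / rc;
  u = e_r - e_rc;
  dudr = -e_r * (1.0 / r + 1.0 / lambda_d);
}

// Total energy and forces; 1-2 bonded pairs excluded from nonbonded terms.
// Returns false (overlap) if any nonbonded distance is below hard_floor.
static bool energy_forces(const FFTables& ff, const std::vector<double>& x,
                          std::vector<double>& f, double& e_bond,
                          double& e_wf, double& e_el) {
  int n = ff.n;
  std::fill(f.begin(), f.end(), 0.0);
  e_bond = e_wf = e_el = 0.0;
  bool ok = true;
  // bonds
  for (int i = 0; i + 1 < n; ++i) {
    double dx = min_image(x[3*i] - x[3*(i+1)], ff.box);
    double dy = min_image(x[3*i+1] - x[3*(i+1)+1], ff.box);
    double dz = min_image(x[3*i+2] - x[3*(i+1)+2], ff.box);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - ff.bond_r0;
    e_bond += ff.bond_k * dr * dr;
    double dudr = 2.0 * ff.bond_k * dr;
    double fac = -dudr / r;
    f[3*i]   += fac * dx; f[3*(i+1)]   -= fac * dx;
    f[3*i+1] += fac * dy; f[3*(i+1)+1] -= fac * dy;
    f[3*i+2] += fac * dz; f[3*(i+1)+2] -= fac * dz;
  }
  // nonbonded
  bool check_floor = ff.hard_floor > 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      int k = ff.type[i] * ff.ntype + ff.type[j];
      double eps = ff.eps[k];
      double qq_pre = ff.charge[i] * ff.charge[j];
      if (eps == 0.0 && qq_pre == 0.0 && !check_floor) continue;
      double dx = min_image(x[3*i] - x[3*j], ff.box);
      double dy = min_image(x[3*i+1] - x[3*j+1], ff.box);
      double dz = min_image(x[3*i+2] - x[3*j+2], ff.box);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (check_floor && r2 < ff.hard_floor * ff.hard_floor) ok = false;
      if (r2 <= 0) continue;
      double u1 = 0, du1 = 0, u2 = 0, du2 = 0;
      double r = -1.0;
      if (eps != 0.0 && r2 < ff.rc2[k]) {
        r = std::sqrt(r2);
        if (ff.fast[k]) {
          // mu = 2, nu = 1: powers of r^-2 only
          double inv2 = 1.0 / r2;
          double s4 = ff.sig2mu[k], c4 = ff.rc2mu[k];
          double A = s4 * inv2 * inv2 - 1.0;
          double B = c4 * inv2 * inv2 - 1.0;
          double ea = eps * ff.alpha[k];
          u1 = ea * A * B * B;
          double dA = -4.0 * s4 * inv2 * inv2 / r;
          double dB = -4.0 * c4 * inv2 * inv2 / r;
          du1 = ea * (dA * B * B + 2.0 * A * B * dB);
        } else {
          double m = ff.mu[k], v = ff.nu[k];
          double A = ff.sig2mu[k] * std::pow(r, -2.0 * m) - 1.0;
          double B = ff.rc2mu[k] * std::pow(r, -2.0 * m) - 1.0;
          double Bp = std::pow(B, 2.0 * v);
          double ea = eps * ff.alpha[k];
          u1 = ea * A * Bp;
          double dA = -2.0 * m * ff.sig2mu[k] * std::pow(r, -2.0 * m - 1.0);
          double dB = -2.0 * m * ff.rc2mu[k] * std::pow(r, -2.0 * m - 1.0);
          du1 = ea * (dA * Bp + A * 2.0 * v * std::pow(B, 2.0 * v - 1.0) * dB);
        }
      }
      double qq = qq_pre;
      if (qq != 0.0 && r2 < ff.coulomb_cutoff * ff.coulomb_cutoff) {
        if (r < 0) r = std::sqrt(r2);
        dh_pair(r, qq, ff.dielectric, ff.lambda_d, ff.coulomb_cutoff, u2, du2);
      }
      if (u1 == 0.0 && u2 == 0.0 && du1 == 0.0 && du2 == 0.0) continue;
      if (r < 0) r = std::sqrt(r2);
      e_wf += u1; e_el += u2;
      double fac = -(du1 + du2) / r;
      f[3*i]   += fac * dx; f[3*j]   -= fac * dx;
      f[3*i+1] += fac * dy; f[3*j+1] -= fac * dy;
      f[3*i+2] += fac * dz; f[3*j+2] -= fac * dz;
    }
  }
  return ok;
}

static FFTables make_tables(const List& ff) {
  FFTables t;
  IntegerVector type = ff["type"];
  NumericVector charge = ff["charge"];
  NumericMatrix eps = ff["eps"], sig = ff["sig"], mu = ff["mu"], nu = ff["nu"];
  t.n = type.size();
  t.ntype = eps.nrow();
  t.type.assign(type.begin(), type.end());
  t.charge.assign(charge.begin(), charge.end());
  auto flat = [&](NumericMatrix m) {
    std::vector<double> v(t.ntype * t.ntype);
    for (int i = 0; i < t.ntype; ++i)
      for (int j = 0; j < t.ntype; ++j) v[i * t.ntype + j] = m(i, j);
    return v;
  };
  t.eps = flat(eps); t.sig = flat(sig); t.mu = flat(mu); t.nu = flat(nu);
  t.bond_k = ff["bond_k"]; t.bond_r0 = ff["bond_r0"];
  t.dielectric = ff["dielectric"]; t.lambda_d = ff["lambda_d"];
  t.coulomb_cutoff = ff["coulomb_cutoff"];
  t.box = ff["box"]; t.hard_floor = ff["hard_floor"];
  t.precompute();
  return t;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, List ff) {
  FFTables t = make_tables(ff);
  int n = coords.nrow();
  if (n != t.n) stop("coords/sequence length mismatch");
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = coords(i, k);
  double eb, ew, ee;
  bool ok = energy_forces(t, x, f, eb, ew, ee);
  NumericMatrix fout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) fout(i, k) = f[3*i+k];
  return List::create(_["energy"] = eb + ew + ee, _["bond"] = eb,
                      _["wf"] = ew, _["elec"] = ee, _["forces"] = fout,
                      _["overlap"] = !ok);
}

// [[Rcpp::export]]
NumericVector cpp_wf_energy(NumericVector r, double eps, double sigma,
                            double mu, double nu) {
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i) {
    double u, du;
    wf_pair(r[i], eps, sigma, mu, nu, u, du);
    out[i] = u;
  }
  return out;
}

// BAOAB Langevin integrator. Saves coordinates (and per-frame potential and
// kinetic energies) every save_every steps after nsteps_equil steps.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix coords0, NumericVector mass, List ff,
                      double dt, double temperature, double gamma_fs,
                      double nsteps_equil, double nsteps_prod,
                      double save_every, int seed, double blowup_bond) {
  FFTables t = make_tables(ff);
  int n = coords0.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n), m(n);
  for (int i = 0; i < n; ++i) {
    m[i] = mass[i];
    for (int k = 0; k < 3; ++k) x[3*i+k] = coords0(i, k);
  }
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  double kT = KB * temperature * KCAL;  // Da A^2 / fs^2
  // Maxwell-Boltzmann initial velocities
  for (int i = 0; i < n; ++i) {
    double s = std::sqrt(kT / m[i]);
    for (int k = 0; k < 3; ++k) v[3*i+k] = s * gauss(rng);
  }
  double c1 = std::exp(-gamma_fs * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);

  double eb, ew, ee;
  energy_forces(t, x, f, eb, ew, ee);

  long long total = (long long)(nsteps_equil + nsteps_prod);
  long long equil = (long long)nsteps_equil;
  long long save = (long long)save_every;
  int nframes = (int)(((long long)nsteps_prod) / save);
  NumericVector frames(std::max(nframes, 0) * n * 3);
  NumericVector epot(std::max(nframes, 0)), ekin(std::max(nframes, 0));
  int fi = 0;

  for (long long step = 1; step <= total; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i) {
      double a = 0.5 * dt * KCAL / m[i];
      for (int k = 0; k < 3; ++k) v[3*i+k] += a * f[3*i+k];
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O: Ornstein-Uhlenbeck
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(kT / m[i]);
      for (int k = 0; k < 3; ++k)
        v[3*i+k] = c1 * v[3*i+k] + c2 * s * gauss(rng);
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // recompute forces, B: half kick
    energy_forces(t, x, f, eb, ew, ee);
    for (int i = 0; i < n; ++i) {
      double a = 0.5 * dt * KCAL / m[i];
      for (int k = 0; k < 3; ++k) v[3*i+k] += a * f[3*i+k];
    }

    if (step % 10000 == 0) {
      for (int i = 0; i + 1 < n; ++i) {
        double dx = x[3*i] - x[3*(i+1)], dy = x[3*i+1] - x[3*(i+1)+1],
               dz = x[3*i+2] - x[3*(i+1)+2];
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (r > blowup_bond)
          stop("bond length %.1f A exceeds blow-up threshold; reduce the timestep", r);
      }
    }
    if (step > equil && (step - equil) % save == 0 && fi < nframes) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          frames[(size_t)fi * n * 3 + (size_t)i * 3 + k] = x[3*i+k];
      epot[fi] = eb + ew + ee;
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) ke += 0.5 * m[i] * v[3*i+k] * v[3*i+k];
      ekin[fi] = ke / KCAL;  // kcal/mol
      ++fi;
    }
  }
  frames.attr("dim") = IntegerVector::create(3, n, nframes);
  return List::create(_["frames"] = frames, _["epot"] = epot,
                      _["ekin"] = ekin, _["nframes"] = fi);
}

// NVE velocity-Verlet (gamma -> 0 limit check).
// [[Rcpp::export]]
List cpp_run_nve(NumericMatrix coords0, NumericMatrix vel0, NumericVector mass,
                 List ff, double dt, double nsteps, double save_every) {
  FFTables t = make_tables(ff);
  int n = coords0.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n), m(n);
  for (int i = 0; i < n; ++i) {
    m[i] = mass[i];
    for (int k = 0; k < 3; ++k) {
      x[3*i+k] = coords0(i, k);
      v[3*i+k] = vel0(i, k);
    }
  }
  double eb, ew, ee;
  energy_forces(t, x, f, eb, ew, ee);
  long long total = (long long)nsteps, save = (long long)save_every;
  int nframes = (int)(total / save);
  NumericVector etot(nframes);
  int fi = 0;
  for (long long step = 1; step <= total; ++step) {
    for (int i = 0; i < n; ++i) {
      double a = 0.5 * dt * KCAL / m[i];
      for (int k = 0; k < 3; ++k) v[3*i+k] += a * f[3*i+k];
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += dt * v[i];
    energy_forces(t, x, f, eb, ew, ee);
    for (int i = 0; i < n; ++i) {
      double a = 0.5 * dt * KCAL / m[i];
      for (int k = 0; k < 3; ++k) v[3*i+k] += a * f[3*i+k];
    }
    if (step % save == 0 && fi < nframes) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) ke += 0.5 * m[i] * v[3*i+k] * v[3*i+k];
      etot[fi++] = eb + ew + ee + ke / KCAL;
    }
  }
  return List::create(_["etot"] = etot);
}

// Mean inter-residue distance at every sequence separation, averaged over
// frames (internal scaling profile).
// [[Rcpp::export]]
NumericVector cpp_internal_scaling(NumericVector frames, int n, int nframes) {
  NumericVector prof(n - 1);
  std::vector<double> acc(n - 1, 0.0);
  std::vector<long long> cnt(n - 1, 0);
  for (int fi = 0; fi < nframes; ++fi) {
    const double* x = &frames[(size_t)fi * n * 3];
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
               dz = x[3*i+2] - x[3*j+2];
        acc[j - i - 1] += std::sqrt(dx*dx + dy*dy + dz*dz);
        cnt[j - i - 1]++;
      }
    }
  }
  for (int d = 0; d < n - 1; ++d) prof[d] = acc[d] / (double)cnt[d];
  return prof;
}
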