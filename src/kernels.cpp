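// Nonbonded kernels, constraint dynamics and steepest-descent minimization.
//
// Units: length Å, time ps, mass amu, energy kcal/mol, charge e.
// 1 kcal/mol = 418.4 amu Å²/ps²  (FCONV below).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KCOUL = 332.0636;   // kcal Å / (mol e²)
static const double FCONV = 418.4;      // kcal/mol -> amu Å²/ps²
static const double KBOLTZ = 0.0019872; // kcal/(mol K)

struct NBContext {
  int n;
  const double *pos;
  const double *q, *eps, *rmh;
  const int *haslj;
  const int *molid, *isfixed, *restrained;
  double bx, by, bz;
  int px, py, pz;
  double rc, rc2;
  int scheme; // 0 = plain truncation, 1 = force-shifted, 2 = smooth Ewald
  double alpha; // Ewald splitting parameter (Å^-1)
  int kmax;     // Ewald reciprocal-space shell bound
  double efz; // field term, kcal/(mol e Å), along z
  double rzlo, rzhi, rk;
  int has_walls;
  // alchemical transform of a site subset (dual-topology, soft-core LJ)
  int has_alch;
  const int *alch;
  const double *qB, *epsB, *rmhB;
  const int *hasljB;
  double lam, scs;
  // optional restriction: count only pairs touching this site set
  const int *ingroup;
};

static inline double mi_round(double x) {
  return static_cast<double>(static_cast<long long>(x >= 0.0 ? x + 0.5 : x - 0.5));
}

static inline double eff_q(const NBContext &c, int i) {
  if (c.has_alch && c.alch[i])
    return (1.0 - c.lam) * c.q[i] + c.lam * c.qB[i];
  return c.q[i];
}

// Plain 12-6: E = eps[(R/r)^12 - 2(R/r)^6]; returns energy, adds F/r to fr.
static inline double lj_126(double epsij, double Rij, double r2, double *fr) {
  double s2 = (Rij * Rij) / r2;
  double u = s2 * s2 * s2; // (R/r)^6
  double e = epsij * (u * u - 2.0 * u);
  if (fr) *fr += 12.0 * epsij * (u * u - u) / r2;
  return e;
}

// Soft-core 12-6 with shift alpha in the r^6 denominator.
static inline double lj_softcore(double epsij, double Rij, double r2,
                                 double alpha, double *fr) {
  double R6 = Rij * Rij * Rij;
  R6 = R6 * R6;
  double r6 = r2 * r2 * r2;
  double den = r6 + alpha;
  double u = R6 / den;
  double e = epsij * (u * u - 2.0 * u);
  if (fr) {
    // F = -dE/dr = 6 r^5 R6 eps (2u-2)/den^2 ; fr accumulates F/r
    double r4 = r2 * r2;
    *fr += 6.0 * r4 * R6 * epsij * (2.0 * u - 2.0) / (den * den);
  }
  return e;
}

static inline double coul(const NBContext &c, double qq, double r, double r2,
                          double *fr) {
  double C = KCOUL * qq;
  if (c.scheme == 1) {
    double e = C * (1.0 / r - 1.0 / c.rc + (r - c.rc) / (c.rc * c.rc));
    if (fr) *fr += C * (1.0 / r2 - 1.0 / (c.rc * c.rc)) / r;
    return e;
  }
  if (c.scheme == 2) {
    double er = std::erfc(c.alpha * r);
    double e = C * er / r;
    if (fr)
      *fr += C * (er / r2 + 2.0 * c.alpha / std::sqrt(M_PI) *
                              std::exp(-c.alpha * c.alpha * r2) / r) / r;
    return e;
  }
  double e = C / r;
  if (fr) *fr += C / (r2 * r);
  return e;
}

// Ewald reciprocal-space sum, self energy, net-charge background, and the
// correction removing intramolecular (excluded) pairs from the lattice sum.
static void ewald_extras(const NBContext &c, double *F, double &Ec) {
  const int n = c.n;
  const double V = c.bx * c.by * c.bz;
  const double a = c.alpha;
  // self + background
  double q2 = 0.0, qtot = 0.0;
  for (int i = 0; i < n; i++) {
    double qi = eff_q(c, i);
    q2 += qi * qi;
    qtot += qi;
  }
  Ec -= KCOUL * a / std::sqrt(M_PI) * q2;
  Ec -= KCOUL * M_PI / (2.0 * a * a * V) * qtot * qtot;
  // excluded (intramolecular) pairs: remove the erf part the lattice sum adds
  for (int i = 0; i < n; i++) {
    double qi = eff_q(c, i);
    if (qi == 0.0) continue;
    for (int j = i + 1; j < n && c.molid[j] == c.molid[i]; j++) {
      double qj = eff_q(c, j);
      if (qj == 0.0) continue;
      double dx = c.pos[i] - c.pos[j];
      double dy = c.pos[i + n] - c.pos[j + n];
      double dz = c.pos[i + 2 * n] - c.pos[j + 2 * n];
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      double C = KCOUL * qi * qj;
      double ef = std::erf(a * r);
      Ec -= C * ef / r;
      if (F) {
        double fr = -C * (ef / r2 - 2.0 * a / std::sqrt(M_PI) *
                                        std::exp(-a * a * r2) / r) / r;
        F[i] += fr * dx;
        F[i + n] += fr * dy;
        F[i + 2 * n] += fr * dz;
        F[j] -= fr * dx;
        F[j + n] -= fr * dy;
        F[j + 2 * n] -= fr * dz;
      }
    }
  }
  // reciprocal space over half the k lattice (doubled), with per-site phase
  // tables e^{i 2 pi n x / L}
  const int km = c.kmax;
  const int width = 2 * km + 1;
  std::vector<double> exr(3 * n * width), exi(3 * n * width);
  const double tp = 2.0 * M_PI;
  const double gx = tp / c.bx, gy = tp / c.by, gz = tp / c.bz;
  for (int ax = 0; ax < 3; ax++) {
    double g = ax == 0 ? gx : (ax == 1 ? gy : gz);
    for (int i = 0; i < n; i++) {
      double x = c.pos[i + ax * n];
      double cr = std::cos(g * x), ci = std::sin(g * x);
      double *er = &exr[(ax * n + i) * width];
      double *ei = &exi[(ax * n + i) * width];
      er[km] = 1.0;
      ei[km] = 0.0;
      for (int m = 1; m <= km; m++) {
        er[km + m] = er[km + m - 1] * cr - ei[km + m - 1] * ci;
        ei[km + m] = er[km + m - 1] * ci + ei[km + m - 1] * cr;
        er[km - m] = er[km - m + 1] * cr + ei[km - m + 1] * ci;
        ei[km - m] = -er[km - m + 1] * ci + ei[km - m + 1] * cr;
      }
    }
  }
  std::vector<double> phr(n), phi(n), pxyr(n), pxyi(n), qv(n);
  for (int i = 0; i < n; i++) qv[i] = eff_q(c, i);
  const double pref = 2.0 * M_PI * KCOUL / V;
  for (int nx = 0; nx <= km; nx++) {
    int ny0 = (nx == 0) ? 0 : -km;
    for (int ny = ny0; ny <= km; ny++) {
      if (nx * nx + ny * ny > km * km) continue;
      for (int i = 0; i < n; i++) {
        const double *erx = &exr[(0 * n + i) * width];
        const double *eix = &exi[(0 * n + i) * width];
        const double *ery = &exr[(1 * n + i) * width];
        const double *eiy = &exi[(1 * n + i) * width];
        double r1 = erx[km + nx], i1 = eix[km + nx];
        pxyr[i] = r1 * ery[km + ny] - i1 * eiy[km + ny];
        pxyi[i] = r1 * eiy[km + ny] + i1 * ery[km + ny];
      }
      int nz0 = (nx == 0 && ny == 0) ? 1 : -km;
      for (int nz = nz0; nz <= km; nz++) {
        if (nx * nx + ny * ny + nz * nz > km * km) continue;
        double kx = nx * gx, ky = ny * gy, kz = nz * gz;
        double k2 = kx * kx + ky * ky + kz * kz;
        double A = std::exp(-k2 / (4.0 * a * a)) / k2;
        double sr = 0.0, si = 0.0;
        for (int i = 0; i < n; i++) {
          const double *erz = &exr[(2 * n + i) * width];
          const double *eiz = &exi[(2 * n + i) * width];
          double r3 = pxyr[i] * erz[km + nz] - pxyi[i] * eiz[km + nz];
          double i3 = pxyr[i] * eiz[km + nz] + pxyi[i] * erz[km + nz];
          phr[i] = r3;
          phi[i] = i3;
          sr += qv[i] * r3;
          si += qv[i] * i3;
        }
        Ec += 2.0 * pref * A * (sr * sr + si * si);
        if (F) {
          double fA = 4.0 * pref * A;
          for (int i = 0; i < n; i++) {
            if (qv[i] == 0.0) continue;
            // Im[S* e^{ik r_i}] = sr*phi[i] - si*phr[i]
            double im = sr * phi[i] - si * phr[i];
            double s = fA * qv[i] * im;
            F[i] += s * kx;
            F[i + n] += s * ky;
            F[i + 2 * n] += s * kz;
          }
        }
      }
    }
  }
}

// Full evaluation. F may be NULL. Energies accumulated into the four slots.
static void nb_eval(const NBContext &c, double *F, double &Ec, double &El,
                    double &Ef, double &Er) {
  Ec = El = Ef = Er = 0.0;
  const int n = c.n;
  const double ibx = c.px ? 1.0 / c.bx : 0.0;
  const double iby = c.py ? 1.0 / c.by : 0.0;
  const double ibz = c.pz ? 1.0 / c.bz : 0.0;
  const double irc = 1.0 / c.rc, irc2 = irc * irc;
  const double *px_ = c.pos, *py_ = c.pos + n, *pz_ = c.pos + 2 * n;
  std::vector<double> seps(n);
  for (int i = 0; i < n; i++) seps[i] = std::sqrt(c.eps[i]);
  // screened-Coulomb lookup, cubic Hermite on r: g1 = erfc(alpha r) with
  // analytic derivative d1 = -(2 alpha/sqrt(pi)) exp(-(alpha r)^2); the
  // force uses the exact derivative of the interpolant, so energy and force
  // stay consistent to machine precision.
  const int NT = 2048;
  static std::vector<double> tg1, td1;
  static double cached_alpha = -1.0, cached_rc = -1.0;
  double tscale = 0.0, tstep = 0.0;
  if (c.scheme == 2) {
    tscale = (NT - 1) / c.rc;
    tstep = 1.0 / tscale;
    if (c.alpha != cached_alpha || c.rc != cached_rc) {
      tg1.assign(NT + 2, 0.0);
      td1.assign(NT + 2, 0.0);
      for (int m = 0; m < NT + 2; m++) {
        double r = m * tstep;
        tg1[m] = std::erfc(c.alpha * r);
        td1[m] = -2.0 * c.alpha / std::sqrt(M_PI) *
                 std::exp(-c.alpha * c.alpha * r * r);
      }
      cached_alpha = c.alpha;
      cached_rc = c.rc;
    }
  }
  for (int i = 0; i < n; i++) {
    bool gi = !c.ingroup || c.ingroup[i];
    if (gi) {
      double qi = eff_q(c, i);
      double z = c.pos[i + 2 * n];
      if (c.efz != 0.0) {
        Ef += -qi * c.efz * z;
        if (F) F[i + 2 * n] += qi * c.efz;
      }
      if (c.has_walls && c.restrained[i] && !c.isfixed[i]) {
        if (z > c.rzhi) {
          double d = z - c.rzhi;
          Er += 0.5 * c.rk * d * d;
          if (F) F[i + 2 * n] -= c.rk * d;
        } else if (z < c.rzlo) {
          double d = c.rzlo - z;
          Er += 0.5 * c.rk * d * d;
          if (F) F[i + 2 * n] += c.rk * d;
        }
      }
    }
    const double xi = px_[i], yi = py_[i], zi = pz_[i];
    const int mi = c.molid[i];
    const bool fxi = c.isfixed[i] != 0;
    const double qi0 = eff_q(c, i);
    for (int j = i + 1; j < n; j++) {
      if (mi == c.molid[j]) continue;
      if (fxi && c.isfixed[j]) continue;
      if (c.ingroup && !(gi || c.ingroup[j])) continue;
      double dx = xi - px_[j];
      double dy = yi - py_[j];
      double dz = zi - pz_[j];
      if (c.px) dx -= c.bx * mi_round(dx * ibx);
      if (c.py) dy -= c.by * mi_round(dy * iby);
      if (c.pz) dz -= c.bz * mi_round(dz * ibz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > c.rc2) continue;
      bool iA = c.has_alch && (c.alch[i] || c.alch[j]);
      if (!iA) {
        // fast path: fixed identities
        double qq = qi0 * c.q[j];
        bool anylj = c.haslj[i] && c.haslj[j];
        if (qq == 0.0 && !anylj) continue;
        if (r2 < 1e-12)
          stop("singular geometry: overlapping sites %d and %d", i + 1, j + 1);
        double ir2 = 1.0 / r2;
        double ir = std::sqrt(ir2);
        double fr = 0.0;
        if (qq != 0.0) {
          double C = KCOUL * qq;
          if (c.scheme == 1) {
            double r = r2 * ir;
            Ec += C * (ir - irc + (r - c.rc) * irc2);
            if (F) fr += C * (ir2 - irc2) * ir;
          } else if (c.scheme == 2) {
            double r = r2 * ir;
            double u = r * tscale;
            int m = (int)u;
            double t = u - m;
            double y0 = tg1[m], y1 = tg1[m + 1];
            double d0 = td1[m] * tstep, d1 = td1[m + 1] * tstep;
            double t2_ = t * t, t3 = t2_ * t;
            double er = (2 * t3 - 3 * t2_ + 1) * y0 + (t3 - 2 * t2_ + t) * d0 +
                        (-2 * t3 + 3 * t2_) * y1 + (t3 - t2_) * d1;
            Ec += C * er * ir;
            if (F) {
              double dg = ((6 * t2_ - 6 * t) * (y0 - y1) +
                           (3 * t2_ - 4 * t + 1) * d0 + (3 * t2_ - 2 * t) * d1) *
                          tscale;
              fr += C * (er * ir2 - dg * ir) * ir;
            }
          } else {
            Ec += C * ir;
            if (F) fr += C * ir2 * ir;
          }
        }
        if (anylj) {
          double epsij = seps[i] * seps[j];
          double Rij = c.rmh[i] + c.rmh[j];
          double s2 = Rij * Rij * ir2;
          double u = s2 * s2 * s2;
          El += epsij * (u * u - 2.0 * u);
          if (F) fr += 12.0 * epsij * (u * u - u) * ir2;
        }
        if (F) {
          F[i] += fr * dx;
          F[i + n] += fr * dy;
          F[i + 2 * n] += fr * dz;
          F[j] -= fr * dx;
          F[j + n] -= fr * dy;
          F[j + 2 * n] -= fr * dz;
        }
        continue;
      }
      // alchemical path. Pairs present at both endpoints mix plain 12-6
      // legs linearly (identity transforms are exact at every coupling);
      // pairs that vanish at one endpoint use Beutler-style soft cores on
      // both the LJ leg and the Coulomb term so overlaps stay finite.
      double qq = qi0 * eff_q(c, j);
      bool hasA = c.haslj[i] && c.haslj[j];
      int hBi = c.alch[i] ? c.hasljB[i] : c.haslj[i];
      int hBj = c.alch[j] ? c.hasljB[j] : c.haslj[j];
      bool hasB = hBi && hBj;
      if (qq == 0.0 && !hasA && !hasB) continue;
      if (r2 < 1e-12)
        stop("singular geometry: overlapping sites %d and %d", i + 1, j + 1);
      double r = std::sqrt(r2);
      double fr = 0.0;
      double *frp = F ? &fr : (double *)0;
      double epsA = 0, RA = 0, epsB = 0, RB = 0;
      if (hasA) {
        epsA = std::sqrt(c.eps[i] * c.eps[j]);
        RA = c.rmh[i] + c.rmh[j];
      }
      if (hasB) {
        double eBi = c.alch[i] ? c.epsB[i] : c.eps[i];
        double eBj = c.alch[j] ? c.epsB[j] : c.eps[j];
        double RBi = c.alch[i] ? c.rmhB[i] : c.rmh[i];
        double RBj = c.alch[j] ? c.rmhB[j] : c.rmh[j];
        epsB = std::sqrt(eBi * eBj);
        RB = RBi + RBj;
      }
      double alpha = 0.0; // soft-core r^6 shift, nonzero for vanishing pairs
      if (hasA && !hasB) {
        double R6 = RA * RA * RA;
        alpha = c.scs * c.lam * R6 * R6;
      } else if (hasB && !hasA) {
        double R6 = RB * RB * RB;
        alpha = c.scs * (1.0 - c.lam) * R6 * R6;
      }
      if (qq != 0.0) {
        if (alpha == 0.0) {
          Ec += coul(c, qq, r, r2, frp);
        } else {
          double r6 = r2 * r2 * r2;
          double den = r6 + alpha;
          double rsc = std::pow(den, 1.0 / 6.0);
          double C = KCOUL * qq;
          Ec += C / rsc;
          // F = -dE/dr = C r^5 den^{-7/6}
          if (frp) fr += C * r2 * r2 / (den * rsc);
        }
      }
      if (hasA && c.lam < 1.0) {
        double fA = 0.0;
        double eA = alpha == 0.0 ? lj_126(epsA, RA, r2, frp ? &fA : 0)
                                 : lj_softcore(epsA, RA, r2, alpha,
                                               frp ? &fA : 0);
        El += (1.0 - c.lam) * eA;
        if (frp) fr += (1.0 - c.lam) * fA;
      }
      if (hasB && c.lam > 0.0) {
        double fB = 0.0;
        double eB = alpha == 0.0 ? lj_126(epsB, RB, r2, frp ? &fB : 0)
                                 : lj_softcore(epsB, RB, r2, alpha,
                                               frp ? &fB : 0);
        El += c.lam * eB;
        if (frp) fr += c.lam * fB;
      }
      if (F) {
        F[i] += fr * dx;
        F[i + n] += fr * dy;
        F[i + 2 * n] += fr * dz;
        F[j] -= fr * dx;
        F[j + n] -= fr * dy;
        F[j + 2 * n] -= fr * dz;
      }
    }
  }
  if (c.scheme == 2 && !c.ingroup) {
    if (!(c.px && c.py && c.pz))
      stop("Ewald requires a fully periodic box");
    ewald_extras(c, F, Ec);
  }
}

static NBContext make_ctx(const NumericMatrix &pos, const NumericVector &q,
                          const NumericVector &eps, const NumericVector &rmh,
                          const IntegerVector &haslj, const IntegerVector &molid,
                          const IntegerVector &isfixed,
                          const IntegerVector &restrained,
                          const NumericVector &box, const IntegerVector &periodic,
                          double cutoff, int scheme, double efz,
                          const NumericVector &walls, const List &alch,
                          const IntegerVector &ingroup,
                          const NumericVector &ewald) {
  NBContext c;
  c.n = pos.nrow();
  c.pos = pos.begin();
  c.q = q.begin();
  c.eps = eps.begin();
  c.rmh = rmh.begin();
  c.haslj = haslj.begin();
  c.molid = molid.begin();
  c.isfixed = isfixed.begin();
  c.restrained = restrained.begin();
  c.bx = box[0];
  c.by = box[1];
  c.bz = box[2];
  c.px = periodic[0];
  c.py = periodic[1];
  c.pz = periodic[2];
  c.rc = cutoff;
  c.rc2 = cutoff * cutoff;
  c.scheme = scheme;
  c.alpha = ewald.size() > 0 ? ewald[0] : 0.0;
  c.kmax = ewald.size() > 1 ? (int)ewald[1] : 0;
  if (scheme == 2 && (c.alpha <= 0 || c.kmax < 1))
    stop("Ewald scheme requires alpha > 0 and kmax >= 1");
  c.efz = efz;
  c.rzlo = walls[0];
  c.rzhi = walls[1];
  c.rk = walls[2];
  c.has_walls = (c.rk > 0.0);
  c.has_alch = alch.size() > 0;
  c.lam = 0.0;
  c.scs = 0.0;
  c.alch = 0;
  c.qB = 0;
  c.epsB = 0;
  c.rmhB = 0;
  c.hasljB = 0;
  if (c.has_alch) {
    c.alch = INTEGER(as<IntegerVector>(alch["mask"]));
    c.qB = REAL(as<NumericVector>(alch["q"]));
    c.epsB = REAL(as<NumericVector>(alch["eps"]));
    c.rmhB = REAL(as<NumericVector>(alch["rmh"]));
    c.hasljB = INTEGER(as<IntegerVector>(alch["haslj"]));
    c.lam = as<double>(alch["lambda"]);
    c.scs = as<double>(alch["softcore"]);
  }
  c.ingroup = ingroup.size() ? ingroup.begin() : 0;
  return c;
}

// [[Rcpp::export]]
List cpp_nonbonded(NumericMatrix pos, NumericVector q, NumericVector eps,
                   NumericVector rmh, IntegerVector haslj, IntegerVector molid,
                   IntegerVector isfixed, IntegerVector restrained,
                   NumericVector box, IntegerVector periodic, double cutoff,
                   int scheme, double efz, NumericVector walls, List alch,
                   IntegerVector ingroup, NumericVector ewald, bool forces) {
  NBContext c = make_ctx(pos, q, eps, rmh, haslj, molid, isfixed, restrained,
                         box, periodic, cutoff, scheme, efz, walls, alch,
                         ingroup, ewald);
  NumericMatrix F;
  double *Fp = 0;
  if (forces) {
    F = NumericMatrix(pos.nrow(), 3);
    Fp = F.begin();
  }
  double Ec, El, Ef, Er;
  nb_eval(c, Fp, Ec, El, Ef, Er);
  List out = List::create(_["coulomb"] = Ec, _["lj"] = El, _["field"] = Ef,
                          _["restraint"] = Er,
                          _["total"] = Ec + El + Ef + Er);
  if (forces) out["forces"] = F;
  return out;
}

// SHAKE: project `pos` onto the constraint manifold using `ref` directions.
// Optionally applies the position corrections to velocities (divided by dt).
static int shake_iter(double *pos, const double *ref, double *vel, int n,
                      const int *ci, const int *cj, const double *cd, int nc,
                      const double *invm, double tol, int maxit, double dt) {
  for (int it = 0; it < maxit; it++) {
    double maxdev = 0.0;
    for (int k = 0; k < nc; k++) {
      int i = ci[k] - 1, j = cj[k] - 1;
      double d = cd[k];
      double dx = pos[i] - pos[j];
      double dy = pos[i + n] - pos[j + n];
      double dz = pos[i + 2 * n] - pos[j + 2 * n];
      double r2 = dx * dx + dy * dy + dz * dz;
      double dev = std::fabs(std::sqrt(r2) - d);
      if (dev > maxdev) maxdev = dev;
      double diff = r2 - d * d;
      if (std::fabs(diff) < 2.0 * tol * d) continue;
      double rx = ref[i] - ref[j];
      double ry = ref[i + n] - ref[j + n];
      double rz = ref[i + 2 * n] - ref[j + 2 * n];
      double denom = 2.0 * (invm[i] + invm[j]) * (dx * rx + dy * ry + dz * rz);
      if (std::fabs(denom) < 1e-12) continue;
      double g = diff / denom;
      pos[i] -= g * invm[i] * rx;
      pos[i + n] -= g * invm[i] * ry;
      pos[i + 2 * n] -= g * invm[i] * rz;
      pos[j] += g * invm[j] * rx;
      pos[j + n] += g * invm[j] * ry;
      pos[j + 2 * n] += g * invm[j] * rz;
      if (vel) {
        double gi = g * invm[i] / dt, gj = g * invm[j] / dt;
        vel[i] -= gi * rx;
        vel[i + n] -= gi * ry;
        vel[i + 2 * n] -= gi * rz;
        vel[j] += gj * rx;
        vel[j + n] += gj * ry;
        vel[j + 2 * n] += gj * rz;
      }
    }
    if (maxdev < tol) return it + 1;
  }
  return -1;
}

// RATTLE velocity projection: remove velocity components along constraints.
static void rattle_iter(const double *pos, double *vel, int n, const int *ci,
                        const int *cj, const double *cd, int nc,
                        const double *invm, double tol, int maxit) {
  for (int it = 0; it < maxit; it++) {
    double maxrv = 0.0;
    for (int k = 0; k < nc; k++) {
      int i = ci[k] - 1, j = cj[k] - 1;
      double dx = pos[i] - pos[j];
      double dy = pos[i + n] - pos[j + n];
      double dz = pos[i + 2 * n] - pos[j + 2 * n];
      double vx = vel[i] - vel[j];
      double vy = vel[i + n] - vel[j + n];
      double vz = vel[i + 2 * n] - vel[j + 2 * n];
      double rv = dx * vx + dy * vy + dz * vz;
      if (std::fabs(rv) > maxrv) maxrv = std::fabs(rv);
      double kk = rv / ((invm[i] + invm[j]) * cd[k] * cd[k]);
      vel[i] -= kk * invm[i] * dx;
      vel[i + n] -= kk * invm[i] * dy;
      vel[i + 2 * n] -= kk * invm[i] * dz;
      vel[j] += kk * invm[j] * dx;
      vel[j + n] += kk * invm[j] * dy;
      vel[j + 2 * n] += kk * invm[j] * dz;
    }
    if (maxrv < tol) return;
  }
}

// [[Rcpp::export]]
List cpp_shake(NumericMatrix pos, NumericMatrix ref, IntegerVector ci,
               IntegerVector cj, NumericVector cd, NumericVector invmass,
               double tol, int maxit) {
  NumericMatrix p = clone(pos);
  int it = shake_iter(p.begin(), ref.begin(), 0, p.nrow(), ci.begin(),
                      cj.begin(), cd.begin(), ci.size(), invmass.begin(), tol,
                      maxit, 1.0);
  return List::create(_["pos"] = p, _["iterations"] = it,
                      _["converged"] = it > 0);
}

// [[Rcpp::export]]
NumericMatrix cpp_rattle(NumericMatrix pos, NumericMatrix vel, IntegerVector ci,
                         IntegerVector cj, NumericVector cd,
                         NumericVector invmass, double tol, int maxit) {
  NumericMatrix v = clone(vel);
  rattle_iter(pos.begin(), v.begin(), pos.nrow(), ci.begin(), cj.begin(),
              cd.begin(), ci.size(), invmass.begin(), tol, maxit);
  return v;
}

// Velocity-Verlet NVT/NVE driver with SHAKE/RATTLE and velocity-rescale
// thermostat. Frames saved every saveStride steps (0 = none).
// [[Rcpp::export]]
List cpp_md_run(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                NumericVector q, NumericVector eps, NumericVector rmh,
                IntegerVector haslj, IntegerVector molid, IntegerVector isfixed,
                IntegerVector restrained, NumericVector box,
                IntegerVector periodic, double cutoff, int scheme, double efz,
                NumericVector walls, List alch, NumericVector ewald,
                IntegerVector ci,
                IntegerVector cj, NumericVector cd, int nsteps, double dt,
                double thermoT, int thermoInt, double thermoTol, double ndof,
                double shakeTol, int shakeMaxit, int saveStride) {
  int n = pos0.nrow(), nc = ci.size();
  NumericMatrix pos = clone(pos0), vel = clone(vel0);
  NumericVector invm(n);
  for (int i = 0; i < n; i++)
    invm[i] = isfixed[i] ? 0.0 : 1.0 / mass[i];
  IntegerVector nogroup(0);
  NBContext c = make_ctx(pos, q, eps, rmh, haslj, molid, isfixed, restrained,
                         box, periodic, cutoff, scheme, efz, walls, alch,
                         nogroup, ewald);
  std::vector<double> F(3 * n, 0.0), Fold(3 * n), refpos(3 * n);
  double Ec, El, Ef, Er;
  nb_eval(c, F.data(), Ec, El, Ef, Er);
  NumericVector epot(nsteps), ekin(nsteps), temps(nsteps);
  int nframes = saveStride > 0 ? nsteps / saveStride : 0;
  NumericVector frames(nframes > 0 ? nframes * 3 * n : 0);
  int fidx = 0;
  for (int step = 0; step < nsteps; step++) {
    // half kick + drift
    for (int i = 0; i < n; i++) {
      double a = 0.5 * dt * FCONV * invm[i];
      vel[i] += a * F[i];
      vel[i + n] += a * F[i + n];
      vel[i + 2 * n] += a * F[i + 2 * n];
    }
    std::copy(pos.begin(), pos.end(), refpos.begin());
    for (int i = 0; i < n; i++) {
      pos[i] += dt * vel[i];
      pos[i + n] += dt * vel[i + n];
      pos[i + 2 * n] += dt * vel[i + 2 * n];
    }
    if (nc) {
      int it = shake_iter(pos.begin(), refpos.data(), vel.begin(), n,
                          ci.begin(), cj.begin(), cd.begin(), nc, invm.begin(),
                          shakeTol, shakeMaxit, dt);
      if (it < 0) stop("SHAKE failed to converge at step %d", step + 1);
    }
    std::fill(F.begin(), F.end(), 0.0);
    nb_eval(c, F.data(), Ec, El, Ef, Er);
    for (int i = 0; i < n; i++) {
      double a = 0.5 * dt * FCONV * invm[i];
      vel[i] += a * F[i];
      vel[i + n] += a * F[i + n];
      vel[i + 2 * n] += a * F[i + 2 * n];
    }
    if (nc)
      rattle_iter(pos.begin(), vel.begin(), n, ci.begin(), cj.begin(),
                  cd.begin(), nc, invm.begin(), 1e-10, shakeMaxit);
    double ke = 0.0;
    for (int i = 0; i < n; i++) {
      if (isfixed[i]) continue;
      double v2 = vel[i] * vel[i] + vel[i + n] * vel[i + n] +
                  vel[i + 2 * n] * vel[i + 2 * n];
      ke += 0.5 * mass[i] * v2;
    }
    ke /= FCONV;
    double T = ndof > 0 ? 2.0 * ke / (ndof * KBOLTZ) : 0.0;
    if (thermoInt > 0 && ((step + 1) % thermoInt == 0) && ke > 0.0) {
      if (std::fabs(T - thermoT) > thermoTol) {
        double s = std::sqrt(thermoT / T);
        for (int i = 0; i < n; i++) {
          if (isfixed[i]) continue;
          vel[i] *= s;
          vel[i + n] *= s;
          vel[i + 2 * n] *= s;
        }
        ke *= s * s;
        T = thermoT;
      }
    }
    epot[step] = Ec + El + Ef + Er;
    ekin[step] = ke;
    temps[step] = T;
    if (saveStride > 0 && ((step + 1) % saveStride == 0) && fidx < nframes) {
      std::copy(pos.begin(), pos.end(), frames.begin() + (R_xlen_t)fidx * 3 * n);
      fidx++;
    }
  }
  List out = List::create(_["pos"] = pos, _["vel"] = vel, _["epot"] = epot,
                          _["ekin"] = ekin, _["temp"] = temps);
  if (nframes > 0) {
    frames.attr("dim") = IntegerVector::create(n, 3, nframes);
    out["frames"] = frames;
  }
  return out;
}

// Adaptive steepest descent with constraint projection after each move.
// The energy trace is non-increasing: rejected uphill moves halve the step.
// [[Rcpp::export]]
List cpp_min_sd(NumericMatrix pos0, NumericVector mass, NumericVector q,
                NumericVector eps, NumericVector rmh, IntegerVector haslj,
                IntegerVector molid, IntegerVector isfixed,
                IntegerVector restrained, NumericVector box,
                IntegerVector periodic, double cutoff, int scheme, double efz,
                NumericVector walls, List alch, NumericVector ewald,
                IntegerVector ci,
                IntegerVector cj, NumericVector cd, int nsteps, double step0,
                double shakeTol, int shakeMaxit) {
  int n = pos0.nrow(), nc = ci.size();
  NumericMatrix pos = clone(pos0);
  NumericVector invm(n);
  for (int i = 0; i < n; i++)
    invm[i] = isfixed[i] ? 0.0 : 1.0 / mass[i];
  IntegerVector nogroup(0);
  NBContext c = make_ctx(pos, q, eps, rmh, haslj, molid, isfixed, restrained,
                         box, periodic, cutoff, scheme, efz, walls, alch,
                         nogroup, ewald);
  std::vector<double> F(3 * n);
  NumericMatrix trial(n, 3);
  double Ec, El, Ef, Er;
  nb_eval(c, 0, Ec, El, Ef, Er);
  double E = Ec + El + Ef + Er;
  double h = step0;
  NumericVector trace(nsteps + 1);
  trace[0] = E;
  for (int s = 0; s < nsteps; s++) {
    std::fill(F.begin(), F.end(), 0.0);
    nb_eval(c, F.data(), Ec, El, Ef, Er);
    double fmax = 0.0;
    for (int i = 0; i < n; i++) {
      if (isfixed[i]) {
        F[i] = F[i + n] = F[i + 2 * n] = 0.0;
        continue;
      }
      for (int d = 0; d < 3; d++)
        fmax = std::max(fmax, std::fabs(F[i + d * n]));
    }
    if (fmax < 1e-12) {
      trace[s + 1] = E;
      continue;
    }
    double sc = h / fmax;
    for (int i = 0; i < 3 * n; i++) trial[i] = pos[i] + sc * F[i];
    if (nc)
      shake_iter(trial.begin(), pos.begin(), 0, n, ci.begin(), cj.begin(),
                 cd.begin(), nc, invm.begin(), shakeTol, shakeMaxit, 1.0);
    NBContext ct = c;
    ct.pos = trial.begin();
    nb_eval(ct, 0, Ec, El, Ef, Er);
    double Et = Ec + El + Ef + Er;
    if (Et <= E) {
      std::copy(trial.begin(), trial.end(), pos.begin());
      E = Et;
      h = std::min(h * 1.2, 0.5);
    } else {
      h *= 0.5;
    }
    trace[s + 1] = E;
  }
  return List::create(_["pos"] = pos, _["energy"] = E, _["trace"] = trace);
}

// Ewald reciprocal-space structure factor over the half k-lattice used by
// ewald_extras: returns per-k metadata and S(k) for incremental updates.
// [[Rcpp::export]]
List cpp_ewald_sf(NumericMatrix pos, NumericVector q, NumericVector box,
                  double alpha, int kmax) {
  const int n = pos.nrow(), km = kmax;
  const double tp = 2.0 * M_PI;
  const double gx = tp / box[0], gy = tp / box[1], gz = tp / box[2];
  std::vector<double> kxv, kyv, kzv, Av, Srv, Siv;
  for (int nx = 0; nx <= km; nx++) {
    int ny0 = (nx == 0) ? 0 : -km;
    for (int ny = ny0; ny <= km; ny++) {
      if (nx * nx + ny * ny > km * km) continue;
      int nz0 = (nx == 0 && ny == 0) ? 1 : -km;
      for (int nz = nz0; nz <= km; nz++) {
        if (nx * nx + ny * ny + nz * nz > km * km) continue;
        double kx = nx * gx, ky = ny * gy, kz = nz * gz;
        double k2 = kx * kx + ky * ky + kz * kz;
        double sr = 0.0, si = 0.0;
        for (int i = 0; i < n; i++) {
          if (q[i] == 0.0) continue;
          double ph = kx * pos(i, 0) + ky * pos(i, 1) + kz * pos(i, 2);
          sr += q[i] * std::cos(ph);
          si += q[i] * std::sin(ph);
        }
        kxv.push_back(kx); kyv.push_back(ky); kzv.push_back(kz);
        Av.push_back(std::exp(-k2 / (4.0 * alpha * alpha)) / k2);
        Srv.push_back(sr); Siv.push_back(si);
      }
    }
  }
  double V = box[0] * box[1] * box[2];
  return List::create(_["kx"] = kxv, _["ky"] = kyv, _["kz"] = kzv,
                      _["A"] = Av, _["Sr"] = Srv, _["Si"] = Siv,
                      _["pref"] = 2.0 * M_PI * KCOUL / V);
}

// k-space energy change when `changed` sites move from (pos, q) to
// (pos_new, q_new): E_k(S + dS) - E_k(S) from a cached structure factor.
// [[Rcpp::export]]
double cpp_ewald_de_kspace(List sf, NumericMatrix pos, NumericVector q,
                           IntegerVector changed, NumericMatrix pos_new,
                           NumericVector q_new) {
  NumericVector kx = sf["kx"], ky = sf["ky"], kz = sf["kz"], A = sf["A"],
                Sr = sf["Sr"], Si = sf["Si"];
  double pref = as<double>(sf["pref"]);
  int nk = kx.size(), m = changed.size();
  double de = 0.0;
  for (int k = 0; k < nk; k++) {
    double dsr = 0.0, dsi = 0.0;
    for (int c = 0; c < m; c++) {
      int i = changed[c] - 1;
      if (q[i] != 0.0) {
        double ph = kx[k] * pos(i, 0) + ky[k] * pos(i, 1) + kz[k] * pos(i, 2);
        dsr -= q[i] * std::cos(ph);
        dsi -= q[i] * std::sin(ph);
      }
      if (q_new[c] != 0.0) {
        double ph = kx[k] * pos_new(c, 0) + ky[k] * pos_new(c, 1) +
                    kz[k] * pos_new(c, 2);
        dsr += q_new[c] * std::cos(ph);
        dsi += q_new[c] * std::sin(ph);
      }
    }
    double sr = Sr[k] + dsr, si = Si[k] + dsi;
    de += 2.0 * pref * A[k] *
          (sr * sr + si * si - Sr[k] * Sr[k] - Si[k] * Si[k]);
  }
  return de;
}

// Pair-histogram accumulation for RDFs over a frame stack (n x 3 x nf array).
// [[Rcpp::export]]
NumericVector cpp_rdf_counts(NumericVector frames, IntegerVector sela,
                             IntegerVector selb, NumericVector box,
                             IntegerVector periodic, double binw, double rmax,
                             IntegerVector molid, bool exclude_same_mol) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], nf = dim[2];
  int nbins = (int)std::ceil(rmax / binw);
  NumericVector counts(nbins);
  double bx = box[0], by = box[1], bz = box[2];
  int px = periodic[0], py = periodic[1], pz = periodic[2];
  for (int f = 0; f < nf; f++) {
    const double *p = frames.begin() + (R_xlen_t)f * 3 * n;
    for (int ia = 0; ia < sela.size(); ia++) {
      int i = sela[ia] - 1;
      for (int ib = 0; ib < selb.size(); ib++) {
        int j = selb[ib] - 1;
        if (i == j) continue;
        if (exclude_same_mol && molid[i] == molid[j]) continue;
        double dx = p[i] - p[j];
        double dy = p[i + n] - p[j + n];
        double dz = p[i + 2 * n] - p[j + 2 * n];
        if (px) dx -= bx * std::nearbyint(dx / bx);
        if (py) dy -= by * std::nearbyint(dy / by);
        if (pz) dz -= bz * std::nearbyint(dz / bz);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < rmax) counts[(int)(r / binw)] += 1.0;
      }
    }
  }
  return counts;
}
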