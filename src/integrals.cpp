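// Gaussian integral engine: McMurchie-Davidson scheme over contracted
// Cartesian shells with l <= 1 (s, p).  All lengths in bohr, energies in
// hartree.  Shells arrive from R as a list of lists with fields
//   l      integer (0 or 1)
//   center numeric[3]
//   exps   numeric[nprim]
//   coefs  numeric[nprim]   (primitive-normalised, contraction-normalised)
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// Boys function F_0..F_nmax at x, downward recursion from a truncated
// series (x < 35) or upward from the asymptotic F_0 (x >= 35).
static void boys(int nmax, double x, double* F) {
  if (x < 1e-14) {
    for (int n = 0; n <= nmax; ++n) F[n] = 1.0 / (2.0 * n + 1.0);
    return;
  }
  if (x < 35.0) {
    // series for F_nmax: e^-x * sum_k (2x)^k / (2nmax+1)(2nmax+3)...(2nmax+2k+1)
    double s = 0.0, term = 1.0 / (2.0 * nmax + 1.0);
    for (int k = 0; k < 200; ++k) {
      s += term;
      term *= 2.0 * x / (2.0 * nmax + 2.0 * k + 3.0);
      if (term < 1e-17 * s) break;
    }
    double ex = std::exp(-x);
    F[nmax] = s * ex;
    for (int n = nmax - 1; n >= 0; --n)
      F[n] = (2.0 * x * F[n + 1] + ex) / (2.0 * n + 1.0);
  } else {
    double ex = std::exp(-x);
    F[0] = 0.5 * std::sqrt(PI / x);
    for (int n = 0; n < nmax; ++n)
      F[n + 1] = ((2.0 * n + 1.0) * F[n] - ex) / (2.0 * x);
  }
}

// Hermite expansion coefficient E_t^{ij} for a 1-D primitive pair.
// Simple recursive form; i, j <= 3 here so depth is trivial.
static double Ecoef(int i, int j, int t, double Qx, double a, double b) {
  double p = a + b, q = a * b / p;
  if (t < 0 || t > i + j) return 0.0;
  if (i == 0 && j == 0 && t == 0) return std::exp(-q * Qx * Qx);
  if (j == 0) {
    return (1.0 / (2.0 * p)) * Ecoef(i - 1, j, t - 1, Qx, a, b)
         - (q * Qx / a)      * Ecoef(i - 1, j, t, Qx, a, b)
         + (t + 1.0)         * Ecoef(i - 1, j, t + 1, Qx, a, b);
  }
  return (1.0 / (2.0 * p)) * Ecoef(i, j - 1, t - 1, Qx, a, b)
       + (q * Qx / b)      * Ecoef(i, j - 1, t, Qx, a, b)
       + (t + 1.0)         * Ecoef(i, j - 1, t + 1, Qx, a, b);
}

// Hermite Coulomb repulsion R^0_{tuv} via recursion with auxiliary order n.
static double Rherm(int t, int u, int v, int n, double p, double PCx,
                    double PCy, double PCz, const double* F) {
  if (t < 0 || u < 0 || v < 0) return 0.0;
  if (t == 0 && u == 0 && v == 0) {
    double val = F[n];
    double f = std::pow(-2.0 * p, n);
    return f * val;
  }
  if (t > 0)
    return (t - 1) * Rherm(t - 2, u, v, n + 1, p, PCx, PCy, PCz, F)
         + PCx * Rherm(t - 1, u, v, n + 1, p, PCx, PCy, PCz, F);
  if (u > 0)
    return (u - 1) * Rherm(t, u - 2, v, n + 1, p, PCx, PCy, PCz, F)
         + PCy * Rherm(t, u - 1, v, n + 1, p, PCx, PCy, PCz, F);
  return (v - 1) * Rherm(t, u, v - 2, n + 1, p, PCx, PCy, PCz, F)
       + PCz * Rherm(t, u, v - 1, n + 1, p, PCx, PCy, PCz, F);
}

struct Shell {
  int l;
  double cx, cy, cz;
  std::vector<double> exps, coefs;
  int nfun() const { return l == 0 ? 1 : 3; }
};

// Cartesian powers for the components of an l=0 or l=1 shell.
static void powers(int l, int comp, int* ijk) {
  ijk[0] = ijk[1] = ijk[2] = 0;
  if (l == 1) ijk[comp] = 1;
}

static std::vector<Shell> parse_shells(const List& shells) {
  std::vector<Shell> out;
  for (int s = 0; s < shells.size(); ++s) {
    List sh = shells[s];
    Shell S;
    S.l = as<int>(sh["l"]);
    NumericVector c = sh["center"];
    S.cx = c[0]; S.cy = c[1]; S.cz = c[2];
    S.exps = as<std::vector<double> >(sh["exps"]);
    S.coefs = as<std::vector<double> >(sh["coefs"]);
    out.push_back(S);
  }
  return out;
}

static int nbf_total(const std::vector<Shell>& sh) {
  int n = 0;
  for (size_t i = 0; i < sh.size(); ++i) n += sh[i].nfun();
  return n;
}

// Primitive overlap in 1-D including the (pi/p)^{1/2} factor split at the end.
static double S1d(int i, int j, double Qx, double a, double b) {
  return Ecoef(i, j, 0, Qx, a, b);
}

// [[Rcpp::export(name = ".ovl_kin")]]
List ovl_kin(List shells) {
  std::vector<Shell> sh = parse_shells(shells);
  int n = nbf_total(sh);
  NumericMatrix S(n, n), T(n, n);
  int iof = 0;
  for (size_t si = 0; si < sh.size(); ++si) {
    int jof = 0;
    for (size_t sj = 0; sj < sh.size(); ++sj) {
      if (sj < si) { jof += sh[sj].nfun(); continue; }
      const Shell &A = sh[si], &B = sh[sj];
      double ABx = A.cx - B.cx, ABy = A.cy - B.cy, ABz = A.cz - B.cz;
      for (int ca = 0; ca < A.nfun(); ++ca) {
        int ia[3]; powers(A.l, ca, ia);
        for (int cb = 0; cb < B.nfun(); ++cb) {
          int ib[3]; powers(B.l, cb, ib);
          double sv = 0.0, tv = 0.0;
          for (size_t pa = 0; pa < A.exps.size(); ++pa) {
            for (size_t pb = 0; pb < B.exps.size(); ++pb) {
              double a = A.exps[pa], b = B.exps[pb];
              double p = a + b;
              double pref = A.coefs[pa] * B.coefs[pb]
                          * std::pow(PI / p, 1.5);
              double sx = S1d(ia[0], ib[0], ABx, a, b);
              double sy = S1d(ia[1], ib[1], ABy, a, b);
              double sz = S1d(ia[2], ib[2], ABz, a, b);
              sv += pref * sx * sy * sz;
              // kinetic: -1/2 d2/dq2 acting on ket, per axis
              double AB[3] = {ABx, ABy, ABz};
              double ss[3] = {sx, sy, sz};
              double tk = 0.0;
              for (int ax = 0; ax < 3; ++ax) {
                int jb = ib[ax];
                double d2 = 4.0 * b * b * S1d(ia[ax], jb + 2, AB[ax], a, b)
                          - 2.0 * b * (2.0 * jb + 1.0) * ss[ax];
                if (jb >= 2)
                  d2 += jb * (jb - 1.0) * S1d(ia[ax], jb - 2, AB[ax], a, b);
                double term = -0.5 * d2;
                for (int ox = 0; ox < 3; ++ox)
                  if (ox != ax) term *= ss[ox];
                tk += term;
              }
              tv += pref * tk;
            }
          }
          S(iof + ca, jof + cb) = sv; S(jof + cb, iof + ca) = sv;
          T(iof + ca, jof + cb) = tv; T(jof + cb, iof + ca) = tv;
        }
      }
      jof += sh[sj].nfun();
    }
    iof += sh[si].nfun();
  }
  return List::create(_["S"] = S, _["T"] = T);
}

// Matrix of <mu | sum_i q_i / |r - R_i| | nu>  (attraction kernel, positive
// for positive q; callers multiply by -1 for the electron's charge).
// [[Rcpp::export(name = ".coulomb_attraction")]]
NumericMatrix coulomb_attraction(List shells, NumericMatrix pos,
                                 NumericVector q) {
  std::vector<Shell> sh = parse_shells(shells);
  int n = nbf_total(sh);
  int nc = pos.nrow();
  NumericMatrix V(n, n);
  double F[16];
  int iof = 0;
  for (size_t si = 0; si < sh.size(); ++si) {
    int jof = 0;
    for (size_t sj = 0; sj < sh.size(); ++sj) {
      if (sj < si) { jof += sh[sj].nfun(); continue; }
      const Shell &A = sh[si], &B = sh[sj];
      double ABx = A.cx - B.cx, ABy = A.cy - B.cy, ABz = A.cz - B.cz;
      int ltot = A.l + B.l;
      for (int ca = 0; ca < A.nfun(); ++ca) {
        int ia[3]; powers(A.l, ca, ia);
        for (int cb = 0; cb < B.nfun(); ++cb) {
          int ib[3]; powers(B.l, cb, ib);
          double val = 0.0;
          for (size_t pa = 0; pa < A.exps.size(); ++pa) {
            for (size_t pb = 0; pb < B.exps.size(); ++pb) {
              double a = A.exps[pa], b = B.exps[pb];
              double p = a + b;
              double Px = (a * A.cx + b * B.cx) / p;
              double Py = (a * A.cy + b * B.cy) / p;
              double Pz = (a * A.cz + b * B.cz) / p;
              double pref = A.coefs[pa] * B.coefs[pb] * 2.0 * PI / p;
              // Hermite coefficients per axis
              double Ex[4], Ey[4], Ez[4];
              for (int t = 0; t <= ltot; ++t) {
                Ex[t] = Ecoef(ia[0], ib[0], t, ABx, a, b);
                Ey[t] = Ecoef(ia[1], ib[1], t, ABy, a, b);
                Ez[t] = Ecoef(ia[2], ib[2], t, ABz, a, b);
              }
              for (int c = 0; c < nc; ++c) {
                double PCx = Px - pos(c, 0), PCy = Py - pos(c, 1),
                       PCz = Pz - pos(c, 2);
                double r2 = PCx * PCx + PCy * PCy + PCz * PCz;
                boys(ltot, p * r2, F);
                double acc = 0.0;
                for (int t = 0; t <= ltot; ++t)
                  for (int u = 0; u <= ltot - t; ++u)
                    for (int v = 0; v <= ltot - t - u; ++v)
                      acc += Ex[t] * Ey[u] * Ez[v]
                           * Rherm(t, u, v, 0, p, PCx, PCy, PCz, F);
                val += pref * q[c] * acc;
              }
            }
          }
          V(iof + ca, jof + cb) = val; V(jof + cb, iof + ca) = val;
        }
      }
      jof += sh[sj].nfun();
    }
    iof += sh[si].nfun();
  }
  return V;
}

// Full two-electron repulsion tensor (mu nu | la si), chemists' notation,
// returned as a flat vector indexed mu + n*(nu + n*(la + n*si)), 0-based.
// [[Rcpp::export(name = ".eri_tensor")]]
NumericVector eri_tensor(List shells) {
  std::vector<Shell> sh = parse_shells(shells);
  int ns = (int)sh.size();
  int n = nbf_total(sh);
  std::vector<int> off(ns);
  { int o = 0; for (int s = 0; s < ns; ++s) { off[s] = o; o += sh[s].nfun(); } }
  NumericVector out((double)n * n * n * n);
  double* O = REAL(out);
  double F[16];
  for (int si = 0; si < ns; ++si)
  for (int sj = 0; sj <= si; ++sj)
  for (int sk = 0; sk <= si; ++sk)
  for (int sl = 0; sl <= (sk == si ? sj : sk); ++sl) {
    const Shell &A = sh[si], &B = sh[sj], &C = sh[sk], &D = sh[sl];
    double ABx = A.cx - B.cx, ABy = A.cy - B.cy, ABz = A.cz - B.cz;
    double CDx = C.cx - D.cx, CDy = C.cy - D.cy, CDz = C.cz - D.cz;
    int lab = A.l + B.l, lcd = C.l + D.l, ltot = lab + lcd;
    int na = A.nfun(), nb = B.nfun(), nc = C.nfun(), nd = D.nfun();
    std::vector<double> block(na * nb * nc * nd, 0.0);
    for (size_t pa = 0; pa < A.exps.size(); ++pa)
    for (size_t pb = 0; pb < B.exps.size(); ++pb) {
      double a = A.exps[pa], b = B.exps[pb], p = a + b;
      double Px = (a * A.cx + b * B.cx) / p;
      double Py = (a * A.cy + b * B.cy) / p;
      double Pz = (a * A.cz + b * B.cz) / p;
      double cab = A.coefs[pa] * B.coefs[pb];
      for (size_t pc = 0; pc < C.exps.size(); ++pc)
      for (size_t pd = 0; pd < D.exps.size(); ++pd) {
        double c = C.exps[pc], d = D.exps[pd], qq = c + d;
        double Qx = (c * C.cx + d * D.cx) / qq;
        double Qy = (c * C.cy + d * D.cy) / qq;
        double Qz = (c * C.cz + d * D.cz) / qq;
        double ccd = C.coefs[pc] * D.coefs[pd];
        double alpha = p * qq / (p + qq);
        double PQx = Px - Qx, PQy = Py - Qy, PQz = Pz - Qz;
        double r2 = PQx * PQx + PQy * PQy + PQz * PQz;
        boys(ltot, alpha * r2, F);
        double pref = cab * ccd * 2.0 * std::pow(PI, 2.5)
                    / (p * qq * std::sqrt(p + qq));
        int bi = 0;
        for (int caa = 0; caa < na; ++caa) {
          int i1[3]; powers(A.l, caa, i1);
          for (int cbb = 0; cbb < nb; ++cbb) {
            int i2[3]; powers(B.l, cbb, i2);
            double E1x[4], E1y[4], E1z[4];
            for (int t = 0; t <= lab; ++t) {
              E1x[t] = Ecoef(i1[0], i2[0], t, ABx, a, b);
              E1y[t] = Ecoef(i1[1], i2[1], t, ABy, a, b);
              E1z[t] = Ecoef(i1[2], i2[2], t, ABz, a, b);
            }
            for (int ccc = 0; ccc < nc; ++ccc) {
              int i3[3]; powers(C.l, ccc, i3);
              for (int cdd = 0; cdd < nd; ++cdd, ++bi) {
                int i4[3]; powers(D.l, cdd, i4);
                double E2x[4], E2y[4], E2z[4];
                for (int t = 0; t <= lcd; ++t) {
                  E2x[t] = Ecoef(i3[0], i4[0], t, CDx, c, d);
                  E2y[t] = Ecoef(i3[1], i4[1], t, CDy, c, d);
                  E2z[t] = Ecoef(i3[2], i4[2], t, CDz, c, d);
                }
                double acc = 0.0;
                for (int t = 0; t <= lab; ++t)
                for (int u = 0; u <= lab - t; ++u)
                for (int v = 0; v <= lab - t - u; ++v) {
                  double e1 = E1x[t] * E1y[u] * E1z[v];
                  if (e1 == 0.0) continue;
                  for (int tt = 0; tt <= lcd; ++tt)
                  for (int uu = 0; uu <= lcd - tt; ++uu)
                  for (int vv = 0; vv <= lcd - tt - uu; ++vv) {
                    double e2 = E2x[tt] * E2y[uu] * E2z[vv];
                    if (e2 == 0.0) continue;
                    double sgn = ((tt + uu + vv) % 2) ? -1.0 : 1.0;
                    acc += e1 * e2 * sgn
                         * Rherm(t + tt, u + uu, v + vv, 0, alpha,
                                 PQx, PQy, PQz, F);
                  }
                }
                block[bi] += pref * acc;
              }
            }
          }
        }
      }
    }
    // scatter with 8-fold permutational symmetry
    int bi = 0;
    long long N = n;
    for (int caa = 0; caa < na; ++caa)
    for (int cbb = 0; cbb < nb; ++cbb)
    for (int ccc = 0; ccc < nc; ++ccc)
    for (int cdd = 0; cdd < nd; ++cdd, ++bi) {
      long long mu = off[si] + caa, nu = off[sj] + cbb,
                la = off[sk] + ccc, sg = off[sl] + cdd;
      double v = block[bi];
      long long idx[8][4] = {
        {mu, nu, la, sg}, {nu, mu, la, sg}, {mu, nu, sg, la},
        {nu, mu, sg, la}, {la, sg, mu, nu}, {sg, la, mu, nu},
        {la, sg, nu, mu}, {sg, la, nu, mu}};
      for (int k = 0; k < 8; ++k)
        O[idx[k][0] + N * (idx[k][1] + N * (idx[k][2] + N * idx[k][3]))] = v;
    }
  }
  return out;
}

// AO dipole-moment integrals <mu| r_c |nu> about the origin, one matrix per
// Cartesian component (bohr).
// [[Rcpp::export(name = ".dipole_matrices")]]
List dipole_matrices(List shells) {
  std::vector<Shell> sh = parse_shells(shells);
  int n = nbf_total(sh);
  NumericMatrix MX(n, n), MY(n, n), MZ(n, n);
  int iof = 0;
  for (size_t si = 0; si < sh.size(); ++si) {
    int jof = 0;
    for (size_t sj = 0; sj < sh.size(); ++sj) {
      if (sj < si) { jof += sh[sj].nfun(); continue; }
      const Shell &A = sh[si], &B = sh[sj];
      double ABx = A.cx - B.cx, ABy = A.cy - B.cy, ABz = A.cz - B.cz;
      for (int ca = 0; ca < A.nfun(); ++ca) {
        int ia[3]; powers(A.l, ca, ia);
        for (int cb = 0; cb < B.nfun(); ++cb) {
          int ib[3]; powers(B.l, cb, ib);
          double vx = 0.0, vy = 0.0, vz = 0.0;
          for (size_t pa = 0; pa < A.exps.size(); ++pa) {
            for (size_t pb = 0; pb < B.exps.size(); ++pb) {
              double a = A.exps[pa], b = B.exps[pb];
              double p = a + b;
              double Px = (a * A.cx + b * B.cx) / p;
              double Py = (a * A.cy + b * B.cy) / p;
              double Pz = (a * A.cz + b * B.cz) / p;
              double pref = A.coefs[pa] * B.coefs[pb]
                          * std::pow(PI / p, 1.5);
              double sx = Ecoef(ia[0], ib[0], 0, ABx, a, b);
              double sy = Ecoef(ia[1], ib[1], 0, ABy, a, b);
              double sz = Ecoef(ia[2], ib[2], 0, ABz, a, b);
              // <x> = E_1 + Px E_0 along the chosen axis
              double mx = Ecoef(ia[0], ib[0], 1, ABx, a, b) + Px * sx;
              double my = Ecoef(ia[1], ib[1], 1, ABy, a, b) + Py * sy;
              double mz = Ecoef(ia[2], ib[2], 1, ABz, a, b) + Pz * sz;
              vx += pref * mx * sy * sz;
              vy += pref * sx * my * sz;
              vz += pref * sx * sy * mz;
            }
          }
          MX(iof + ca, jof + cb) = vx; MX(jof + cb, iof + ca) = vx;
          MY(iof + ca, jof + cb) = vy; MY(jof + cb, iof + ca) = vy;
          MZ(iof + ca, jof + cb) = vz; MZ(jof + cb, iof + ca) = vz;
        }
      }
      jof += sh[sj].nfun();
    }
    iof += sh[si].nfun();
  }
  return List::create(_["x"] = MX, _["y"] = MY, _["z"] = MZ);
}

// Coulomb and exchange matrices from a spin-summed density matrix D:
// J_{mn} = sum_{ls} D_{ls} (mn|ls),  K_{mn} = sum_{ls} D_{ls} (ml|ns).
// [[Rcpp::export(name = ".jk_build")]]
List jk_build(NumericVector eri, NumericMatrix D) {
  int n = D.nrow();
  long long N = n;
  const double* E = REAL(eri);
  NumericMatrix J(n, n), K(n, n);
  for (int m = 0; m < n; ++m)
    for (int nu = m; nu < n; ++nu) {
      double j = 0.0, k = 0.0;
      for (int l = 0; l < n; ++l)
        for (int s = 0; s < n; ++s) {
          double d = D(l, s);
          if (d == 0.0) continue;
          j += d * E[m + N * (nu + N * (l + N * s))];
          k += d * E[m + N * (l + N * (nu + N * s))];
        }
      J(m, nu) = j; J(nu, m) = j;
      K(m, nu) = k; K(nu, m) = k;
    }
  return List::create(_["J"] = J, _["K"] = K);
}

// Classical Coulomb sum between two point sets: sum_i sum_j qa_i qb_j / r_ij.
// [[Rcpp::export(name = ".pair_coulomb")]]
double pair_coulomb(NumericMatrix pa, NumericVector qa,
                    NumericMatrix pb, NumericVector qb) {
  double e = 0.0;
  for (int i = 0; i < pa.nrow(); ++i)
    for (int j = 0; j < pb.nrow(); ++j) {
      double dx = pa(i, 0) - pb(j, 0);
      double dy = pa(i, 1) - pb(j, 1);
      double dz = pa(i, 2) - pb(j, 2);
      e += qa[i] * qb[j] / std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  return e;
}
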