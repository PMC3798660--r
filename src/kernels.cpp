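#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 2D corotational Euler-Bernoulli beam + tension cable kernels.
// Unit system: micrometre (length), nanonewton (force), nN.um (moment);
// stresses then come out in nN/um^2 == kPa.

// Grid-binned proximity search: all unordered node pairs on distinct
// filaments with Euclidean distance strictly inside (rmin, rmax).  The
// lower bound reflects the physical size of a cross-linking protein; it
// also excludes coincident binding sites (which the translate-into-domain
// rule can produce at domain corners) whose zero-length cables would be
// degenerate.  Results match a brute-force double loop.
// [[Rcpp::export]]
IntegerMatrix cpp_proximity_pairs(NumericVector x, NumericVector y,
                                  IntegerVector fil, double rmax,
                                  double rmin) {
  const int n = x.size();
  std::vector<int> pi, pj;
  if (n > 1 && rmax > 0) {
    const double r2 = rmax * rmax;
    const double r2min = rmin * rmin;
    std::unordered_map<long long, std::vector<int> > grid;
    grid.reserve(2 * n);
    std::vector<long long> cellx(n), celly(n);
    for (int i = 0; i < n; ++i) {
      cellx[i] = (long long) std::floor(x[i] / rmax);
      celly[i] = (long long) std::floor(y[i] / rmax);
      long long key = cellx[i] * 2000003LL + celly[i];
      grid[key].push_back(i);
    }
    for (int i = 0; i < n; ++i) {
      for (long long dx = -1; dx <= 1; ++dx) {
        for (long long dy = -1; dy <= 1; ++dy) {
          long long key = (cellx[i] + dx) * 2000003LL + (celly[i] + dy);
          std::unordered_map<long long, std::vector<int> >::iterator it =
            grid.find(key);
          if (it == grid.end()) continue;
          const std::vector<int> &cell = it->second;
          for (size_t k = 0; k < cell.size(); ++k) {
            int j = cell[k];
            if (j <= i) continue;           // each unordered pair once
            if (fil[j] == fil[i]) continue; // distinct filaments only
            double ddx = x[j] - x[i], ddy = y[j] - y[i];
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 < r2 && d2 > r2min) { pi.push_back(i + 1); pj.push_back(j + 1); }
          }
        }
      }
    }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) { out(k, 0) = pi[k]; out(k, 1) = pj[k]; }
  return out;
}


// Tension-only elastic cable law with prestress offset, C1-smoothed at the
// slack point: with u = P + k (l - l0)/l0 the exact hinge max(0, u) is
// replaced by (u + sqrt(u^2 + delta^2))/2 with delta = 0.5 P, so that
// Newton iterations do not chatter on the slack set.  The smoothing
// perturbs tensions by at most delta/2 (0.75 pN at the default
// pre-stress); with P = 0 the law reduces to the exact hinge.
static inline void cable_elastic_law(double l, double L0, double P,
                                     double kcab, double *T, double *dT,
                                     double *V) {
  const double eps = (l - L0) / L0;
  const double u = P + kcab * eps;
  const double delta = 0.5 * P;
  if (delta > 0.0 && kcab > 0.0) {
    const double h = std::sqrt(u * u + delta * delta);
    *T = 0.5 * (u + h);
    *dT = 0.5 * (1.0 + u / h) * kcab / L0;
    if (V) *V = (L0 / kcab) *
      (0.25 * u * u + 0.25 * (u * h + delta * delta * std::asinh(u / delta)));
  } else {
    if (u > 0.0) {
      *T = u; *dT = kcab / L0;
      if (V) *V = L0 * (P * eps + 0.5 * kcab * eps * eps);
    } else {
      *T = 0.0; *dT = 0.0;
      if (V) *V = (kcab > 0.0) ? -L0 * P * P / (2.0 * kcab) : 0.0;
    }
  }
}

// Internal force vector, element forces, and (optionally) the consistent
// tangent as upper-triangle triplets, for the current configuration q =
// (ux1, uy1, th1, ux2, ...) holding *absolute* coordinates and rotations:
// q[3i] = x_i, q[3i+1] = y_i, q[3i+2] = theta_i.
//
// Beam: corotational decomposition about the chord.  With reference length
// L0 and reference chord angle beta0, current chord angle beta, the rigid
// rotation alpha = beta - beta0 (unwrapped to lie near the mean nodal
// rotation), local deformations are ubar = l - L0 and tbar_i = th_i - alpha.
// Local law: N = EA*ubar/L0, M1 = (EI/L0)(4 tbar1 + 2 tbar2),
// M2 = (EI/L0)(2 tbar1 + 4 tbar2).
//
// Cable (translational DOF only), tension-only:
//   mode 0 (constant force): T = P independent of length (smoothly
//     regularised to zero at lengths below cable_floor);
//   mode 1 (elastic):        T = max(0, P + k*(l - L0)/L0).
// Constant-force cables still contribute the geometric (reorientation)
// stiffness T/l, essential for form-finding convergence.
// [[Rcpp::export]]
List cpp_system(NumericVector q, int nnode,
                IntegerVector ba, IntegerVector bb,
                NumericVector bL0, NumericVector bBeta0,
                NumericVector bEA, NumericVector bEI,
                IntegerVector ca, IntegerVector cb, NumericVector cL0,
                int cable_mode, double P, double kcab, double cable_floor,
                bool want_tangent, bool psd_tangent) {
  const int nb = ba.size(), nc = ca.size();
  NumericVector f(3 * nnode);
  NumericVector N(nb), M1(nb), M2(nb), V(nb);
  NumericVector T(nc);
  double energy = 0.0;   // total internal potential (beams + cables)

  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    size_t cap = (size_t) nb * 21 + (size_t) nc * 10;
    ti.reserve(cap); tj.reserve(cap); tx.reserve(cap);
  }

  double a1[6], a2[6], b1[6], b2[6], fe[6], K[36];
  int dof[6];

  for (int e = 0; e < nb; ++e) {
    const int na = ba[e] - 1, nbn = bb[e] - 1;
    const double xa = q[3 * na], ya = q[3 * na + 1], tha = q[3 * na + 2];
    const double xb = q[3 * nbn], yb = q[3 * nbn + 1], thb = q[3 * nbn + 2];
    const double dx = xb - xa, dy = yb - ya;
    const double l = std::sqrt(dx * dx + dy * dy);
    if (l < 1e-12) stop("beam element %d has coincident end nodes", e + 1);
    const double c = dx / l, s = dy / l;
    const double L0 = bL0[e], EA = bEA[e], EI = bEI[e];
    double alpha = std::atan2(dy, dx) - bBeta0[e];
    const double thm = 0.5 * (tha + thb);
    alpha += 2.0 * M_PI * std::round((thm - alpha) / (2.0 * M_PI));
    const double t1 = tha - alpha, t2 = thb - alpha;
    const double ubar = l - L0;
    const double Ne = EA * ubar / L0;
    const double M1e = (EI / L0) * (4.0 * t1 + 2.0 * t2);
    const double M2e = (EI / L0) * (2.0 * t1 + 4.0 * t2);
    N[e] = Ne; M1[e] = M1e; M2[e] = M2e; V[e] = (M1e + M2e) / l;
    energy += 0.5 * (Ne * ubar + M1e * t1 + M2e * t2);

    a1[0] = -c; a1[1] = -s; a1[2] = 0; a1[3] = c; a1[4] = s; a1[5] = 0;
    a2[0] =  s; a2[1] = -c; a2[2] = 0; a2[3] = -s; a2[4] = c; a2[5] = 0;
    // b1 = d(tbar1)/dq = e3 - a2/l ; b2 = e6 - a2/l
    for (int k = 0; k < 6; ++k) { b1[k] = -a2[k] / l; b2[k] = b1[k]; }
    b1[2] += 1.0; b2[5] += 1.0;

    const double Msum = M1e + M2e;
    for (int k = 0; k < 6; ++k)
      fe[k] = Ne * a1[k] + M1e * b1[k] + M2e * b2[k];

    dof[0] = 3 * na; dof[1] = 3 * na + 1; dof[2] = 3 * na + 2;
    dof[3] = 3 * nbn; dof[4] = 3 * nbn + 1; dof[5] = 3 * nbn + 2;
    for (int k = 0; k < 6; ++k) f[dof[k]] += fe[k];

    if (want_tangent) {
      const double cEA = EA / L0, cEI = EI / L0;
      // psd_tangent: drop the sign-indefinite geometric terms (compressive
      // axial softening and the moment-chord coupling) so that the
      // assembled matrix is positive semi-definite by construction; the
      // residual stays exact, so equilibria are unchanged and only the
      // iteration path differs (modified Newton)
      const double Ngeo = psd_tangent ? std::max(Ne, 0.0) : Ne;
      const double Mgeo = psd_tangent ? 0.0 : Msum;
      for (int r = 0; r < 6; ++r)
        for (int cc = 0; cc < 6; ++cc)
          K[r * 6 + cc] =
            cEA * a1[r] * a1[cc] +
            cEI * (4.0 * b1[r] * b1[cc] + 2.0 * b1[r] * b2[cc] +
                   2.0 * b2[r] * b1[cc] + 4.0 * b2[r] * b2[cc]) +
            (Ngeo / l) * a2[r] * a2[cc] +
            (Mgeo / (l * l)) * (a1[r] * a2[cc] + a2[r] * a1[cc]);
      for (int r = 0; r < 6; ++r)
        for (int cc = 0; cc < 6; ++cc) {
          int gi = dof[r], gj = dof[cc];
          if (gi <= gj) { ti.push_back(gi + 1); tj.push_back(gj + 1); tx.push_back(K[r * 6 + cc]); }
        }
    }
  }

  double r4[4], g4[4], K4[16];
  int dof4[4];
  for (int e = 0; e < nc; ++e) {
    const int na = ca[e] - 1, nbn = cb[e] - 1;
    const double xa = q[3 * na], ya = q[3 * na + 1];
    const double xb = q[3 * nbn], yb = q[3 * nbn + 1];
    const double dx = xb - xa, dy = yb - ya;
    const double l = std::sqrt(dx * dx + dy * dy);
    if (l < 1e-12) stop("cable element %d has coincident end nodes", e + 1);
    const double c = dx / l, s = dy / l;
    double Te, dT;
    if (cable_mode == 0) {
      // constant tension, smoothly regularised near zero length
      // (T = P l / sqrt(l^2 + lf^2), potential P sqrt(l^2 + lf^2)) so that
      // a fully reeled-in cable reaches equilibrium instead of a
      // singularity; for l >> lf the tension is P to O((lf/l)^2)
      const double lf = cable_floor;
      const double h = std::sqrt(l * l + lf * lf);
      Te = P * l / h;
      dT = P * lf * lf / (h * h * h);
      energy += P * h;
    } else {
      double Vc;
      cable_elastic_law(l, cL0[e], P, kcab, &Te, &dT, &Vc);
      energy += Vc;
    }
    T[e] = Te;
    r4[0] = -c; r4[1] = -s; r4[2] = c; r4[3] = s;
    g4[0] =  s; g4[1] = -c; g4[2] = -s; g4[3] = c;
    dof4[0] = 3 * na; dof4[1] = 3 * na + 1; dof4[2] = 3 * nbn; dof4[3] = 3 * nbn + 1;
    for (int k = 0; k < 4; ++k) f[dof4[k]] += Te * r4[k];
    if (want_tangent && (Te > 0.0 || dT > 0.0)) {
      for (int r = 0; r < 4; ++r)
        for (int cc = 0; cc < 4; ++cc)
          K4[r * 4 + cc] = dT * r4[r] * r4[cc] + (Te / l) * g4[r] * g4[cc];
      for (int r = 0; r < 4; ++r)
        for (int cc = 0; cc < 4; ++cc) {
          int gi = dof4[r], gj = dof4[cc];
          if (gi <= gj) { ti.push_back(gi + 1); tj.push_back(gj + 1); tx.push_back(K4[r * 4 + cc]); }
        }
    }
  }

  List out = List::create(_["f"] = f, _["N"] = N, _["M1"] = M1, _["M2"] = M2,
                          _["V"] = V, _["T"] = T, _["energy"] = energy);
  if (want_tangent) {
    out["i"] = IntegerVector(ti.begin(), ti.end());
    out["j"] = IntegerVector(tj.begin(), tj.end());
    out["x"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}

// ---- statically condensed assembly ------------------------------------
//
// Rotational DOF couple only along a filament chain (cables attach to
// translations), so the theta-theta block of the tangent is symmetric
// tridiagonal per filament and always positive definite (pure bending
// stiffness, diagonally dominant).  Exact block elimination gives a
// translation-only system with identical Newton iterates at 2/3 the DOF:
//   K_red = K_tt - K_ttheta A^-1 K_theta t,   with A = K_theta theta
//   rhs correction c_t = K_ttheta A^-1 r_theta.
// Chains must have consecutive node ids (the generator guarantees this);
// chain_first[f] is the first (1-based) node of filament f and bfil maps
// each beam to its (1-based) filament index in chain order.

// tridiagonal LDL factor/solve helpers (in place)
static void tri_factor(std::vector<double> &a, std::vector<double> &b) {
  const int n = (int) a.size();
  for (int i = 0; i < n - 1; ++i) {
    b[i] /= a[i];
    a[i + 1] -= b[i] * b[i] * a[i];
  }
}
static void tri_solve(const std::vector<double> &a,
                      const std::vector<double> &b, double *x) {
  const int n = (int) a.size();
  for (int i = 1; i < n; ++i) x[i] -= b[i - 1] * x[i - 1];
  for (int i = 0; i < n; ++i) x[i] /= a[i];
  for (int i = n - 2; i >= 0; --i) x[i] -= b[i] * x[i + 1];
}

// shared beam evaluation: fills fe[6] and (optionally) K[36]
static void beam_eval(const double *q, int na, int nb,
                      double L0, double beta0, double EA, double EI,
                      double *fe, double *K, bool want_K,
                      double *Ne_out, double *M1_out, double *M2_out,
                      double *l_out) {
  const double xa = q[3 * na], ya = q[3 * na + 1], tha = q[3 * na + 2];
  const double xb = q[3 * nb], yb = q[3 * nb + 1], thb = q[3 * nb + 2];
  const double dx = xb - xa, dy = yb - ya;
  const double l = std::sqrt(dx * dx + dy * dy);
  if (l < 1e-12) stop("beam element has coincident end nodes");
  const double c = dx / l, s = dy / l;
  double alpha = std::atan2(dy, dx) - beta0;
  const double thm = 0.5 * (tha + thb);
  alpha += 2.0 * M_PI * std::round((thm - alpha) / (2.0 * M_PI));
  const double t1 = tha - alpha, t2 = thb - alpha;
  const double ubar = l - L0;
  const double Ne = EA * ubar / L0;
  const double M1e = (EI / L0) * (4.0 * t1 + 2.0 * t2);
  const double M2e = (EI / L0) * (2.0 * t1 + 4.0 * t2);
  double a1[6], a2[6], b1[6], b2[6];
  a1[0] = -c; a1[1] = -s; a1[2] = 0; a1[3] = c; a1[4] = s; a1[5] = 0;
  a2[0] =  s; a2[1] = -c; a2[2] = 0; a2[3] = -s; a2[4] = c; a2[5] = 0;
  for (int k = 0; k < 6; ++k) { b1[k] = -a2[k] / l; b2[k] = b1[k]; }
  b1[2] += 1.0; b2[5] += 1.0;
  const double Msum = M1e + M2e;
  for (int k = 0; k < 6; ++k)
    fe[k] = Ne * a1[k] + M1e * b1[k] + M2e * b2[k];
  if (want_K) {
    const double cEA = EA / L0, cEI = EI / L0;
    for (int r = 0; r < 6; ++r)
      for (int cc = 0; cc < 6; ++cc)
        K[r * 6 + cc] =
          cEA * a1[r] * a1[cc] +
          cEI * (4.0 * b1[r] * b1[cc] + 2.0 * b1[r] * b2[cc] +
                 2.0 * b2[r] * b1[cc] + 4.0 * b2[r] * b2[cc]) +
          (Ne / l) * a2[r] * a2[cc] +
          (Msum / (l * l)) * (a1[r] * a2[cc] + a2[r] * a1[cc]);
  }
  *Ne_out = Ne; *M1_out = M1e; *M2_out = M2e; *l_out = l;
}

// [[Rcpp::export]]
List cpp_system_condensed(NumericVector q, int nnode,
                          IntegerVector ba, IntegerVector bb,
                          NumericVector bL0, NumericVector bBeta0,
                          NumericVector bEA, NumericVector bEI,
                          IntegerVector bfil, IntegerVector chain_first,
                          IntegerVector chain_len,
                          IntegerVector ca, IntegerVector cb,
                          NumericVector cL0,
                          int cable_mode, double P, double kcab,
                          double cable_floor, double rot_reg,
                          NumericVector r_extra) {
  const int nb = ba.size(), nc = ca.size(), nf = chain_first.size();
  NumericVector f(3 * nnode);       // full residual (internal forces)
  NumericVector ct(2 * nnode);      // Schur rhs correction on translations
  double energy = 0.0;
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve((size_t) nb * 10 + (size_t) nc * 10 + (size_t) nf * 2500);
  tj.reserve(ti.capacity());
  tx.reserve(ti.capacity());

  double fe[6], K[36];
  double Ne, M1e, M2e, l;
  const bool have_extra = r_extra.size() == 3 * nnode;

  int e = 0;
  for (int fidx = 0; fidx < nf; ++fidx) {
    const int first = chain_first[fidx] - 1;   // 0-based first node
    const int nn = chain_len[fidx];            // nodes in chain
    const int m = nn - 1;                      // beams in chain
    const int ntr = 2 * nn;                    // chain translation dofs
    std::vector<double> A(nn, rot_reg), Bd(std::max(m, 0), 0.0);
    std::vector<double> Bmat((size_t) nn * ntr, 0.0);
    std::vector<double> rth(nn, 0.0);
    // assemble chain
    for (int j = 0; j < m; ++j, ++e) {
      const int na = ba[e] - 1, nbn = bb[e] - 1;
      beam_eval(q.begin(), na, nbn, bL0[e], bBeta0[e], bEA[e], bEI[e],
                fe, K, true, &Ne, &M1e, &M2e, &l);
      // local chain indices
      const int ia = na - first, ib = nbn - first;
      // forces
      int dof[6] = {3 * na, 3 * na + 1, 3 * na + 2,
                    3 * nbn, 3 * nbn + 1, 3 * nbn + 2};
      for (int k = 0; k < 6; ++k) f[dof[k]] += fe[k];
      // theta-theta tridiagonal
      A[ia] += K[2 * 6 + 2];
      A[ib] += K[5 * 6 + 5];
      Bd[std::min(ia, ib)] += K[2 * 6 + 5];
      // K_theta,t into Bmat: rows ia/ib, cols = chain translations
      const int tc[4] = {0, 1, 3, 4};             // element translation slots
      const int cc4[4] = {2 * ia, 2 * ia + 1, 2 * ib, 2 * ib + 1};
      for (int k = 0; k < 4; ++k) {
        Bmat[(size_t) ia * ntr + cc4[k]] += K[2 * 6 + tc[k]];
        Bmat[(size_t) ib * ntr + cc4[k]] += K[5 * 6 + tc[k]];
      }
      // K_tt triplets (global 2-dof indexing)
      const int g2[4] = {2 * na, 2 * na + 1, 2 * nbn, 2 * nbn + 1};
      for (int r = 0; r < 4; ++r)
        for (int cq = 0; cq < 4; ++cq) {
          int gi = g2[r], gj = g2[cq];
          if (gi <= gj) {
            ti.push_back(gi + 1); tj.push_back(gj + 1);
            tx.push_back(K[tc[r] * 6 + tc[cq]]);
          }
        }
      // energy (beam): 0.5 (N ubar + M1 t1 + M2 t2); recover t1, t2
      {
        const double L0e = bL0[e], EIe = bEI[e];
        // invert local law: [4 2;2 4] (EI/L) t = M  ->  t = L/(12 EI) [4 -2;-2 4] M... wait: inv([4 2;2 4]) = 1/12 [4 -2; -2 4]
        const double c0 = L0e / (12.0 * EIe);
        const double t1 = c0 * (4.0 * M1e - 2.0 * M2e);
        const double t2 = c0 * (-2.0 * M1e + 4.0 * M2e);
        energy += 0.5 * (Ne * (l - L0e) + M1e * t1 + M2e * t2);
      }
    }
    // chain theta residual (internal + extra)
    for (int i = 0; i < nn; ++i) {
      rth[i] = f[3 * (first + i) + 2];
      if (have_extra) rth[i] += r_extra[3 * (first + i) + 2];
    }
    if (m >= 0 && nn > 0) {
      tri_factor(A, Bd);
      // y = A^-1 r_theta ; ct_chain = B^T y
      std::vector<double> ycol(rth);
      tri_solve(A, Bd, ycol.data());
      for (int cq = 0; cq < ntr; ++cq) {
        double acc = 0.0;
        for (int i = 0; i < nn; ++i) acc += Bmat[(size_t) i * ntr + cq] * ycol[i];
        const int node = first + cq / 2, comp = cq % 2;
        ct[2 * node + comp] += acc;
      }
      // Z = A^-1 B, D = B^T Z, emit -D
      std::vector<double> Z(Bmat);
      for (int cq = 0; cq < ntr; ++cq) {
        std::vector<double> col(nn);
        for (int i = 0; i < nn; ++i) col[i] = Bmat[(size_t) i * ntr + cq];
        tri_solve(A, Bd, col.data());
        for (int i = 0; i < nn; ++i) Z[(size_t) i * ntr + cq] = col[i];
      }
      for (int r = 0; r < ntr; ++r) {
        const int gnr = 2 * (first + r / 2) + r % 2;
        for (int cq = r; cq < ntr; ++cq) {
          double acc = 0.0;
          for (int i = 0; i < nn; ++i)
            acc += Bmat[(size_t) i * ntr + r] * Z[(size_t) i * ntr + cq];
          if (acc != 0.0) {
            const int gnc = 2 * (first + cq / 2) + cq % 2;
            int gi = gnr, gj = gnc;
            if (gi > gj) { int t = gi; gi = gj; gj = t; }
            ti.push_back(gi + 1); tj.push_back(gj + 1); tx.push_back(-acc);
          }
        }
      }
    }
  }

  // cables (translations only), same laws as cpp_system
  NumericVector T(nc);
  double r4[4], g4[4], K4[16];
  for (int ec = 0; ec < nc; ++ec) {
    const int na = ca[ec] - 1, nbn = cb[ec] - 1;
    const double dx = q[3 * nbn] - q[3 * na], dy = q[3 * nbn + 1] - q[3 * na + 1];
    const double l2 = std::sqrt(dx * dx + dy * dy);
    if (l2 < 1e-12) stop("cable element has coincident end nodes");
    const double c = dx / l2, s = dy / l2;
    double Te, dT;
    if (cable_mode == 0) {
      const double lf = cable_floor;
      const double h = std::sqrt(l2 * l2 + lf * lf);
      Te = P * l2 / h;
      dT = P * lf * lf / (h * h * h);
      energy += P * h;
    } else {
      double Vc;
      cable_elastic_law(l2, cL0[ec], P, kcab, &Te, &dT, &Vc);
      energy += Vc;
    }
    T[ec] = Te;
    r4[0] = -c; r4[1] = -s; r4[2] = c; r4[3] = s;
    g4[0] =  s; g4[1] = -c; g4[2] = -s; g4[3] = c;
    int dof3[4] = {3 * na, 3 * na + 1, 3 * nbn, 3 * nbn + 1};
    int g2[4] = {2 * na, 2 * na + 1, 2 * nbn, 2 * nbn + 1};
    for (int k = 0; k < 4; ++k) f[dof3[k]] += Te * r4[k];
    if (Te > 0.0 || dT > 0.0) {
      for (int r = 0; r < 4; ++r)
        for (int cq = 0; cq < 4; ++cq)
          K4[r * 4 + cq] = dT * r4[r] * r4[cq] + (Te / l2) * g4[r] * g4[cq];
      for (int r = 0; r < 4; ++r)
        for (int cq = 0; cq < 4; ++cq) {
          int gi = g2[r], gj = g2[cq];
          if (gi <= gj) { ti.push_back(gi + 1); tj.push_back(gj + 1); tx.push_back(K4[r * 4 + cq]); }
        }
    }
  }

  return List::create(_["f"] = f, _["ct"] = ct, _["T"] = T,
                      _["energy"] = energy,
                      _["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tx.begin(), tx.end()));
}

// Rotation increment recovery: dtheta = -A^-1 (r_theta + B dq_t), chainwise
// at the same configuration q used for the condensed assembly.
// [[Rcpp::export]]
NumericVector cpp_recover_rotations(NumericVector q, int nnode,
                                    IntegerVector ba, IntegerVector bb,
                                    NumericVector bL0, NumericVector bBeta0,
                                    NumericVector bEA, NumericVector bEI,
                                    IntegerVector chain_first,
                                    IntegerVector chain_len,
                                    double rot_reg,
                                    NumericVector rtheta_full,
                                    NumericVector dqt) {
  const int nf = chain_first.size();
  NumericVector dth(nnode);
  double fe[6], K[36];
  double Ne, M1e, M2e, l;
  int e = 0;
  for (int fidx = 0; fidx < nf; ++fidx) {
    const int first = chain_first[fidx] - 1;
    const int nn = chain_len[fidx];
    const int m = nn - 1;
    const int ntr = 2 * nn;
    std::vector<double> A(nn, rot_reg), Bd(std::max(m, 0), 0.0);
    std::vector<double> Bmat((size_t) nn * ntr, 0.0);
    for (int j = 0; j < m; ++j, ++e) {
      const int na = ba[e] - 1, nbn = bb[e] - 1;
      beam_eval(q.begin(), na, nbn, bL0[e], bBeta0[e], bEA[e], bEI[e],
                fe, K, true, &Ne, &M1e, &M2e, &l);
      const int ia = na - first, ib = nbn - first;
      A[ia] += K[2 * 6 + 2];
      A[ib] += K[5 * 6 + 5];
      Bd[std::min(ia, ib)] += K[2 * 6 + 5];
      const int tc[4] = {0, 1, 3, 4};
      const int cc4[4] = {2 * ia, 2 * ia + 1, 2 * ib, 2 * ib + 1};
      for (int k = 0; k < 4; ++k) {
        Bmat[(size_t) ia * ntr + cc4[k]] += K[2 * 6 + tc[k]];
        Bmat[(size_t) ib * ntr + cc4[k]] += K[5 * 6 + tc[k]];
      }
    }
    std::vector<double> rhs(nn);
    for (int i = 0; i < nn; ++i) {
      double acc = rtheta_full[first + i];
      for (int cq = 0; cq < ntr; ++cq) {
        const int node = first + cq / 2, comp = cq % 2;
        acc += Bmat[(size_t) i * ntr + cq] * dqt[2 * node + comp];
      }
      rhs[i] = acc;
    }
    tri_factor(A, Bd);
    tri_solve(A, Bd, rhs.data());
    for (int i = 0; i < nn; ++i) dth[first + i] = -rhs[i];
  }
  return dth;
}

// Matrix-free tangent-vector product K(q) * v (full 3n DOF, no BCs; the
// caller projects fixed DOF).  Used by the Newton-PCG form-finding path,
// where assembling and factorising the full tangent would dominate the
// cost.
// [[Rcpp::export]]
NumericVector cpp_tangent_matvec(NumericVector q, int nnode,
                                 IntegerVector ba, IntegerVector bb,
                                 NumericVector bL0, NumericVector bBeta0,
                                 NumericVector bEA, NumericVector bEI,
                                 IntegerVector ca, IntegerVector cb,
                                 NumericVector cL0,
                                 int cable_mode, double P, double kcab,
                                 double cable_floor,
                                 NumericVector v) {
  const int nb = ba.size(), nc = ca.size();
  NumericVector out(3 * nnode);
  double fe[6], K[36];
  double Ne, M1e, M2e, l;
  for (int e = 0; e < nb; ++e) {
    const int na = ba[e] - 1, nbn = bb[e] - 1;
    beam_eval(q.begin(), na, nbn, bL0[e], bBeta0[e], bEA[e], bEI[e],
              fe, K, true, &Ne, &M1e, &M2e, &l);
    const int dof[6] = {3 * na, 3 * na + 1, 3 * na + 2,
                        3 * nbn, 3 * nbn + 1, 3 * nbn + 2};
    double vl[6];
    for (int k = 0; k < 6; ++k) vl[k] = v[dof[k]];
    for (int r = 0; r < 6; ++r) {
      double acc = 0.0;
      for (int c = 0; c < 6; ++c) acc += K[r * 6 + c] * vl[c];
      out[dof[r]] += acc;
    }
  }
  for (int e = 0; e < nc; ++e) {
    const int na = ca[e] - 1, nbn = cb[e] - 1;
    const double dx = q[3 * nbn] - q[3 * na];
    const double dy = q[3 * nbn + 1] - q[3 * na + 1];
    const double l2 = std::sqrt(dx * dx + dy * dy);
    if (l2 < 1e-12) stop("cable element has coincident end nodes");
    const double c = dx / l2, s = dy / l2;
    double Te, dT;
    if (cable_mode == 0) {
      const double lf = cable_floor;
      const double h = std::sqrt(l2 * l2 + lf * lf);
      Te = P * l2 / h;
      dT = P * lf * lf / (h * h * h);
    } else {
      cable_elastic_law(l2, cL0[e], P, kcab, &Te, &dT, (double *) 0);
    }
    if (Te == 0.0 && dT == 0.0) continue;
    const double r4[4] = {-c, -s, c, s};
    const double g4[4] = {s, -c, -s, c};
    const int dof4[4] = {3 * na, 3 * na + 1, 3 * nbn, 3 * nbn + 1};
    double vr = 0.0, vg = 0.0;
    for (int k = 0; k < 4; ++k) { vr += r4[k] * v[dof4[k]]; vg += g4[k] * v[dof4[k]]; }
    const double ar = dT * vr, ag = (Te / l2) * vg;
    for (int k = 0; k < 4; ++k) out[dof4[k]] += ar * r4[k] + ag * g4[k];
  }
  return out;
}

// Diagonal of the cable part of the tangent (translations), for the
// beams-plus-cable-diagonal preconditioner.
// [[Rcpp::export]]
NumericVector cpp_cable_diag(NumericVector q, int nnode,
                             IntegerVector ca, IntegerVector cb,
                             NumericVector cL0,
                             int cable_mode, double P, double kcab,
                             double cable_floor) {
  const int nc = ca.size();
  NumericVector d(3 * nnode);
  for (int e = 0; e < nc; ++e) {
    const int na = ca[e] - 1, nbn = cb[e] - 1;
    const double dx = q[3 * nbn] - q[3 * na];
    const double dy = q[3 * nbn + 1] - q[3 * na + 1];
    const double l2 = std::sqrt(dx * dx + dy * dy);
    if (l2 < 1e-12) stop("cable element has coincident end nodes");
    const double c = dx / l2, s = dy / l2;
    double Te, dT;
    if (cable_mode == 0) {
      const double lf = cable_floor;
      const double h = std::sqrt(l2 * l2 + lf * lf);
      Te = P * l2 / h;
      dT = P * lf * lf / (h * h * h);
    } else {
      cable_elastic_law(l2, cL0[e], P, kcab, &Te, &dT, (double *) 0);
    }
    const double dxx = dT * c * c + (Te / l2) * s * s;
    const double dyy = dT * s * s + (Te / l2) * c * c;
    d[3 * na] += dxx; d[3 * na + 1] += dyy;
    d[3 * nbn] += dxx; d[3 * nbn + 1] += dyy;
  }
  return d;
}

// Greedy closest-first matching on the candidate pair list: each binding
// site hosts at most `capacity` cross-linkers; pairs are taken in order of
// increasing separation.  ord is a 1-based permutation sorting the pairs
// by distance.
// [[Rcpp::export]]
LogicalVector cpp_greedy_capacity(IntegerVector pa, IntegerVector pb,
                                  IntegerVector ord, int nnode,
                                  int capacity) {
  const int m = pa.size();
  LogicalVector keep(m);
  std::vector<int> used(nnode, 0);
  for (int k = 0; k < m; ++k) {
    const int e = ord[k] - 1;
    const int a = pa[e] - 1, b = pb[e] - 1;
    if (used[a] < capacity && used[b] < capacity) {
      keep[e] = true;
      ++used[a]; ++used[b];
    }
  }
  return keep;
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Return freed allocator arenas to the operating system.  The sparse
// factorisations allocate and free hundreds of megabytes outside R's
// heap; glibc retains those arenas by default, which inflates resident
// memory across repeated solves.
// [[Rcpp::export]]
void cpp_malloc_trim() {
#ifdef __GLIBC__
  malloc_trim(0);
#endif
}
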