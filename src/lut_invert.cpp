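#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Inverse bilinear interpolation of a forward lookup table.
//
// The table holds diffuse reflectance R0 (planar) and Rn (modulated) on a
// rectangular (mu_a, mu_s') grid.  Over the supported domain R0 is strictly
// decreasing in mu_a and non-decreasing in mu_s', so each physical
// reflectance pair has a unique preimage, located by nested monotone root
// finding in continuous grid coordinates (a, b):
//
//   1. the admissible interval [a_min, a_max] of mu_a rows on which the
//      R0 = r0 contour exists is found by bisecting the monotone edge
//      profiles R0(a, b = 0) and R0(a, b = Q-1);
//   2. within a row, R0(a, .) is piecewise linear and monotone in b, so
//      b(a) follows from a binary segment search and one exact linear
//      solve;
//   3. the residual Rn(a, b(a)) - rn is monotone across the admissible
//      interval and is bisected to ~1e-12 of a grid cell.
//
// Grid nodes are recovered exactly up to bisection tolerance.  Queries off
// the forward-mapped manifold are answered with the nearest clamped
// solution and flagged out-of-domain (status 1); non-finite inputs get
// status 2.

namespace {

struct Lut {
  const double *R0, *Rn;
  int P, Q;

  inline double r0_at(double a, int j) const {
    int i = static_cast<int>(a);
    if (i > P - 2) i = P - 2;
    const double fa = a - i;
    return (1.0 - fa) * R0[i + j * P] + fa * R0[i + 1 + j * P];
  }
  inline double rn_at(double a, double b) const {
    int i = static_cast<int>(a);
    if (i > P - 2) i = P - 2;
    int j = static_cast<int>(b);
    if (j > Q - 2) j = Q - 2;
    const double fa = a - i, fb = b - j;
    const double v0 = (1.0 - fa) * Rn[i + j * P] + fa * Rn[i + 1 + j * P];
    const double v1 =
        (1.0 - fa) * Rn[i + (j + 1) * P] + fa * Rn[i + 1 + (j + 1) * P];
    return (1.0 - fb) * v0 + fb * v1;
  }

  // solve R0(a, b) = r0 for b within a row; caller guarantees r0 lies
  // inside [R0(a, 0), R0(a, Q-1)] up to clamping
  double solve_b(double a, double r0) const {
    double lo = r0_at(a, 0), hi = r0_at(a, Q - 1);
    if (r0 <= lo) return 0.0;
    if (r0 >= hi) return Q - 1.0;
    int jlo = 0, jhi = Q - 1;  // invariant: f(jlo) <= r0 < f(jhi)
    while (jhi - jlo > 1) {
      const int jm = (jlo + jhi) / 2;
      if (r0_at(a, jm) <= r0) jlo = jm; else jhi = jm;
    }
    const double f0 = r0_at(a, jlo), f1 = r0_at(a, jlo + 1);
    const double df = f1 - f0;
    return jlo + (df > 0 ? (r0 - f0) / df : 0.5);
  }

  // largest a with edge(a) >= r0, for a monotone-decreasing edge profile
  // R0(a, j_edge); returns -1 if even a = 0 is below r0
  double edge_crossing(int j_edge, double r0) const {
    double glo = r0_at(0.0, j_edge);
    if (glo < r0) return -1.0;
    double ghi = r0_at(P - 1.0, j_edge);
    if (ghi >= r0) return P - 1.0;
    double alo = 0.0, ahi = P - 1.0;
    for (int it = 0; it < 60 && ahi - alo > 1e-12; ++it) {
      const double am = 0.5 * (alo + ahi);
      if (r0_at(am, j_edge) >= r0) alo = am; else ahi = am;
    }
    return 0.5 * (alo + ahi);
  }
};

}  // namespace

// [[Rcpp::export(name = ".lut_invert")]]
List lut_invert_cpp(NumericVector mu_a_axis, NumericVector mu_s_axis,
                    NumericMatrix R0, NumericMatrix Rn,
                    NumericVector r0q, NumericVector rnq) {
  const int P = mu_a_axis.size(), Q = mu_s_axis.size();
  if (R0.nrow() != P || R0.ncol() != Q || Rn.nrow() != P || Rn.ncol() != Q)
    stop("reflectance tables must be P x Q");
  const R_xlen_t n = r0q.size();
  if (rnq.size() != n) stop("R0 and Rn query vectors must have equal length");

  Lut lut{REAL(R0), REAL(Rn), P, Q};
  NumericVector mua(n), mus(n);
  IntegerVector status(n);
  const double ha = (mu_a_axis[P - 1] - mu_a_axis[0]) / (P - 1);
  const double hb = (mu_s_axis[Q - 1] - mu_s_axis[0]) / (Q - 1);

  for (R_xlen_t q = 0; q < n; ++q) {
    const double r0 = r0q[q], rn = rnq[q];
    if (!std::isfinite(r0) || !std::isfinite(rn)) {
      mua[q] = NA_REAL; mus[q] = NA_REAL; status[q] = 2;
      continue;
    }
    int flag = 0;

    // admissible mu_a interval on which the R0 = r0 contour exists: the
    // contour needs R0(a, 0) <= r0 <= R0(a, Q-1), and both edge profiles
    // decrease in a, so each condition is a single monotone crossing
    const double c0 = lut.edge_crossing(0, r0);      // last a with R0(a,0) >= r0
    const double cQ = lut.edge_crossing(Q - 1, r0);  // last a with R0(a,Q-1) >= r0
    double a_lo = (c0 < 0.0) ? 0.0 : c0;   // first admissible row
    double a_hi = (cQ < 0.0) ? 0.0 : cQ;   // last admissible row
    if (cQ < 0.0) flag = 1;                // r0 above the whole manifold
    if (a_hi < a_lo) { const double t = a_lo; a_lo = a_hi; a_hi = t; flag = 1; }

    double glo = lut.rn_at(a_lo, lut.solve_b(a_lo, r0)) - rn;
    double ghi = lut.rn_at(a_hi, lut.solve_b(a_hi, r0)) - rn;
    double a;
    if (glo == 0.0) a = a_lo;
    else if (ghi == 0.0) a = a_hi;
    else if (glo * ghi > 0.0) {
      // no sign change on the admissible interval: off the manifold
      a = (std::fabs(glo) <= std::fabs(ghi)) ? a_lo : a_hi;
      flag = 1;
    } else {
      double lo = a_lo, hi = a_hi;
      for (int it = 0; it < 60 && hi - lo > 1e-12; ++it) {
        const double am = 0.5 * (lo + hi);
        const double gm = lut.rn_at(am, lut.solve_b(am, r0)) - rn;
        if (gm == 0.0) { lo = hi = am; break; }
        if (glo * gm < 0.0) { hi = am; }
        else { lo = am; glo = gm; }
      }
      a = 0.5 * (lo + hi);
    }

    const double b = lut.solve_b(a, r0);
    mua[q] = mu_a_axis[0] + a * ha;
    mus[q] = mu_s_axis[0] + b * hb;
    status[q] = flag;
  }

  return List::create(_["mu_a"] = mua, _["mu_s_prime"] = mus,
                      _["status"] = status);
}
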