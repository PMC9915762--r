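// Hartigan dip statistic: minimal sup-distance between the empirical CDF
// and the class of unimodal CDFs (convex below the mode, concave above,
// at most one jump, located at the mode).
//
// Computation: bisection on the tolerance d. For a given d the empirical
// CDF step values a_i (upper) and b_i (lower) define bands
// [l_i, u_i] = [a_i - d, b_i + d] at the unique sample points. A unimodal
// G within d exists iff for some mode position the convex branch fits the
// bands left of the mode, the concave branch fits them on the right, and
// the two branches can be joined: the convex branch's minimal forward
// extension V(t) (limited from below by chord slopes (l_j - u_i)/(x_j -
// x_i)) must pass under the gap band and under the concave branch's
// maximal backward extension W(t). Modes strictly inside a gap and modes
// at a sample point (where the band upper bound relaxes from b_j + d to
// a_j + d on the concave side) are both examined.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Bands {
  std::vector<double> x, a, b;  // unique points, upper and lower steps
  int m;
};

// greatest convex minorant of (x, y) over indices [0, k): fitted values
static void gcmFit(const std::vector<double>& x,
                   const std::vector<double>& y, int k,
                   std::vector<double>& fit) {
  std::vector<int> hull;
  for (int i = 0; i < k; ++i) {
    while (hull.size() >= 2) {
      int a1 = hull[hull.size() - 2], b1 = hull.back();
      if ((y[i] - y[a1]) * (x[b1] - x[a1]) <
          (y[b1] - y[a1]) * (x[i] - x[a1]))
        hull.pop_back();
      else break;
    }
    hull.push_back(i);
  }
  for (size_t s = 0; s + 1 < hull.size(); ++s) {
    int p = hull[s], q = hull[s + 1];
    for (int i = p; i <= q; ++i)
      fit[i] = y[p] + (y[q] - y[p]) * (x[i] - x[p]) / (x[q] - x[p]);
  }
  if (hull.size() == 1) fit[hull[0]] = y[hull[0]];
}

// largest prefix length k such that a convex function fits the bands at
// points 0..k-1 (gcm of upper band >= lower band)
static int maxFeasPrefix(const Bands& B, double d) {
  int m = B.m;
  std::vector<double> u(m), l(m), fit(m);
  for (int i = 0; i < m; ++i) { u[i] = B.b[i] + d; l[i] = B.a[i] - d; }
  // incremental would be faster; m is modest so refit per prefix length
  // is avoided by one full fit + check monotone property via scan
  int best = 0;
  for (int k = 1; k <= m; ++k) {
    gcmFit(B.x, u, k, fit);
    bool ok = true;
    for (int i = 0; i < k && ok; ++i) if (fit[i] < l[i] - 1e-12) ok = false;
    if (ok) best = k; else break;  // feasibility is monotone in k
  }
  return best;
}

static int maxFeasSuffix(const Bands& B, double d) {
  // mirror: concave fit over suffix; reflect and reuse
  int m = B.m;
  Bands R;
  R.m = m;
  R.x.resize(m); R.a.resize(m); R.b.resize(m);
  for (int i = 0; i < m; ++i) {
    R.x[i] = -B.x[m - 1 - i];
    // reflected CDF: steps mirror, upper<->lower roles swap around 1
    R.a[i] = 1.0 - B.b[m - 1 - i];
    R.b[i] = 1.0 - B.a[m - 1 - i];
  }
  return maxFeasPrefix(R, d);
}

// forward-extension slope floor for each left point j:
// sL[j] = max(0, max_{i<j} (l_j - u_i)/(x_j - x_i))
static void slopeL(const Bands& B, double d, std::vector<double>& sL) {
  int m = B.m;
  sL.assign(m, 0.0);
  for (int j = 1; j < m; ++j) {
    double lj = B.a[j] - d, best = 0.0;
    for (int i = 0; i < j; ++i) {
      double s = (lj - (B.b[i] + d)) / (B.x[j] - B.x[i]);
      if (s > best) best = s;
    }
    sL[j] = best;
  }
}

static void slopeR(const Bands& B, double d, std::vector<double>& sR) {
  int m = B.m;
  sR.assign(m, 0.0);
  for (int p = 0; p < m - 1; ++p) {
    double up = B.b[p] + d, best = 0.0;
    for (int q = p + 1; q < m; ++q) {
      double s = ((B.a[q] - d) - up) / (B.x[q] - B.x[p]);
      if (s > best) best = s;
    }
    sR[p] = best;
  }
}

// V_k(t): minimal value at t >= x_{k-1} of a convex branch through bands
// 0..k-1 (k >= 1); monotone nondecreasing in t
static double evalV(const Bands& B, double d,
                    const std::vector<double>& sL, int k, double t) {
  double v = 0.0;
  for (int j = 0; j < k; ++j) {
    double c = (B.a[j] - d) + sL[j] * (t - B.x[j]);
    if (c > v) v = c;
  }
  return v;
}

// W_k(t): maximal value at t <= x_k of a concave branch through bands
// k..m-1; uses relaxed upper band a_k + d at its first point when
// pointMode is true
static double evalW(const Bands& B, double d,
                    const std::vector<double>& sR, int k, double t,
                    bool pointMode) {
  double w = 1.0 + d;
  for (int p = k; p < B.m; ++p) {
    double up = (pointMode && p == k) ? (B.a[p] + d) : (B.b[p] + d);
    double c = up - sR[p] * (B.x[p] - t);
    if (c < w) w = c;
  }
  return w;
}

static bool junctionGap(const Bands& B, double d,
                        const std::vector<double>& sL,
                        const std::vector<double>& sR, int k) {
  int m = B.m;
  double agap = (k >= 1) ? B.a[k - 1] : 0.0;
  double cA = agap + d, cB = agap - d;
  if (k == 0) {
    // mode before the first point: V = 0; need W(t) >= cB as t -> x_0
    return evalW(B, d, sR, 0, B.x[0], false) >= cB - 1e-12;
  }
  if (k == m) {
    // mode after the last point: need V(t) <= cA at t -> x_{m-1}
    return evalV(B, d, sL, m, B.x[m - 1]) <= cA + 1e-12;
  }
  double tlo = B.x[k - 1], thi = B.x[k];
  // (A) V(t) <= cA: closed-form upper limit on t per support line
  for (int j = 0; j < k; ++j) {
    double lj = B.a[j] - d;
    if (sL[j] > 0) {
      double t = B.x[j] + (cA - lj) / sL[j];
      if (t < thi) thi = t;
    } else if (lj > cA + 1e-12) return false;
  }
  // (B) W(t) >= cB: closed-form lower limit on t
  for (int p = k; p < m; ++p) {
    double up = B.b[p] + d;
    if (sR[p] > 0) {
      double t = B.x[p] - (up - cB) / sR[p];
      if (t > tlo) tlo = t;
    } else if (up < cB - 1e-12) return false;
  }
  if (tlo > thi + 1e-15) return false;
  // (C) min over t of V - W (convex in t): endpoints first, then ternary
  double fl = evalV(B, d, sL, k, tlo) - evalW(B, d, sR, k, tlo, false);
  if (fl <= 1e-12) return true;
  double fh = evalV(B, d, sL, k, thi) - evalW(B, d, sR, k, thi, false);
  if (fh <= 1e-12) return true;
  double lo = tlo, hi = thi;
  for (int it = 0; it < 40; ++it) {
    double m1 = lo + (hi - lo) / 3.0, m2 = hi - (hi - lo) / 3.0;
    double f1 = evalV(B, d, sL, k, m1) - evalW(B, d, sR, k, m1, false);
    double f2 = evalV(B, d, sL, k, m2) - evalW(B, d, sR, k, m2, false);
    if (f1 <= 1e-12 || f2 <= 1e-12) return true;
    if (f1 < f2) hi = m2; else lo = m1;
  }
  double t = 0.5 * (lo + hi);
  return evalV(B, d, sL, k, t) - evalW(B, d, sR, k, t, false) <= 1e-12;
}

static bool junctionPoint(const Bands& B, double d,
                          const std::vector<double>& sL,
                          const std::vector<double>& sR, int j) {
  // mode at sample point x_j: left branch over 0..j-1 with limit
  // w <= b_j + d; right branch starts at x_j with relaxed band
  double V = (j == 0) ? 0.0 : evalV(B, d, sL, j, B.x[j]);
  double Wstart = evalW(B, d, sR, j, B.x[j], true);
  if (Wstart < (B.a[j] - d) - 1e-12) return false;  // band at x_j empty
  double cap = std::min(B.b[j] + d, Wstart);
  return V <= cap + 1e-12;
}

static bool feasible(const Bands& B, double d) {
  int m = B.m;
  std::vector<double> sL, sR;
  slopeL(B, d, sL);
  slopeR(B, d, sR);
  int fpre = maxFeasPrefix(B, d);
  int fsufLen = maxFeasSuffix(B, d);  // feasible suffix length
  int minStart = m - fsufLen;          // smallest feasible suffix start
  // gap modes: left part 0..k-1, right part k..m-1
  for (int k = 0; k <= m; ++k) {
    if (k > fpre) break;
    if (k < minStart) continue;
    if (junctionGap(B, d, sL, sR, k)) return true;
  }
  // point modes: left 0..j-1, right j..m-1 where the band upper bound at
  // x_j relaxes to a_j + d; the branch interior j+1..m-1 keeps full bands,
  // so suffix feasibility is required from j+1 (i.e. j >= minStart - 1)
  for (int j = 0; j < m; ++j) {
    if (j > fpre) break;
    if (j < minStart - 1) continue;
    if (junctionPoint(B, d, sL, sR, j)) return true;
  }
  return false;
}

}  // namespace

// [[Rcpp::export(name = ".dipCpp")]]
double dipCpp(NumericVector xs) {
  std::vector<double> x(xs.begin(), xs.end());
  std::sort(x.begin(), x.end());
  int n = x.size();
  if (n < 2 || x[0] == x[n - 1]) return 0.0;
  Bands B;
  for (int i = 0; i < n; ++i) {
    if (i == 0 || x[i] != x[i - 1]) {
      B.x.push_back(x[i]);
      B.a.push_back(0.0);
      B.b.push_back(0.0);
    }
    B.a.back() = double(i + 1) / n;
  }
  B.m = B.x.size();
  for (int i = 1; i < B.m; ++i) B.b[i] = B.a[i - 1];
  B.b[0] = 0.0;
  double lo = 0.5 / n - 1e-12, hi = 0.5;
  if (feasible(B, lo)) return 0.5 / n;
  for (int it = 0; it < 40 && (hi - lo) > 1e-11; ++it) {
    double mid = 0.5 * (lo + hi);
    if (feasible(B, mid)) hi = mid; else lo = mid;
  }
  return 0.5 * (lo + hi);
}
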