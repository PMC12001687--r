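// Windowed weighted local regression engine.
//
// Each point is smoothed by a degree-<=2 weighted least-squares fit over its
// q nearest neighbours (q = max(ceil(span * n), 4)), with tricube kernel
// weights multiplied by per-observation weights.  The per-point hat diagonal
// (the point's own leverage in its local fit) is returned so the caller can
// form the trace of the smoother matrix without materialising it.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double tricube(double d, double h) {
  if (h <= 0.0) return 1.0;
  double u = d / h;
  if (u >= 1.0) return 0.0;
  double t = 1.0 - u * u * u;
  return t * t * t;
}

// Solve A out = rhs for a p x p system (p <= 3) by Gaussian elimination with
// partial pivoting; returns false when the system is numerically singular.
static bool solve_gauss(const double A[3][3], const double rhs[3], int p,
                        double out[3]) {
  double M[3][4];
  double scale = 0.0;
  for (int r = 0; r < p; ++r) {
    for (int c = 0; c < p; ++c) {
      M[r][c] = A[r][c];
      scale = std::max(scale, std::fabs(A[r][c]));
    }
    M[r][p] = rhs[r];
  }
  if (scale <= 0.0) return false;
  for (int col = 0; col < p; ++col) {
    int piv = col;
    for (int r = col + 1; r < p; ++r)
      if (std::fabs(M[r][col]) > std::fabs(M[piv][col])) piv = r;
    if (std::fabs(M[piv][col]) < 1e-12 * scale) return false;
    if (piv != col)
      for (int c = col; c <= p; ++c) std::swap(M[piv][c], M[col][c]);
    for (int r = col + 1; r < p; ++r) {
      double fac = M[r][col] / M[col][col];
      for (int c = col; c <= p; ++c) M[r][c] -= fac * M[col][c];
    }
  }
  for (int r = p - 1; r >= 0; --r) {
    double s = M[r][p];
    for (int c = r + 1; c < p; ++c) s -= M[r][c] * out[c];
    out[r] = s / M[r][r];
  }
  return true;
}

// Fit local polynomial from moment sums S[0..2d], T[0..d]; fills beta0
// (fitted value at the window centre, where u = 0) and a11 (the (1,1) entry
// of the inverse normal matrix, for the hat diagonal).  Degrades the degree
// when the local design is singular; degree 0 is the weighted mean.
static bool fit_local(const double S[5], const double T[3], int degree,
                      double* beta0, double* a11) {
  for (int d = degree; d >= 1; --d) {
    int p = d + 1;
    double A[3][3], rhs[3], sol[3];
    for (int r = 0; r < p; ++r) {
      for (int c = 0; c < p; ++c) A[r][c] = S[r + c];
      rhs[r] = T[r];
    }
    if (!solve_gauss(A, rhs, p, sol)) continue;
    double e1[3] = {1.0, 0.0, 0.0}, z[3];
    if (!solve_gauss(A, e1, p, z)) continue;
    *beta0 = sol[0];
    *a11 = z[0];
    return true;
  }
  if (S[0] > 0.0) {
    *beta0 = T[0] / S[0];
    *a11 = 1.0 / S[0];
    return true;
  }
  return false;
}

// x must be sorted ascending.  Returns per-point fitted values and hat
// diagonals (hat is 0 for zero-weight points, which are predicted but carry
// no leverage).
// [[Rcpp::export]]
List cpp_loess_fit(NumericVector x, NumericVector y, NumericVector w,
                   double span, int degree) {
  const int n = x.size();
  int q = (int)std::ceil(span * n);
  if (q < 4) q = 4;
  if (q > n) q = n;

  NumericVector fitted(n), hat(n);
  std::vector<int> pos_idx;
  pos_idx.reserve(n);
  for (int i = 0; i < n; ++i)
    if (w[i] > 0.0) pos_idx.push_back(i);

  for (int j = 0; j < n; ++j) {
    int lo = j, hi = j;
    while (hi - lo + 1 < q) {
      double dl = (lo > 0) ? x[j] - x[lo - 1] : R_PosInf;
      double dr = (hi < n - 1) ? x[hi + 1] - x[j] : R_PosInf;
      if (dl <= dr) --lo; else ++hi;  // ties extend toward the lower index
    }
    double h = std::max(x[j] - x[lo], x[hi] - x[j]);
    if (h <= 0.0) {
      // whole window is one tie class at x[j]; the q nearest points with
      // ties broken by index are the q lowest-indexed members of the class
      int s = lo;
      while (s > 0 && x[s - 1] == x[j]) --s;
      lo = s;
      hi = s + q - 1;
    }

    double S[5] = {0, 0, 0, 0, 0}, T[3] = {0, 0, 0};
    double wself = 0.0;
    int npos = 0;
    for (int k = lo; k <= hi; ++k) {
      if (w[k] <= 0.0) continue;
      double u = (h > 0.0) ? (x[k] - x[j]) / h : 0.0;
      double kw = (h > 0.0) ? tricube(std::fabs(x[k] - x[j]), h) * w[k] : w[k];
      if (kw <= 0.0) continue;
      ++npos;
      if (k == j) wself = kw;
      double up = 1.0;
      for (int m = 0; m <= 2 * degree; ++m) {
        S[m] += kw * up;
        if (m <= degree) T[m] += kw * up * y[k];
        up *= u;
      }
    }

    if (npos == 0) {
      // Window holds no positively-weighted mass (the point itself is masked
      // and its neighbours are masked or at the kernel boundary): predict
      // from the nearest positively-weighted points with uniform weights.
      if (pos_idx.empty()) stop("no positively weighted observations");
      std::vector<int>::iterator it =
          std::lower_bound(pos_idx.begin(), pos_idx.end(), j);
      int ri = (int)(it - pos_idx.begin());
      int li = ri - 1;
      int npi = (int)pos_idx.size();
      int take = std::min(q, npi);
      for (int m = 0; m < 5; ++m) S[m] = 0.0;
      for (int m = 0; m < 3; ++m) T[m] = 0.0;
      std::vector<int> chosen;
      chosen.reserve(take);
      while ((int)chosen.size() < take) {
        double dl = (li >= 0) ? x[j] - x[pos_idx[li]] : R_PosInf;
        double dr = (ri < npi) ? x[pos_idx[ri]] - x[j] : R_PosInf;
        if (dl <= dr) chosen.push_back(pos_idx[li--]);
        else chosen.push_back(pos_idx[ri++]);
      }
      double h2 = 0.0;
      for (size_t m = 0; m < chosen.size(); ++m)
        h2 = std::max(h2, std::fabs(x[chosen[m]] - x[j]));
      for (size_t m = 0; m < chosen.size(); ++m) {
        int k = chosen[m];
        double u = (h2 > 0.0) ? (x[k] - x[j]) / h2 : 0.0;
        double kw = w[k];
        double up = 1.0;
        for (int mm = 0; mm <= 2 * degree; ++mm) {
          S[mm] += kw * up;
          if (mm <= degree) T[mm] += kw * up * y[k];
          up *= u;
        }
      }
      wself = 0.0;
    }

    double beta0 = 0.0, a11 = 0.0;
    if (!fit_local(S, T, degree, &beta0, &a11))
      stop("degenerate local fit at index %d", j + 1);
    fitted[j] = beta0;
    hat[j] = (wself > 0.0) ? wself * a11 : 0.0;
  }

  return List::create(_["fitted"] = fitted, _["hat"] = hat);
}

static double median_inplace(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t m = n / 2;
  std::nth_element(v.begin(), v.begin() + m, v.end());
  double hi = v[m];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + m);
  return 0.5 * (lo + hi);
}

// Flag points whose residual deviates from the local median by more than
// k times the local (unscaled) MAD, the local set being all points with
// positive ratio within +/- halfwidth.  f need not be sorted.
// [[Rcpp::export]]
LogicalVector cpp_local_mad_flags(NumericVector f, NumericVector e, double k,
                                  double halfwidth) {
  const int n = f.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return f[a] < f[b]; });
  std::vector<double> fs(n), es(n);
  for (int i = 0; i < n; ++i) {
    fs[i] = f[ord[i]];
    es[i] = e[ord[i]];
  }

  LogicalVector flag(n);
  std::vector<double> buf;
  buf.reserve(n);
  int lo = 0, hi = 0;
  for (int j = 0; j < n; ++j) {
    while (lo < n && fs[j] - fs[lo] > halfwidth) ++lo;
    if (hi < j + 1) hi = j + 1;
    while (hi < n && fs[hi] - fs[j] <= halfwidth) ++hi;
    buf.assign(es.begin() + lo, es.begin() + hi);
    double med = median_inplace(buf);
    for (size_t m = 0; m < buf.size(); ++m)
      buf[m] = std::fabs(es[lo + m] - med);
    double mad = median_inplace(buf);
    flag[ord[j]] = std::fabs(es[j] - med) > k * mad;
  }
  return flag;
}
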