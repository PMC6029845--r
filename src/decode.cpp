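#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

namespace {

// Linear C-SVC trained by SMO on the dual with a bias term (libsvm's
// formulation).  Problems here are tiny (a handful of pseudo-trials), so a
// simple max-violation working-set rule converges in a few sweeps.
struct LinearSvm {
  std::vector<double> w;
  double b;
};

LinearSvm smo_train(const std::vector<double>& X, int n, int d,
                    const std::vector<int>& y, double C) {
  const double tol = 1e-6;     // KKT violation tolerance
  const double eps = 1e-12;    // minimal alpha step
  const int max_sweeps = 2000;

  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) s += X[(size_t)i * d + k] * X[(size_t)j * d + k];
      K[(size_t)i * n + j] = s;
      K[(size_t)j * n + i] = s;
    }

  std::vector<double> alpha(n, 0.0);
  double b = 0.0;
  auto fval = [&](int i) {
    double s = b;
    for (int j = 0; j < n; ++j)
      if (alpha[j] != 0.0) s += alpha[j] * y[j] * K[(size_t)i * n + j];
    return s;
  };

  // joint optimization of (alpha_i, alpha_j); returns true on progress
  auto take_step = [&](int i, int j, double Ei, double Ej) {
    if (i == j) return false;
    double ai_old = alpha[i], aj_old = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (H - L < eps) return false;
    double curv = K[(size_t)i * n + i] + K[(size_t)j * n + j] -
                  2.0 * K[(size_t)i * n + j];
    double aj;
    if (curv > eps) {
      aj = aj_old + y[j] * (Ei - Ej) / curv;
      if (aj > H) aj = H;
      if (aj < L) aj = L;
    } else {
      // flat direction (duplicate points): move to the better endpoint
      double slope = y[j] * (Ei - Ej);
      if (slope > eps) aj = H;
      else if (slope < -eps) aj = L;
      else return false;
    }
    if (std::fabs(aj - aj_old) < eps * (aj + aj_old + eps)) return false;
    double ai = ai_old + y[i] * y[j] * (aj_old - aj);
    alpha[i] = ai;
    alpha[j] = aj;
    double b1 = b - Ei - y[i] * (ai - ai_old) * K[(size_t)i * n + i] -
                y[j] * (aj - aj_old) * K[(size_t)i * n + j];
    double b2 = b - Ej - y[i] * (ai - ai_old) * K[(size_t)i * n + j] -
                y[j] * (aj - aj_old) * K[(size_t)j * n + j];
    if (ai > 0.0 && ai < C) b = b1;
    else if (aj > 0.0 && aj < C) b = b2;
    else b = 0.5 * (b1 + b2);
    return true;
  };

  std::vector<double> E(n);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double Ei = fval(i) - y[i];
      bool viol = (y[i] * Ei < -tol && alpha[i] < C) ||
                  (y[i] * Ei > tol && alpha[i] > 0.0);
      if (!viol) continue;
      for (int jj = 0; jj < n; ++jj) E[jj] = fval(jj) - y[jj];
      // second choice: best |Ei - Ej| first, then every other candidate
      int jbest = -1;
      double best = -1.0;
      for (int jj = 0; jj < n; ++jj) {
        if (jj == i) continue;
        double v = std::fabs(Ei - E[jj]);
        if (v > best) { best = v; jbest = jj; }
      }
      bool done = false;
      if (jbest >= 0) done = take_step(i, jbest, Ei, E[jbest]);
      for (int jj = 0; !done && jj < n; ++jj) {
        if (jj == i || jj == jbest) continue;
        done = take_step(i, jj, Ei, E[jj]);
      }
      if (done) ++changed;
    }
    if (changed == 0) break;  // KKT conditions hold within tol
  }

  // Recompute the bias from the final alphas (KKT): average of y_i - u_i over
  // free support vectors; with none, the midpoint of the feasible interval.
  std::vector<double> u(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (alpha[j] != 0.0) u[i] += alpha[j] * y[j] * K[(size_t)i * n + j];
  const double bnd = 1e-8 * C;
  double bsum = 0.0;
  int nfree = 0;
  double lo = -std::numeric_limits<double>::infinity();
  double hi = std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i) {
    bool at0 = alpha[i] <= bnd, atC = alpha[i] >= C - bnd;
    if (!at0 && !atC) {
      bsum += y[i] - u[i];
      ++nfree;
    } else if ((y[i] > 0 && at0) || (y[i] < 0 && atC)) {
      lo = std::max(lo, (y[i] > 0 ? 1.0 : -1.0) - u[i]);
    } else {
      hi = std::min(hi, (y[i] > 0 ? 1.0 : -1.0) - u[i]);
    }
  }
  if (nfree > 0) b = bsum / nfree;
  else if (std::isfinite(lo) && std::isfinite(hi)) b = 0.5 * (lo + hi);
  else if (std::isfinite(lo)) b = lo;
  else if (std::isfinite(hi)) b = hi;
  else b = 0.0;

  LinearSvm m;
  m.b = b;
  m.w.assign(d, 0.0);
  for (int i = 0; i < n; ++i)
    if (alpha[i] != 0.0)
      for (int k = 0; k < d; ++k)
        m.w[k] += alpha[i] * y[i] * X[(size_t)i * d + k];
  return m;
}

// slice pseudo-trial m of condition array A (M x d x T, R column-major) at
// time t into row `row` of a flat (n x d) training buffer
inline void copy_trial(const double* A, int M, int d, int m, int t,
                       std::vector<double>& buf, int row) {
  for (int ch = 0; ch < d; ++ch)
    buf[(size_t)row * d + ch] = A[(size_t)m + (size_t)M * ch + (size_t)M * d * t];
}

inline double decide(const LinearSvm& svm, const double* A, int M, int d,
                     int m, int t) {
  double s = svm.b;
  for (int ch = 0; ch < d; ++ch)
    s += svm.w[ch] * A[(size_t)m + (size_t)M * ch + (size_t)M * d * t];
  return s;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".svm_linear_cpp")]]
List svm_linear_cpp(NumericMatrix X, IntegerVector y, double cost) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> Xr((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) Xr[(size_t)i * d + k] = X(i, k);
  std::vector<int> yv(y.begin(), y.end());
  LinearSvm m = smo_train(Xr, n, d, yv, cost);
  return List::create(_["w"] = NumericVector(m.w.begin(), m.w.end()),
                      _["b"] = m.b);
}

// Leave-one-pseudo-trial-per-class-out pairwise decoding across time.
// A, B: M x d x T arrays (pseudo-trials of the two conditions).  Fold k
// tests (a_k, b_k) and trains on the remaining 2(M-1).  A decision value of
// exactly 0 counts as incorrect.  Returns % accuracy per time point.
// [[Rcpp::export(name = ".decode_pair_cpp")]]
NumericVector decode_pair_cpp(NumericVector A, NumericVector B, int M, int d,
                              int T, double cost) {
  const double* pa = A.begin();
  const double* pb = B.begin();
  NumericVector acc(T);
  std::vector<double> Xtr((size_t)(2 * (M - 1)) * d);
  std::vector<int> ytr(2 * (M - 1));
  for (int t = 0; t < T; ++t) {
    int correct = 0;
    for (int k = 0; k < M; ++k) {
      int row = 0;
      for (int m = 0; m < M; ++m) {
        if (m == k) continue;
        copy_trial(pa, M, d, m, t, Xtr, row);
        ytr[row++] = 1;
      }
      for (int m = 0; m < M; ++m) {
        if (m == k) continue;
        copy_trial(pb, M, d, m, t, Xtr, row);
        ytr[row++] = -1;
      }
      LinearSvm svm = smo_train(Xtr, 2 * (M - 1), d, ytr, cost);
      if (decide(svm, pa, M, d, k, t) > 0.0) ++correct;
      if (decide(svm, pb, M, d, k, t) < 0.0) ++correct;
    }
    acc[t] = 100.0 * correct / (2.0 * M);
  }
  return acc;
}

// Temporal generalization for one condition pair: train at t, test at every
// t'.  Same folds as decode_pair_cpp, so the diagonal reproduces it exactly.
// Returns T x T matrix (rows = training time, cols = testing time), %.
// [[Rcpp::export(name = ".tgm_pair_cpp")]]
NumericMatrix tgm_pair_cpp(NumericVector A, NumericVector B, int M, int d,
                           int T, double cost) {
  const double* pa = A.begin();
  const double* pb = B.begin();
  NumericMatrix acc(T, T);
  std::vector<double> Xtr((size_t)(2 * (M - 1)) * d);
  std::vector<int> ytr(2 * (M - 1));
  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < M; ++k) {
      int row = 0;
      for (int m = 0; m < M; ++m) {
        if (m == k) continue;
        copy_trial(pa, M, d, m, t, Xtr, row);
        ytr[row++] = 1;
      }
      for (int m = 0; m < M; ++m) {
        if (m == k) continue;
        copy_trial(pb, M, d, m, t, Xtr, row);
        ytr[row++] = -1;
      }
      LinearSvm svm = smo_train(Xtr, 2 * (M - 1), d, ytr, cost);
      for (int t2 = 0; t2 < T; ++t2) {
        int c = 0;
        if (decide(svm, pa, M, d, k, t2) > 0.0) ++c;
        if (decide(svm, pb, M, d, k, t2) < 0.0) ++c;
        acc(t, t2) += c;
      }
    }
  }
  for (int t = 0; t < T; ++t)
    for (int t2 = 0; t2 < T; ++t2) acc(t, t2) = 100.0 * acc(t, t2) / (2.0 * M);
  return acc;
}

// 4-connected components of a logical matrix; returns integer labels
// (0 = background) and component sizes in discovery order.
// [[Rcpp::export(name = ".label_components_cpp")]]
List label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> sizes;
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      int sz = 0;
      stack.push_back(i + nr * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int ci = cur % nr, cj = cur / nr;
        ++sz;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int q = 0; q < 4; ++q) {
          int ni = ci + di[q], nj = cj + dj[q];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (!mask(ni, nj) || lab(ni, nj) != 0) continue;
          lab(ni, nj) = next;
          stack.push_back(ni + nr * nj);
        }
      }
      sizes.push_back(sz);
    }
  return List::create(_["labels"] = lab,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}
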