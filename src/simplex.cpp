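// Dense two-phase primal simplex for small linear programs of the form
//   min c'x  s.t.  A x {<=,>=} b,  x >= 0,  b >= 0.
// Used by the sparse support-vector-regression fitter, where the program has
// a few hundred variables and constraints. The caller may supply a "crash"
// column per >= row: a structural column with unit coefficient in that row
// whose pivot keeps the right-hand sides non-negative (the loss-slack
// columns of the SVR program have this property), which removes the need
// for artificial variables and phase 1. Dantzig pricing with a Bland
// fallback after a stall budget guards against cycling.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

const double EPS = 1e-9;

struct Tab {
  std::vector<double> v; // column-major (m+1) x ncol
  int rows, cols;
  double& at(int i, int j) { return v[(size_t)j * rows + i]; }
};

// Row-elimination pivot; column-major storage keeps the inner loops on
// contiguous memory (copy the pivot-column factors first, then sweep).
void pivot_ref(Tab& T, std::vector<int>& basis, int prow, int pcol) {
  int m = T.rows, ncol = T.cols;
  double piv = T.at(prow, pcol);
  for (int j = 0; j < ncol; ++j) T.at(prow, j) /= piv;
  std::vector<double> f(m);
  for (int i = 0; i < m; ++i) f[i] = (i == prow) ? 0.0 : T.at(i, pcol);
  for (int j = 0; j < ncol; ++j) {
    double* col = &T.v[(size_t)j * m];
    double pr = col[prow];
    if (pr == 0.0) continue;
    for (int i = 0; i < m; ++i)
      if (f[i] != 0.0) col[i] -= f[i] * pr;
  }
  basis[prow] = pcol;
}

int iterate(Tab& T, std::vector<int>& basis, int nvar_total, int max_iter) {
  int m = T.rows - 1, ncol = T.cols;
  int stall = 0;
  double last_obj = T.at(m, ncol - 1);
  for (int it = 0; it < max_iter; ++it) {
    bool bland = stall > 2 * (m + nvar_total);
    int pcol = -1;
    double best = -EPS;
    for (int j = 0; j < nvar_total; ++j) {
      double rc = T.at(m, j);
      if (rc < -EPS) {
        if (bland) { pcol = j; break; }
        if (rc < best) { best = rc; pcol = j; }
      }
    }
    if (pcol < 0) return 0;
    int prow = -1;
    double best_ratio = R_PosInf;
    for (int i = 0; i < m; ++i) {
      double a = T.at(i, pcol);
      if (a > EPS) {
        double ratio = T.at(i, ncol - 1) / a;
        if (ratio < best_ratio - EPS ||
            (ratio < best_ratio + EPS && prow >= 0 && basis[i] < basis[prow])) {
          best_ratio = ratio;
          prow = i;
        }
      }
    }
    if (prow < 0) return 1;
    pivot_ref(T, basis, prow, pcol);
    double obj = T.at(m, ncol - 1);
    if (std::abs(obj - last_obj) < EPS) ++stall; else stall = 0;
    last_obj = obj;
  }
  return 2;
}

} // namespace

// [[Rcpp::export(name = ".simplex_lp")]]
List simplex_lp(NumericVector cvec, NumericMatrix A, NumericVector b,
                IntegerVector is_ge, IntegerVector crash_col,
                int max_iter = 100000) {
  int m = A.nrow(), n = A.ncol();
  int n_slack = m;
  int n_ge = 0;
  for (int i = 0; i < m; ++i) if (is_ge[i]) ++n_ge;
  int ntot = n + n_slack + n_ge; // artificial columns allocated up front
  Tab T;
  T.rows = m + 1; T.cols = ntot + 1;
  T.v.assign((size_t)T.rows * T.cols, 0.0);
  std::vector<int> basis(m, -1);

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) T.at(i, j) = A(i, j);
    T.at(i, n + i) = is_ge[i] ? -1.0 : 1.0;
    if (!is_ge[i]) basis[i] = n + i;
    T.at(i, ntot) = b[i];
  }

  // crash pivots: unit-coefficient structural columns for >= rows whose
  // pivot provably keeps the RHS non-negative
  for (int i = 0; i < m; ++i) {
    if (basis[i] >= 0) continue;
    int j = crash_col[i];
    if (j < 0 || j >= n) continue;
    double a = T.at(i, j);
    if (a < EPS) continue;
    bool safe = true;
    double ratio_i = T.at(i, ntot) / a;
    for (int k = 0; k < m && safe; ++k) {
      double ak = T.at(k, j);
      if (k != i && ak > EPS && T.at(k, ntot) / ak < ratio_i - EPS)
        safe = false;
    }
    if (safe) pivot_ref(T, basis, i, j);
  }

  // artificials for any rows still without a basic variable
  int art = n + n_slack;
  int n_art = 0;
  for (int i = 0; i < m; ++i) {
    if (basis[i] < 0) { T.at(i, art) = 1.0; basis[i] = art; ++art; ++n_art; }
  }

  if (n_art > 0) { // phase 1
    for (int i = 0; i < m; ++i) {
      if (basis[i] >= n + n_slack)
        for (int j = 0; j <= ntot; ++j) T.at(m, j) -= T.at(i, j);
    }
    for (int j = n + n_slack; j < art; ++j) T.at(m, j) += 1.0;
    int st = iterate(T, basis, ntot, max_iter);
    if (st != 0 || T.at(m, ntot) < -1e-7)
      return List::create(_["status"] = 3);
    for (int i = 0; i < m; ++i) {
      if (basis[i] >= n + n_slack) {
        for (int j = 0; j < n + n_slack; ++j)
          if (std::abs(T.at(i, j)) > EPS) { pivot_ref(T, basis, i, j); break; }
      }
    }
    for (int j = 0; j <= ntot; ++j) T.at(m, j) = 0.0;
  }

  // phase 2 objective row, with artificial columns blocked
  for (int j = 0; j < n; ++j) T.at(m, j) = cvec[j];
  for (int j = n + n_slack; j < ntot; ++j) T.at(m, j) = 1e30;
  for (int i = 0; i < m; ++i) {
    double cb = basis[i] < n ? cvec[basis[i]]
                             : (basis[i] >= n + n_slack ? 1e30 : 0.0);
    if (cb != 0.0)
      for (int j = 0; j <= ntot; ++j) T.at(m, j) -= cb * T.at(i, j);
  }
  int st = iterate(T, basis, ntot, max_iter);
  if (st != 0) return List::create(_["status"] = st);

  NumericVector x(n);
  for (int i = 0; i < m; ++i)
    if (basis[i] < n) x[basis[i]] = T.at(i, ntot);
  double value = 0.0;
  for (int j = 0; j < n; ++j) value += cvec[j] * x[j];
  return List::create(_["status"] = 0, _["solution"] = x, _["value"] = value);
}
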