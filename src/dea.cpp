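#include <Rcpp.h>
#include <vector>
#include <functional>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Output-oriented DEA envelopment LP, solved per evaluated DMU with a dense
// two-phase primal simplex.  The tableau has only m + s (+1 under VRS) rows,
// so full-tableau pivoting is cheap even with hundreds of reference DMUs.
//
//   max delta
//   s.t.  sum_j lambda_j xref_jk           <= x_ik   (k = 1..m)
//         sum_j lambda_j yref_jr - delta y_ir >= 0    (r = 1..s)
//         sum_j lambda_j = 1                          (VRS only)
//         lambda >= 0, delta free >= 0
//
// Column layout: [lambda_1..lambda_n | delta | input slacks m | output
// surpluses s | artificial (VRS)].  Output rows are sign-flipped so every
// right-hand side is nonnegative and the surplus enters with +1.

static const double EPS = 1e-9;

struct SimplexResult {
  double delta;
  std::vector<double> lambda;
  int status; // 0 ok, 1 infeasible, 2 unbounded, 3 iteration limit
};

static SimplexResult solve_dea_lp(const double* Xref, const double* Yref,
                                  int n, int m, int s,
                                  const double* xi, const double* yi,
                                  bool vrs) {
  const int rows = m + s + (vrs ? 1 : 0);
  const int ncol = n + 1 + m + s + (vrs ? 1 : 0); // + rhs stored separately
  const int dcol = n;            // delta column
  const int scol = n + 1;        // first slack column
  const int acol = vrs ? (n + 1 + m + s) : -1; // artificial

  std::vector<double> T(static_cast<size_t>(rows) * ncol, 0.0);
  std::vector<double> rhs(rows, 0.0);
  std::vector<int> basis(rows);

  // input rows: sum lambda xref + slack = x_i
  for (int k = 0; k < m; ++k) {
    double* row = &T[static_cast<size_t>(k) * ncol];
    for (int j = 0; j < n; ++j) row[j] = Xref[j + static_cast<size_t>(k) * n];
    row[scol + k] = 1.0;
    rhs[k] = xi[k];
    basis[k] = scol + k;
  }
  // output rows (flipped): -sum lambda yref + delta y_i + surplus = 0
  for (int r = 0; r < s; ++r) {
    double* row = &T[static_cast<size_t>(m + r) * ncol];
    for (int j = 0; j < n; ++j) row[j] = -Yref[j + static_cast<size_t>(r) * n];
    row[dcol] = yi[r];
    row[scol + m + r] = 1.0;
    rhs[m + r] = 0.0;
    basis[m + r] = scol + m + r;
  }
  // convexity row with artificial
  if (vrs) {
    double* row = &T[static_cast<size_t>(m + s) * ncol];
    for (int j = 0; j < n; ++j) row[j] = 1.0;
    row[acol] = 1.0;
    rhs[m + s] = 1.0;
    basis[m + s] = acol;
  }

  std::vector<double> cost(ncol, 0.0);
  auto run_phase = [&](bool phase1) -> int {
    // minimisation; phase 1 minimises the artificial, phase 2 minimises -delta
    std::fill(cost.begin(), cost.end(), 0.0);
    if (phase1) cost[acol] = 1.0; else cost[dcol] = -1.0;
    const long maxit = 2000 + 10L * ncol;
    for (long it = 0; it < maxit; ++it) {
      bool bland = it > 500 + ncol;
      // reduced costs r_j = c_j - sum_i c_B[i] T[i][j]; c_B sparse
      int enter = -1;
      double best = -EPS;
      for (int j = 0; j < ncol; ++j) {
        if (!phase1 && acol >= 0 && j == acol) continue; // artificial barred
        double cb = 0.0;
        for (int i = 0; i < rows; ++i) {
          double cbi = cost[basis[i]];
          if (cbi != 0.0) cb += cbi * T[static_cast<size_t>(i) * ncol + j];
        }
        double rj = cost[j] - cb;
        if (bland) {
          if (rj < -EPS) { enter = j; break; }
        } else if (rj < best) { best = rj; enter = j; }
      }
      if (enter < 0) return 0; // optimal
      // ratio test
      int leave = -1;
      double bestratio = std::numeric_limits<double>::infinity();
      for (int i = 0; i < rows; ++i) {
        double a = T[static_cast<size_t>(i) * ncol + enter];
        if (a > EPS) {
          double ratio = rhs[i] / a;
          if (ratio < bestratio - EPS ||
              (ratio < bestratio + EPS && leave >= 0 && basis[i] < basis[leave])) {
            bestratio = ratio; leave = i;
          }
        }
      }
      if (leave < 0) return 2; // unbounded
      // pivot
      double piv = T[static_cast<size_t>(leave) * ncol + enter];
      double* prow = &T[static_cast<size_t>(leave) * ncol];
      for (int j = 0; j < ncol; ++j) prow[j] /= piv;
      rhs[leave] /= piv;
      for (int i = 0; i < rows; ++i) {
        if (i == leave) continue;
        double f = T[static_cast<size_t>(i) * ncol + enter];
        if (f != 0.0) {
          double* irow = &T[static_cast<size_t>(i) * ncol];
          for (int j = 0; j < ncol; ++j) irow[j] -= f * prow[j];
          rhs[i] -= f * rhs[leave];
          if (rhs[i] < 0.0 && rhs[i] > -1e-11) rhs[i] = 0.0;
        }
      }
      basis[leave] = enter;
    }
    return 3;
  };

  SimplexResult out;
  out.lambda.assign(n, 0.0);
  if (vrs) {
    int st = run_phase(true);
    double art = 0.0;
    int artrow = -1;
    for (int i = 0; i < rows; ++i) if (basis[i] == acol) { art = rhs[i]; artrow = i; }
    if (st != 0 || art > 1e-7) { out.status = (st == 0 ? 1 : st); out.delta = NA_REAL; return out; }
    // the artificial may end phase 1 basic at zero; a later pivot could then
    // push it positive and silently drop the convexity row, so force it out
    // of the basis with a degenerate pivot now
    if (artrow >= 0) {
      double* prow = &T[static_cast<size_t>(artrow) * ncol];
      int enter = -1;
      double bestmag = 1e-7;
      for (int j = 0; j < ncol; ++j) {
        if (j == acol) continue;
        if (std::fabs(prow[j]) > bestmag) { bestmag = std::fabs(prow[j]); enter = j; }
      }
      if (enter >= 0) {
        double piv = prow[enter];
        for (int j = 0; j < ncol; ++j) prow[j] /= piv;
        rhs[artrow] /= piv;
        if (rhs[artrow] < 0.0 && rhs[artrow] > -1e-9) rhs[artrow] = 0.0;
        for (int i = 0; i < rows; ++i) {
          if (i == artrow) continue;
          double f = T[static_cast<size_t>(i) * ncol + enter];
          if (f != 0.0) {
            double* irow = &T[static_cast<size_t>(i) * ncol];
            for (int j = 0; j < ncol; ++j) irow[j] -= f * prow[j];
            rhs[i] -= f * rhs[artrow];
            if (rhs[i] < 0.0 && rhs[i] > -1e-11) rhs[i] = 0.0;
          }
        }
        basis[artrow] = enter;
      }
    }
  }
  int st = run_phase(false);
  out.status = st;
  out.delta = 0.0;
  for (int i = 0; i < rows; ++i) {
    if (basis[i] == dcol) out.delta = rhs[i];
    else if (basis[i] < n) out.lambda[basis[i]] = rhs[i];
  }
  if (st != 0) { out.delta = NA_REAL; return out; }
  // verify the reported solution against the original constraints; any
  // violation is a solver defect surfaced as a status, never a wrong score
  for (int k = 0; k < m; ++k) {
    double lhs = 0.0;
    for (int j = 0; j < n; ++j) lhs += out.lambda[j] * Xref[j + static_cast<size_t>(k) * n];
    if (lhs > xi[k] * (1.0 + 1e-7) + 1e-7) { out.status = 4; out.delta = NA_REAL; return out; }
  }
  for (int r = 0; r < s; ++r) {
    double lhs = 0.0;
    for (int j = 0; j < n; ++j) lhs += out.lambda[j] * Yref[j + static_cast<size_t>(r) * n];
    double need = out.delta * yi[r];
    if (lhs < need - 1e-7 * (1.0 + std::fabs(need))) { out.status = 4; out.delta = NA_REAL; return out; }
  }
  if (vrs) {
    double sl = 0.0;
    for (int j = 0; j < n; ++j) sl += out.lambda[j];
    if (std::fabs(sl - 1.0) > 1e-6) { out.status = 4; out.delta = NA_REAL; return out; }
  }
  return out;
}

// [[Rcpp::export(name = ".dea_solve_cpp")]]
List dea_solve_cpp(NumericMatrix X, NumericMatrix Y,
                   NumericMatrix Xref, NumericMatrix Yref,
                   bool vrs, bool want_lambda) {
  const int ne = X.nrow(), m = X.ncol(), s = Y.ncol(), n = Xref.nrow();
  if (Y.nrow() != ne) stop("X and Y must have the same number of rows");
  if (Yref.nrow() != n) stop("Xref and Yref must have the same number of rows");
  NumericVector delta(ne);
  IntegerVector status(ne);
  NumericMatrix lambda(want_lambda ? ne : 0, want_lambda ? n : 0);
  std::vector<double> xi(m), yi(s);
  for (int i = 0; i < ne; ++i) {
    for (int k = 0; k < m; ++k) xi[k] = X(i, k);
    for (int r = 0; r < s; ++r) yi[r] = Y(i, r);
    SimplexResult res = solve_dea_lp(&Xref[0], &Yref[0], n, m, s,
                                     xi.data(), yi.data(), vrs);
    delta[i] = res.delta;
    status[i] = res.status;
    if (want_lambda && res.status == 0)
      for (int j = 0; j < n; ++j) lambda(i, j) = res.lambda[j];
  }
  return List::create(_["delta"] = delta, _["status"] = status,
                      _["lambda"] = lambda);
}

// Exhaustive enumeration of lambda over the simplex grid {k/resolution}.
// Independent brute-force reference for the LP above: for each feasible grid
// point (weighted reference input within the evaluated input) the attainable
// expansion is min over outputs of (sum lambda yref_r) / y_ir.  Returns the
// maximum over the grid, a lower bound on the true optimum that approaches it
// as the resolution grows.

// [[Rcpp::export(name = ".dea_grid_cpp")]]
double dea_grid_cpp(NumericVector xref, NumericMatrix Yref,
                    double xi, NumericVector yi, int resolution) {
  const int n = xref.size(), s = Yref.ncol();
  if (n > 6) stop("grid oracle supports at most 6 reference DMUs");
  std::vector<int> k(n, 0);
  double best = -1.0;
  // recursive composition of `resolution` into n parts, with incremental sums
  std::vector<double> sx(n + 1, 0.0);
  std::vector<std::vector<double> > sy(n + 1, std::vector<double>(s, 0.0));
  const double step = 1.0 / resolution;
  std::function<void(int, int)> rec = [&](int pos, int rem) {
    if (pos == n - 1) {
      double lam = rem * step;
      double x = sx[pos] + lam * xref[pos];
      if (x <= xi + 1e-9) {
        double d = std::numeric_limits<double>::infinity();
        for (int r = 0; r < s; ++r) {
          if (yi[r] > 0) {
            double y = sy[pos][r] + lam * Yref(pos, r);
            double v = y / yi[r];
            if (v < d) d = v;
          }
        }
        if (d > best && std::isfinite(d)) best = d;
      }
      return;
    }
    for (int kk = 0; kk <= rem; ++kk) {
      double lam = kk * step;
      sx[pos + 1] = sx[pos] + lam * xref[pos];
      if (sx[pos + 1] > xi + 1e-9 && xref[pos] >= 0) {
        // inputs are nonnegative: larger kk only increases the weighted input
        break;
      }
      for (int r = 0; r < s; ++r) sy[pos + 1][r] = sy[pos][r] + lam * Yref(pos, r);
      rec(pos + 1, rem - kk);
    }
  };
  rec(0, resolution);
  return best;
}
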