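// Dense two-phase primal simplex for the small/medium LPs that arise in
// flux variability analysis, Farkas-certificate checks and the LP
// relaxations of the branch-and-bound MILP search.  Problems are given in
// the general form
//      min/max  c'x   s.t.  A x {<=,=,>=} b,  lb <= x <= ub
// with lb possibly -Inf and ub possibly +Inf.  Internally everything is
// reduced to standard form (min c'y, By = d, y >= 0) by shifting/splitting
// variables; finite upper bounds become extra rows.  Phase 1 minimises the
// sum of artificials; Bland's rule is switched on after a degeneracy budget
// to guarantee termination.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct StdLP {
  // min c'y  s.t. B y = d (d >= 0), y >= 0
  int m, n;                    // rows, structural columns (before artificials)
  std::vector<double> B;       // row-major m x n
  std::vector<double> d;
  std::vector<double> c;
};

// Tolerances: PIV guards pivot selection, FEAS declares phase-1 success.
static const double TOL_PIV  = 1e-9;
static const double TOL_FEAS = 1e-9;
static const double TOL_COST = 1e-9;

// Solve standard-form LP by tableau simplex. Returns status:
// 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit.
static int simplex_core(StdLP &lp, std::vector<double> &ysol, double &objval) {
  const int m = lp.m;
  const int n = lp.n;
  const int ncol = n + m;           // structural + artificial
  // tableau: m rows x (ncol + 1); last column = rhs
  std::vector<long double> T((size_t)m * (ncol + 1), 0.0L);
  std::vector<int> basis(m);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) T[(size_t)i * (ncol + 1) + j] = lp.B[(size_t)i * n + j];
    T[(size_t)i * (ncol + 1) + n + i] = 1.0;       // artificial
    T[(size_t)i * (ncol + 1) + ncol] = lp.d[i];    // d >= 0 by construction
    basis[i] = n + i;
  }
  const std::vector<long double> T0(T);            // pristine tableau
  std::vector<double> cost(ncol, 0.0);

  // Rebuild the tableau exactly from the current basis by Gaussian
  // elimination on [B_basis | T0]; eliminates the error drift that plain
  // pivoting accumulates on badly conditioned pivot sequences.
  auto refactorize = [&]() -> bool {
    const int w = ncol + 1;
    std::vector<long double> M((size_t)m * m);
    std::vector<long double> X(T0);
    for (int i = 0; i < m; ++i)
      for (int k = 0; k < m; ++k)
        M[(size_t)i * m + k] = T0[(size_t)i * w + basis[k]];
    for (int col = 0; col < m; ++col) {
      int piv = col;
      long double mx = fabsl(M[(size_t)col * m + col]);
      for (int i = col + 1; i < m; ++i) {
        long double v = fabsl(M[(size_t)i * m + col]);
        if (v > mx) { mx = v; piv = i; }
      }
      if (mx < 1e-12) return false;                // singular basis: keep T
      if (piv != col) {
        for (int k = 0; k < m; ++k) std::swap(M[(size_t)piv * m + k], M[(size_t)col * m + k]);
        for (int j = 0; j < w; ++j) std::swap(X[(size_t)piv * w + j], X[(size_t)col * w + j]);
      }
      long double p = M[(size_t)col * m + col];
      for (int k = 0; k < m; ++k) M[(size_t)col * m + k] /= p;
      for (int j = 0; j < w; ++j) X[(size_t)col * w + j] /= p;
      for (int i = 0; i < m; ++i) {
        if (i == col) continue;
        long double f = M[(size_t)i * m + col];
        if (f != 0.0L) {
          for (int k = 0; k < m; ++k) M[(size_t)i * m + k] -= f * M[(size_t)col * m + k];
          for (int j = 0; j < w; ++j) X[(size_t)i * w + j] -= f * X[(size_t)col * w + j];
        }
      }
    }
    // rows of X are ordered by elimination pivot = basis position
    T.swap(X);
    return true;
  };

  long maxit = 20000L + 200L * (long)(m + n);
  long blandit = 500L + 10L * (long)(m + n);

  auto run_phase = [&](int phase) -> int {
    // price out basic columns into reduced-cost row z
    std::vector<long double> z(ncol + 1, 0.0L);
    auto reprice = [&]() {
      for (int j = 0; j <= ncol; ++j) z[j] = (j < ncol) ? -(long double)cost[j] : 0.0L;
      for (int i = 0; i < m; ++i) {
        long double cb = cost[basis[i]];
        if (cb != 0.0L) {
          for (int j = 0; j <= ncol; ++j)
            z[j] += cb * T[(size_t)i * (ncol + 1) + j];
        }
      }
    };
    reprice();
    // z[j] = cb'B^-1 A_j - c_j ; entering j has z[j] > 0 (minimisation)
    long iter = 0;
    bool fresh = true;                 // z freshly repriced this iteration
    while (true) {
      if (++iter > maxit) return 3;
      // periodically rebuild tableau and reduced costs from scratch
      if (iter % 300L == 0L) { refactorize(); reprice(); fresh = true; }
      bool bland = iter > blandit;
      int enter = -1;
      double best = TOL_COST;
      for (int j = 0; j < ncol; ++j) {
        if (phase == 2 && j >= n) continue;        // artificials locked out
        if (z[j] > TOL_COST) {
          if (bland) { enter = j; break; }         // first eligible (Bland)
          if (z[j] > best) { best = z[j]; enter = j; }
        }
      }
      if (enter < 0) {
        if (!fresh) {                              // confirm on exact data
          refactorize(); reprice(); fresh = true;
          continue;
        }
        if (getenv("SIMPLEX_DEBUG"))
          Rcpp::Rcout << "phase " << phase << " done: no entering col, iter=" << iter << "\n";
        break;                                     // optimal for this phase
      }
      fresh = false;
      // ratio test
      int leave = -1;
      long double bestRatio = INF;
      for (int i = 0; i < m; ++i) {
        long double a = T[(size_t)i * (ncol + 1) + enter];
        if (a > TOL_PIV) {
          long double ratio = T[(size_t)i * (ncol + 1) + ncol] / a;
          if (leave < 0 || ratio < bestRatio - 1e-12) {
            bestRatio = ratio; leave = i;
          } else if (ratio <= bestRatio + 1e-12 && basis[i] < basis[leave]) {
            leave = i;                     // tie-break: smallest basis index leaves
          }
        }
      }
      if (leave < 0) {
        if (getenv("SIMPLEX_DEBUG"))
          Rcpp::Rcout << "phase " << phase << " unbounded: enter=" << enter
                      << " z=" << z[enter] << " iter=" << iter << "\n";
        return 2;                                  // unbounded
      }
      // pivot on (leave, enter)
      long double piv = T[(size_t)leave * (ncol + 1) + enter];
      long double *prow = &T[(size_t)leave * (ncol + 1)];
      for (int j = 0; j <= ncol; ++j) prow[j] /= piv;
      for (int i = 0; i < m; ++i) {
        if (i == leave) continue;
        long double f = T[(size_t)i * (ncol + 1) + enter];
        if (f != 0.0L) {
          long double *row = &T[(size_t)i * (ncol + 1)];
          for (int j = 0; j <= ncol; ++j) {
            row[j] -= f * prow[j];
            if (fabsl(row[j]) < 1e-14L) row[j] = 0.0L;     // snap dirty zeros
          }
          if (row[ncol] < 0.0L && row[ncol] > -1e-12L) row[ncol] = 0.0L;
        }
      }
      long double fz = z[enter];
      if (fz != 0.0L)
        for (int j = 0; j <= ncol; ++j) z[j] -= fz * prow[j];
      basis[leave] = enter;
    }
    return 0;
  };

  // ---- phase 1
  for (int j = 0; j < ncol; ++j) cost[j] = (j >= n) ? 1.0 : 0.0;
  int st = run_phase(1);
  if (st != 0) return st == 2 ? 1 : st;            // unbounded phase 1 = numeric trouble -> infeasible
  long double p1 = 0.0L;
  for (int i = 0; i < m; ++i) p1 += cost[basis[i]] * T[(size_t)i * (ncol + 1) + ncol];
  if (getenv("SIMPLEX_DEBUG")) Rcpp::Rcout << "phase1 sum=" << (double)p1 << "\n";
  if (p1 > TOL_FEAS) return 1;                     // infeasible
  // drive remaining basic artificials out (or note redundant rows)
  for (int i = 0; i < m; ++i) {
    if (basis[i] >= n) {
      int enter = -1;
      for (int j = 0; j < n; ++j) {
        if (fabsl(T[(size_t)i * (ncol + 1) + j]) > 1e-7L) { enter = j; break; }
      }
      if (enter >= 0) {
        long double piv = T[(size_t)i * (ncol + 1) + enter];
        long double *prow = &T[(size_t)i * (ncol + 1)];
        for (int j = 0; j <= ncol; ++j) prow[j] /= piv;
        for (int k = 0; k < m; ++k) {
          if (k == i) continue;
          long double f = T[(size_t)k * (ncol + 1) + enter];
          if (f != 0.0L) {
            long double *row = &T[(size_t)k * (ncol + 1)];
            for (int j = 0; j <= ncol; ++j) row[j] -= f * prow[j];
          }
        }
        basis[i] = enter;
      }
      // else: redundant row; artificial stays basic at value ~0 and, being
      // locked out of phase-2 pricing, the row is inert.
    }
  }
  // ---- phase 2
  for (int j = 0; j < ncol; ++j) cost[j] = (j < n) ? lp.c[j] : 0.0;
  st = run_phase(2);
  if (st != 0) return st;
  ysol.assign(n, 0.0);
  for (int i = 0; i < m; ++i)
    if (basis[i] < n) ysol[basis[i]] = (double)T[(size_t)i * (ncol + 1) + ncol];
  objval = 0.0;
  for (int j = 0; j < n; ++j) objval += lp.c[j] * ysol[j];
  return 0;
}

// [[Rcpp::export(name = ".cpp_lp_solve")]]
List cpp_lp_solve(NumericVector obj, NumericMatrix A, IntegerVector dir,
                  NumericVector rhs, NumericVector lb, NumericVector ub,
                  bool maximize) {
  const int m0 = A.nrow();
  const int nv = A.ncol();

  // --- variable substitutions to get y >= 0
  // kind: 0 = shift by lb, 1 = reflect around ub, 2 = free split (two cols)
  std::vector<int> kind(nv), col1(nv), col2(nv, -1);
  std::vector<double> shift(nv, 0.0);
  std::vector<int> ubrow_var;                      // vars needing ub row
  int n = 0;
  for (int j = 0; j < nv; ++j) {
    double l = lb[j], u = ub[j];
    if (l > u + 1e-12)
      return List::create(_["status"] = 1, _["x"] = R_NilValue, _["objval"] = R_NilValue);
    if (std::isfinite(l)) {
      kind[j] = 0; shift[j] = l; col1[j] = n++;
      if (std::isfinite(u)) ubrow_var.push_back(j);
    } else if (std::isfinite(u)) {
      kind[j] = 1; shift[j] = u; col1[j] = n++;
    } else {
      kind[j] = 2; col1[j] = n++; col2[j] = n++;
    }
  }
  const int m = m0 + (int)ubrow_var.size();
  StdLP lp;
  lp.m = m; lp.n = n;
  lp.B.assign((size_t)m * n, 0.0);
  lp.d.assign(m, 0.0);
  lp.c.assign(n, 0.0);

  double sgn = maximize ? -1.0 : 1.0;
  for (int j = 0; j < nv; ++j) {
    double cj = sgn * obj[j];
    if (kind[j] == 0)      lp.c[col1[j]] = cj;
    else if (kind[j] == 1) lp.c[col1[j]] = -cj;
    else { lp.c[col1[j]] = cj; lp.c[col2[j]] = -cj; }
  }

  // rows: Ax dir b  ->  sum_j a_ij * y-terms  dir  b_i - a_i . shiftpart
  std::vector<int> rdir(m);
  for (int i = 0; i < m0; ++i) {
    double b = rhs[i];
    for (int j = 0; j < nv; ++j) {
      double a = A(i, j);
      if (a == 0.0) continue;
      b -= a * shift[j];
      if (kind[j] == 0)      lp.B[(size_t)i * n + col1[j]] += a;
      else if (kind[j] == 1) lp.B[(size_t)i * n + col1[j]] -= a;
      else { lp.B[(size_t)i * n + col1[j]] += a; lp.B[(size_t)i * n + col2[j]] -= a; }
    }
    lp.d[i] = b;
    rdir[i] = dir[i];
  }
  for (size_t k = 0; k < ubrow_var.size(); ++k) {
    int i = m0 + (int)k, j = ubrow_var[k];
    lp.B[(size_t)i * n + col1[j]] = 1.0;
    lp.d[i] = ub[j] - lb[j];
    rdir[i] = -1;                                  // y <= ub - lb
  }
  // normalise to equality rows with d >= 0 by adding slack/surplus columns
  int nslack = 0;
  for (int i = 0; i < m; ++i) if (rdir[i] != 0) ++nslack;
  int ntot = n + nslack;
  std::vector<double> B2((size_t)m * ntot, 0.0);
  int sc = n;
  for (int i = 0; i < m; ++i) {
    double flip = 1.0;
    if (lp.d[i] < 0) flip = -1.0;
    for (int j = 0; j < n; ++j) B2[(size_t)i * ntot + j] = flip * lp.B[(size_t)i * n + j];
    double di = flip * lp.d[i];
    int dd = rdir[i] * (flip < 0 ? -1 : 1);
    if (rdir[i] != 0) {
      B2[(size_t)i * ntot + sc] = (dd < 0) ? 1.0 : -1.0;  // slack for <=, surplus for >=
      ++sc;
    }
    lp.d[i] = di;
  }
  lp.B.swap(B2);
  lp.n = ntot;
  lp.c.resize(ntot, 0.0);

  // row equilibration: badly scaled rows (e.g. big-M links) destabilise
  // the tableau; dividing a row and its rhs by its largest coefficient is
  // an exact reformulation
  for (int i = 0; i < m; ++i) {
    double mx = 0.0;
    for (int j = 0; j < ntot; ++j)
      mx = std::max(mx, std::fabs(lp.B[(size_t)i * ntot + j]));
    if (mx > 1e-12 && (mx > 1e3 || mx < 1e-3)) {
      for (int j = 0; j < ntot; ++j) lp.B[(size_t)i * ntot + j] /= mx;
      lp.d[i] /= mx;
    }
  }

  std::vector<double> y;
  double objy = 0.0;
  int st = simplex_core(lp, y, objy);
  if (st != 0) {
    return List::create(_["status"] = st, _["x"] = R_NilValue, _["objval"] = R_NilValue);
  }
  NumericVector x(nv);
  for (int j = 0; j < nv; ++j) {
    if (kind[j] == 0)      x[j] = shift[j] + y[col1[j]];
    else if (kind[j] == 1) x[j] = shift[j] - y[col1[j]];
    else                   x[j] = y[col1[j]] - y[col2[j]];
  }
  double objval = 0.0;
  for (int j = 0; j < nv; ++j) objval += obj[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x, _["objval"] = objval);
}
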