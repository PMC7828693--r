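// Exact rational two-phase simplex for small dense linear programs.
//
// This is the certification route for the flux balance optima: the same
// bounded LP the floating-point solver handles, but pivoted in exact
// rational arithmetic (int64 numerator/denominator, __int128 intermediates,
// hard overflow guard), with Dantzig pivoting switching to Bland's rule
// after a fixed iteration count so termination is guaranteed. Yields of the
// curated networks are exact halves; this solver returns them as such.

#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

const int64_t GUARD = int64_t(1) << 60;

int64_t gcd64(int64_t a, int64_t b) {
  if (a < 0) a = -a;
  if (b < 0) b = -b;
  while (b) { int64_t t = a % b; a = b; b = t; }
  return a ? a : 1;
}

struct Rat {
  int64_t n, d; // d > 0, gcd(n, d) == 1
  Rat() : n(0), d(1) {}
  Rat(int64_t nn, int64_t dd) : n(nn), d(dd) { norm(); }
  void norm() {
    if (d == 0) stop("exact simplex: zero denominator");
    if (d < 0) { n = -n; d = -d; }
    int64_t g = gcd64(n, d);
    n /= g; d /= g;
    if (n > GUARD || n < -GUARD || d > GUARD) {
      stop("exact simplex: rational overflow guard exceeded");
    }
  }
};

Rat make_checked(__int128 n, __int128 d) {
  if (d < 0) { n = -n; d = -d; }
  // reduce in 128-bit before narrowing
  __int128 a = n < 0 ? -n : n, b = d;
  while (b) { __int128 t = a % b; a = b; b = t; }
  if (a == 0) a = 1;
  n /= a; d /= a;
  if (n > GUARD || n < -GUARD || d > GUARD) {
    stop("exact simplex: rational overflow guard exceeded");
  }
  Rat r; r.n = (int64_t)n; r.d = (int64_t)d;
  return r;
}

Rat add(const Rat& x, const Rat& y) {
  return make_checked((__int128)x.n * y.d + (__int128)y.n * x.d,
                      (__int128)x.d * y.d);
}
Rat sub(const Rat& x, const Rat& y) {
  return make_checked((__int128)x.n * y.d - (__int128)y.n * x.d,
                      (__int128)x.d * y.d);
}
Rat mul(const Rat& x, const Rat& y) {
  return make_checked((__int128)x.n * y.n, (__int128)x.d * y.d);
}
Rat divr(const Rat& x, const Rat& y) {
  if (y.n == 0) stop("exact simplex: division by zero");
  return make_checked((__int128)x.n * y.d, (__int128)x.d * y.n);
}
int sgn(const Rat& x) { return (x.n > 0) - (x.n < 0); }
// sign of x - y without building the difference
int cmp(const Rat& x, const Rat& y) {
  __int128 l = (__int128)x.n * y.d, r = (__int128)y.n * x.d;
  return (l > r) - (l < r);
}

struct Tableau {
  int nrow, ncol;
  std::vector<std::vector<Rat>> T; // nrow x ncol
  std::vector<Rat> rhs;            // nrow
  std::vector<int> basis;          // nrow, column index of basic variable

  void pivot(int p, int q) {
    Rat piv = T[p][q];
    for (int j = 0; j < ncol; ++j) T[p][j] = divr(T[p][j], piv);
    rhs[p] = divr(rhs[p], piv);
    for (int i = 0; i < nrow; ++i) {
      if (i == p || T[i][q].n == 0) continue;
      Rat f = T[i][q];
      for (int j = 0; j < ncol; ++j) {
        if (T[p][j].n != 0) T[i][j] = sub(T[i][j], mul(f, T[p][j]));
      }
      rhs[i] = sub(rhs[i], mul(f, rhs[p]));
    }
    basis[p] = q;
  }

  // minimize cost'z; returns 0 optimal, 1 unbounded, 2 iteration limit
  int simplex(const std::vector<Rat>& cost, const std::vector<bool>& allowed) {
    const int bland_after = 300, max_iter = 50000;
    std::vector<bool> in_basis(ncol, false);
    for (int i = 0; i < nrow; ++i) in_basis[basis[i]] = true;
    for (int iter = 0; iter < max_iter; ++iter) {
      // reduced costs r_j = cost_j - cost_B' T_j
      int q = -1;
      Rat best;
      for (int j = 0; j < ncol; ++j) {
        if (!allowed[j] || in_basis[j]) continue;
        Rat r = cost[j];
        for (int i = 0; i < nrow; ++i) {
          if (T[i][j].n != 0 && cost[basis[i]].n != 0) {
            r = sub(r, mul(cost[basis[i]], T[i][j]));
          }
        }
        if (sgn(r) < 0) {
          if (iter >= bland_after) { q = j; break; } // Bland: first improving
          if (q < 0 || cmp(r, best) < 0) { q = j; best = r; }
        }
      }
      if (q < 0) return 0;
      int p = -1;
      Rat ratio;
      for (int i = 0; i < nrow; ++i) {
        if (sgn(T[i][q]) > 0) {
          Rat rt = divr(rhs[i], T[i][q]);
          if (p < 0 || cmp(rt, ratio) < 0 ||
              (cmp(rt, ratio) == 0 && basis[i] < basis[p])) {
            p = i; ratio = rt;
          }
        }
      }
      if (p < 0) return 1;
      in_basis[basis[p]] = false;
      in_basis[q] = true;
      pivot(p, q);
    }
    return 2;
  }
};

Rat from_pair(double num, double den) {
  if (num != std::floor(num) || den != std::floor(den)) {
    stop("exact simplex: non-integral rational input");
  }
  return Rat((int64_t)num, (int64_t)den);
}

} // namespace

// Solve max c'v s.t. A v = b, lb <= v <= ub in exact rational arithmetic.
// All inputs are numerator/denominator pairs of integer-valued doubles.
// [[Rcpp::export(name = ".exact_lp")]]
List exact_lp(NumericMatrix Anum, NumericMatrix Aden,
              NumericVector bnum, NumericVector bden,
              NumericVector cnum, NumericVector cden,
              NumericVector lbnum, NumericVector lbden,
              NumericVector ubnum, NumericVector ubden,
              bool maximize) {
  const int m = Anum.nrow(), n = Anum.ncol();
  std::vector<Rat> lb(n), ub(n), cobj(n);
  for (int j = 0; j < n; ++j) {
    lb[j] = from_pair(lbnum[j], lbden[j]);
    ub[j] = from_pair(ubnum[j], ubden[j]);
    cobj[j] = from_pair(cnum[j], cden[j]);
    if (cmp(lb[j], ub[j]) > 0) {
      return List::create(_["status"] = "infeasible");
    }
  }

  // shift x = v - lb; rows: m equalities then n upper-bound rows
  // columns: x (n), bound slacks (n), artificials (m)
  Tableau tab;
  tab.nrow = m + n;
  tab.ncol = 2 * n + m;
  tab.T.assign(tab.nrow, std::vector<Rat>(tab.ncol));
  tab.rhs.assign(tab.nrow, Rat());
  tab.basis.assign(tab.nrow, 0);

  for (int i = 0; i < m; ++i) {
    Rat bi = from_pair(bnum[i], bden[i]);
    for (int j = 0; j < n; ++j) {
      Rat a = from_pair(Anum(i, j), Aden(i, j));
      tab.T[i][j] = a;
      if (a.n != 0) bi = sub(bi, mul(a, lb[j]));
    }
    tab.rhs[i] = bi;
    if (sgn(bi) < 0) { // flip row so artificial basis is feasible
      for (int j = 0; j < n; ++j) tab.T[i][j] = sub(Rat(), tab.T[i][j]);
      tab.rhs[i] = sub(Rat(), bi);
    }
    tab.T[i][2 * n + i] = Rat(1, 1);
    tab.basis[i] = 2 * n + i;
  }
  for (int j = 0; j < n; ++j) {
    tab.T[m + j][j] = Rat(1, 1);
    tab.T[m + j][n + j] = Rat(1, 1);
    tab.rhs[m + j] = sub(ub[j], lb[j]);
    tab.basis[m + j] = n + j;
  }

  // phase I
  std::vector<Rat> cost1(tab.ncol);
  std::vector<bool> allowed(tab.ncol, true);
  for (int i = 0; i < m; ++i) cost1[2 * n + i] = Rat(1, 1);
  int st = tab.simplex(cost1, allowed);
  if (st == 2) return List::create(_["status"] = "maxiter");
  Rat p1;
  for (int i = 0; i < tab.nrow; ++i) {
    if (tab.basis[i] >= 2 * n) p1 = add(p1, tab.rhs[i]);
  }
  if (p1.n != 0) return List::create(_["status"] = "infeasible");
  // pivot residual zero-level artificials out where possible
  for (int i = 0; i < tab.nrow; ++i) {
    if (tab.basis[i] >= 2 * n) {
      for (int j = 0; j < 2 * n; ++j) {
        if (tab.T[i][j].n != 0) { tab.pivot(i, j); break; }
      }
    }
  }

  // phase II
  std::vector<Rat> cost2(tab.ncol);
  for (int j = 0; j < n; ++j) {
    cost2[j] = maximize ? sub(Rat(), cobj[j]) : cobj[j];
  }
  for (int j = 2 * n; j < tab.ncol; ++j) allowed[j] = false;
  st = tab.simplex(cost2, allowed);
  if (st == 1) return List::create(_["status"] = "unbounded");
  if (st == 2) return List::create(_["status"] = "maxiter");

  std::vector<Rat> x(n);
  for (int i = 0; i < tab.nrow; ++i) {
    if (tab.basis[i] < n) x[tab.basis[i]] = tab.rhs[i];
  }
  Rat obj;
  NumericVector vnum(n), vden(n), v(n);
  for (int j = 0; j < n; ++j) {
    Rat vj = add(x[j], lb[j]);
    vnum[j] = (double)vj.n;
    vden[j] = (double)vj.d;
    v[j] = (double)vj.n / (double)vj.d;
    if (cobj[j].n != 0) obj = add(obj, mul(cobj[j], vj));
  }
  return List::create(
    _["status"] = "optimal",
    _["objective"] = (double)obj.n / (double)obj.d,
    _["objective_num"] = (double)obj.n,
    _["objective_den"] = (double)obj.d,
    _["v"] = v, _["v_num"] = vnum, _["v_den"] = vden);
}
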