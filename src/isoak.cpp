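#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Maximum-weight matching of two small neighbor lists (degree <= 6) by
// exhaustive injective enumeration; returns the best total weight.
static double best_neighbor_matching(const std::vector<int>& na,
                                     const std::vector<int>& nb,
                                     const std::vector<int>& la,
                                     const std::vector<int>& lb,
                                     const NumericMatrix& s) {
  const int da = na.size(), db = nb.size();
  if (da == 0 || db == 0) return 0.0;
  // match each element of the smaller list to a distinct element of the larger
  const bool a_small = da <= db;
  const int ns = a_small ? da : db;
  const int nl = a_small ? db : da;
  std::vector<bool> used(nl, false);
  double best = 0.0;
  // recursive lambda via explicit stack-free recursion
  struct Rec {
    int ns, nl; bool a_small;
    const std::vector<int> &na, &nb, &la, &lb;
    const NumericMatrix& s;
    std::vector<bool>& used;
    double best;
    Rec(int ns_, int nl_, bool asm_, const std::vector<int>& na_,
        const std::vector<int>& nb_, const std::vector<int>& la_,
        const std::vector<int>& lb_, const NumericMatrix& s_, std::vector<bool>& u)
      : ns(ns_), nl(nl_), a_small(asm_), na(na_), nb(nb_), la(la_), lb(lb_),
        s(s_), used(u), best(0.0) {}
    void go(int i, double acc) {
      if (i == ns) { if (acc > best) best = acc; return; }
      // allow leaving i unmatched is never better since weights >= 0 and
      // injective maps to the larger side always exist (ns <= nl)
      for (int j = 0; j < nl; ++j) {
        if (used[j]) continue;
        int ai = a_small ? i : j;
        int bj = a_small ? j : i;
        double w = 0.0;
        if (la[ai] == lb[bj]) w = s(na[ai], nb[bj]);
        used[j] = true;
        go(i + 1, acc + w);
        used[j] = false;
      }
    }
  } rec(ns, nl, a_small, na, nb, la, lb, s, used);
  rec.go(0, 0.0);
  best = rec.best;
  return best;
}

// Iterative neighborhood-aware vertex similarity.
// base: |A| x |B| base similarities; adjA/adjB: 1-based neighbor lists;
// elabA/elabB: integer edge labels aligned with the adjacency lists.
// Fixed point of s = (1-alpha)*base + alpha*matchterm, synchronous updates.
// [[Rcpp::export]]
NumericMatrix isoak_iterate_cpp(NumericMatrix base, List adjA, List adjB,
                                List elabA, List elabB,
                                double alpha, double tol, int max_iter) {
  const int nA = base.nrow(), nB = base.ncol();
  std::vector<std::vector<int>> nbA(nA), nbB(nB), lbA(nA), lbB(nB);
  for (int i = 0; i < nA; ++i) {
    IntegerVector v = adjA[i], l = elabA[i];
    for (int k = 0; k < v.size(); ++k) { nbA[i].push_back(v[k] - 1); lbA[i].push_back(l[k]); }
  }
  for (int j = 0; j < nB; ++j) {
    IntegerVector v = adjB[j], l = elabB[j];
    for (int k = 0; k < v.size(); ++k) { nbB[j].push_back(v[k] - 1); lbB[j].push_back(l[k]); }
  }
  NumericMatrix s = clone(base);
  NumericMatrix s_new(nA, nB);
  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    double delta = 0.0;
    for (int i = 0; i < nA; ++i) {
      const int da = nbA[i].size();
      for (int j = 0; j < nB; ++j) {
        const int db = nbB[j].size();
        double neigh;
        if (da == 0 && db == 0) {
          neigh = base(i, j);          // isolated vertices: base carries through
        } else if (da == 0 || db == 0) {
          neigh = 0.0;
        } else {
          double m = best_neighbor_matching(nbA[i], nbB[j], lbA[i], lbB[j], s);
          neigh = m / (double)std::max(da, db);
        }
        double v = (1.0 - alpha) * base(i, j) + alpha * neigh;
        double d = std::fabs(v - s(i, j));
        if (d > delta) delta = d;
        s_new(i, j) = v;
      }
    }
    std::swap(s, s_new);
    if (delta < tol) { converged = true; ++iter; break; }
  }
  s.attr("iterations") = iter;
  s.attr("converged") = converged;
  return s;
}

// Hungarian algorithm (potentials formulation), minimizing; O(n^3).
// a is square (n+1) x (n+1) 1-based cost matrix packed in a vector.
static std::vector<int> hungarian_min(const std::vector<std::vector<double>>& a, int n) {
  const double INF = 1e18;
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<bool> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = a[i0][j] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  std::vector<int> row_of_col(n + 1);
  for (int j = 1; j <= n; ++j) row_of_col[j] = p[j];
  return row_of_col;
}

// Maximum-weight one-to-one assignment for a rectangular weight matrix.
// Returns list(assignment = integer vector over rows (0 = unassigned,
// else column index, 1-based), value = total weight).
// [[Rcpp::export]]
List hungarian_max_cpp(NumericMatrix w) {
  const int nr = w.nrow(), nc = w.ncol();
  const int n = std::max(nr, nc);
  double wmax = 0.0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (w(i, j) > wmax) wmax = w(i, j);
  std::vector<std::vector<double>> a(n + 1, std::vector<double>(n + 1, wmax));
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      a[i + 1][j + 1] = wmax - w(i, j);   // pad cells cost wmax (weight 0)
  std::vector<int> row_of_col = hungarian_min(a, n);
  IntegerVector assign(nr, 0);
  double value = 0.0;
  for (int j = 1; j <= n; ++j) {
    int i = row_of_col[j];
    if (i >= 1 && i <= nr && j <= nc) {
      assign[i - 1] = j;
      value += w(i - 1, j - 1);
    }
  }
  return List::create(Named("assignment") = assign, Named("value") = value);
}
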