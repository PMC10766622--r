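#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact solver for the discrete transportation problem
//   min sum_ij g_ij C_ij   s.t.  sum_j g_ij = mu_i,  sum_i g_ij = nu_j,  g >= 0
// by the primal transportation simplex on the spanning-tree basis of the
// bipartite supply/demand graph. mu and nu must be strictly positive and have
// equal totals (the caller balances them). Degenerate pivots are permitted;
// after a burn-in with the most-negative-reduced-cost rule the entering rule
// switches to Bland's rule, which cannot cycle.

namespace {

struct Basis {
  int m, n;                       // rows (supplies), cols (demands)
  std::vector<int> bi, bj;        // basic cells
  std::vector<double> bv;         // basic values
  // adjacency: node ids 0..m-1 rows, m..m+n-1 cols; edges indexed into bi/bj
  std::vector<std::vector<int>> adj;

  void rebuild_adj() {
    adj.assign(m + n, {});
    for (int e = 0; e < (int)bi.size(); ++e) {
      adj[bi[e]].push_back(e);
      adj[m + bj[e]].push_back(e);
    }
  }
};

// Compute dual potentials u (rows), v (cols) with u[0] = 0 by tree traversal.
void potentials(const Basis &B, const NumericMatrix &C,
                std::vector<double> &u, std::vector<double> &v) {
  const int m = B.m, n = B.n;
  u.assign(m, 0.0);
  v.assign(n, 0.0);
  std::vector<char> seen(m + n, 0);
  std::vector<int> stack;
  stack.push_back(0);
  seen[0] = 1;
  while (!stack.empty()) {
    int node = stack.back();
    stack.pop_back();
    for (int e : B.adj[node]) {
      int i = B.bi[e], j = B.bj[e];
      int other = (node == i) ? m + j : i;
      if (seen[other]) continue;
      seen[other] = 1;
      if (other >= m) v[other - m] = C(i, j) - u[i];
      else u[other] = C(i, j) - v[j];
      stack.push_back(other);
    }
  }
}

// Path in the basis tree from row node i to col node (m + j); returns the
// sequence of basic-edge indices.
std::vector<int> tree_path(const Basis &B, int from, int to) {
  const int N = B.m + B.n;
  std::vector<int> par_edge(N, -1), par_node(N, -1);
  std::vector<char> seen(N, 0);
  std::vector<int> queue;
  queue.push_back(from);
  seen[from] = 1;
  for (size_t q = 0; q < queue.size(); ++q) {
    int node = queue[q];
    if (node == to) break;
    for (int e : B.adj[node]) {
      int i = B.bi[e], j = B.bj[e];
      int other = (node == i) ? B.m + j : i;
      if (seen[other]) continue;
      seen[other] = 1;
      par_edge[other] = e;
      par_node[other] = node;
      queue.push_back(other);
    }
  }
  std::vector<int> path;
  for (int node = to; node != from; node = par_node[node]) {
    if (par_edge[node] < 0) stop("internal error: basis is not a tree");
    path.push_back(par_edge[node]);
  }
  return path; // from 'to' back to 'from'
}

} // namespace

// [[Rcpp::export(name = ".ot_exact_cpp")]]
List ot_exact_cpp(NumericVector mu, NumericVector nu, NumericMatrix C,
                  bool want_plan = false) {
  const int m = mu.size(), n = nu.size();
  if (C.nrow() != m || C.ncol() != n)
    stop("cost matrix dimensions do not match the marginals");
  for (int i = 0; i < m; ++i)
    if (!(mu[i] > 0)) stop("mu must be strictly positive");
  for (int j = 0; j < n; ++j)
    if (!(nu[j] > 0)) stop("nu must be strictly positive");

  // Trivial cases
  if (m == 1 || n == 1) {
    double cost = 0.0;
    NumericMatrix plan(m, n);
    if (m == 1) {
      for (int j = 0; j < n; ++j) { cost += nu[j] * C(0, j); plan(0, j) = nu[j]; }
    } else {
      for (int i = 0; i < m; ++i) { cost += mu[i] * C(i, 0); plan(i, 0) = mu[i]; }
    }
    if (want_plan) return List::create(_["cost"] = cost, _["plan"] = plan);
    return List::create(_["cost"] = cost);
  }

  // North-west-corner initial basic feasible solution (m + n - 1 cells,
  // possibly with degenerate zeros).
  Basis B;
  B.m = m; B.n = n;
  {
    std::vector<double> a(mu.begin(), mu.end()), b(nu.begin(), nu.end());
    int i = 0, j = 0;
    while (true) {
      double x = std::min(a[i], b[j]);
      B.bi.push_back(i); B.bj.push_back(j); B.bv.push_back(x);
      a[i] -= x; b[j] -= x;
      if (i == m - 1 && j == n - 1) break;
      if (a[i] <= 0 && i < m - 1) ++i; else ++j;
    }
  }
  B.rebuild_adj();

  const double tol = 1e-11;
  const long max_iter = 200000L;
  const long bland_after = 20000L;
  std::vector<double> u, v;

  for (long iter = 0;; ++iter) {
    if (iter >= max_iter) stop("transportation simplex failed to converge");
    potentials(B, C, u, v);

    // entering cell
    int ei = -1, ej = -1;
    double best = -tol;
    bool bland = iter >= bland_after;
    for (int i = 0; i < m && ei < 0; ++i) {
      for (int j = 0; j < n; ++j) {
        double rc = C(i, j) - u[i] - v[j];
        if (bland) {
          if (rc < -tol) { ei = i; ej = j; break; }
        } else if (rc < best) {
          best = rc; ei = i; ej = j;
        }
      }
      if (bland && ei >= 0) break;
    }
    if (ei < 0) break; // optimal

    // cycle: entering cell (ei, ej) plus tree path col(ej) -> row(ei);
    // path edges alternate -, +, -, ... starting at the edge incident to
    // the entering column.
    std::vector<int> path = tree_path(B, m + ej, ei);
    // path is listed from row ei back to col ej; orient from the column end:
    std::reverse(path.begin(), path.end()); // now starts at node m+ej
    double theta = std::numeric_limits<double>::infinity();
    int leave = -1;
    for (size_t k = 0; k < path.size(); k += 2) { // minus positions
      int e = path[k];
      if (B.bv[e] < theta - 1e-15 ||
          (std::abs(B.bv[e] - theta) <= 1e-15 && (leave < 0 || e < leave))) {
        theta = B.bv[e];
        leave = e;
      }
    }
    if (leave < 0) stop("internal error: no leaving variable");
    for (size_t k = 0; k < path.size(); ++k) {
      if (k % 2 == 0) B.bv[path[k]] -= theta;
      else B.bv[path[k]] += theta;
    }
    // replace leaving cell by entering cell
    B.bi[leave] = ei; B.bj[leave] = ej; B.bv[leave] = theta;
    B.rebuild_adj();
  }

  double cost = 0.0;
  for (size_t e = 0; e < B.bi.size(); ++e)
    if (B.bv[e] > 0) cost += B.bv[e] * C(B.bi[e], B.bj[e]);

  if (want_plan) {
    NumericMatrix plan(m, n);
    for (size_t e = 0; e < B.bi.size(); ++e)
      if (B.bv[e] > 0) plan(B.bi[e], B.bj[e]) = B.bv[e];
    return List::create(_["cost"] = cost, _["plan"] = plan);
  }
  return List::create(_["cost"] = cost);
}
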