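#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// Dinic max-flow / min-cut on a small graph, used for exact binary fusion
// moves in the discrete flow optimizer.
namespace {

struct Dinic {
  struct Edge { int to; double cap; int rev; };
  std::vector<std::vector<Edge>> g;
  std::vector<int> level, iter;
  explicit Dinic(int n) : g(n), level(n), iter(n) {}
  void add_edge(int from, int to, double cap, double rcap = 0.0) {
    g[from].push_back({to, cap, (int)g[to].size()});
    g[to].push_back({from, rcap, (int)g[from].size() - 1});
  }
  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (auto &e : g[v]) {
        if (e.cap > 1e-12 && level[e.to] < 0) {
          level[e.to] = level[v] + 1;
          q.push(e.to);
        }
      }
    }
    return level[t] >= 0;
  }
  double dfs(int v, int t, double f) {
    if (v == t) return f;
    for (int &i = iter[v]; i < (int)g[v].size(); ++i) {
      Edge &e = g[v][i];
      if (e.cap > 1e-12 && level[v] < level[e.to]) {
        double d = dfs(e.to, t, std::min(f, e.cap));
        if (d > 0) {
          e.cap -= d;
          g[e.to][e.rev].cap += d;
          return d;
        }
      }
    }
    return 0.0;
  }
  double maxflow(int s, int t) {
    double flow = 0.0;
    const double INF = std::numeric_limits<double>::infinity();
    while (bfs(s, t)) {
      std::fill(iter.begin(), iter.end(), 0);
      double f;
      while ((f = dfs(s, t, INF)) > 0) flow += f;
    }
    return flow;
  }
  // nodes reachable from s in the residual graph (source side of min cut)
  std::vector<char> min_cut_source_side(int s) {
    std::vector<char> vis(g.size(), 0);
    std::queue<int> q;
    vis[s] = 1; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (auto &e : g[v]) {
        if (e.cap > 1e-12 && !vis[e.to]) { vis[e.to] = 1; q.push(e.to); }
      }
    }
    return vis;
  }
};

} // namespace

// Exact minimizer of a submodular binary pairwise energy
//   E(x) = sum_p [ u1[p]*x_p + u0[p]*(1-x_p) ]
//        + sum_e theta_e(x_{pa[e]}, x_{pb[e]})
// with theta_e given by (A, B, C, D) = costs of (0,0), (0,1), (1,0), (1,1);
// requires B + C >= A + D for every edge. Returns the 0/1 labeling.
// [[Rcpp::export]]
IntegerVector fusion_move_cpp(NumericVector u0, NumericVector u1,
                              IntegerVector pa, IntegerVector pb,
                              NumericVector A, NumericVector B,
                              NumericVector C, NumericVector D) {
  const int n = u0.size();
  const int m = pa.size();
  std::vector<double> lam(n); // cost(x_p = 1) - cost(x_p = 0)
  for (int p = 0; p < n; ++p) lam[p] = u1[p] - u0[p];
  std::vector<double> k(m);
  for (int e = 0; e < m; ++e) {
    double kk = B[e] + C[e] - A[e] - D[e];
    if (kk < -1e-9) stop("non-submodular pairwise term in fusion move");
    if (kk < 0) kk = 0;
    k[e] = kk;
    // theta = const + (D-B) x_p + (B-A) x_q + k * x_p (1 - x_q)
    lam[pa[e]] += D[e] - B[e];
    lam[pb[e]] += B[e] - A[e];
  }
  int s = n, t = n + 1;
  Dinic din(n + 2);
  // x_p = 1 <=> p on source side; cutting s->p costs apply when x_p = 0,
  // cutting p->t when x_p = 1
  for (int p = 0; p < n; ++p) {
    if (lam[p] > 0) din.add_edge(p, t, lam[p]);
    else if (lam[p] < 0) din.add_edge(s, p, -lam[p]);
  }
  for (int e = 0; e < m; ++e) {
    if (k[e] > 0) din.add_edge(pa[e], pb[e], k[e]);
  }
  din.maxflow(s, t);
  std::vector<char> side = din.min_cut_source_side(s);
  IntegerVector x(n);
  for (int p = 0; p < n; ++p) x[p] = side[p] ? 1 : 0;
  return x;
}
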