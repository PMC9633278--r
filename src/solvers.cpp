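// Compiled numerical cores: a successive-shortest-path minimum-cost flow
// solver (used both for the exact generalized Wasserstein distance and for
// the feature-matching networks) and the log-domain Sinkhorn-Knopp scaling
// loop for entropically regularized unbalanced transport.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Edge {
  int to;
  double cap;
  double cost;
  int rev;  // index of the reverse edge in adj[to]
};

// Capacities below this residual are treated as saturated; keeps the
// augmentation loop finite with real-valued masses.
const double CAP_EPS = 1e-12;

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".mcf_solve")]]
List mcf_solve(IntegerVector from, IntegerVector to, NumericVector cap,
               NumericVector cost, int n_nodes, int source, int sink,
               double target_flow) {
  const int m = from.size();
  if (to.size() != m || cap.size() != m || cost.size() != m)
    stop("edge vectors must have equal length");
  std::vector<std::vector<Edge> > adj(n_nodes);
  std::vector<std::pair<int, int> > loc(m);  // (node, index) of each input edge
  for (int e = 0; e < m; ++e) {
    int u = from[e] - 1, v = to[e] - 1;
    if (u < 0 || u >= n_nodes || v < 0 || v >= n_nodes)
      stop("edge endpoint out of range");
    if (cost[e] < 0) stop("negative edge costs are not supported");
    Edge fwd = {v, cap[e], cost[e], static_cast<int>(adj[v].size())};
    Edge bwd = {u, 0.0, -cost[e], static_cast<int>(adj[u].size())};
    adj[u].push_back(fwd);
    loc[e] = std::make_pair(u, static_cast<int>(adj[u].size()) - 1);
    adj[v].push_back(bwd);
  }

  const int s = source - 1, t = sink - 1;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> pot(n_nodes, 0.0), dist(n_nodes);
  std::vector<int> pv(n_nodes), pe(n_nodes);
  double flow = 0.0, total_cost = 0.0;

  while (flow + CAP_EPS < target_flow) {
    std::fill(dist.begin(), dist.end(), INF);
    dist[s] = 0.0;
    typedef std::pair<double, int> QItem;
    std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;
    pq.push(std::make_pair(0.0, s));
    while (!pq.empty()) {
      double d = pq.top().first;
      int u = pq.top().second;
      pq.pop();
      if (d > dist[u] + CAP_EPS) continue;
      for (int i = 0; i < static_cast<int>(adj[u].size()); ++i) {
        const Edge &e = adj[u][i];
        if (e.cap <= CAP_EPS) continue;
        double rc = e.cost + pot[u] - pot[e.to];
        if (rc < 0.0) rc = 0.0;  // clamp FP noise in reduced costs
        double nd = d + rc;
        if (nd < dist[e.to] - CAP_EPS) {
          dist[e.to] = nd;
          pv[e.to] = u;
          pe[e.to] = i;
          pq.push(std::make_pair(nd, e.to));
        }
      }
    }
    if (dist[t] == INF) break;  // no augmenting path left
    for (int v = 0; v < n_nodes; ++v)
      if (dist[v] < INF) pot[v] += dist[v];

    double push = target_flow - flow;
    for (int v = t; v != s; v = pv[v])
      push = std::min(push, adj[pv[v]][pe[v]].cap);
    for (int v = t; v != s; v = pv[v]) {
      Edge &e = adj[pv[v]][pe[v]];
      e.cap -= push;
      adj[e.to][e.rev].cap += push;
      total_cost += push * e.cost;
    }
    flow += push;
  }

  NumericVector eflow(m);
  for (int e = 0; e < m; ++e) {
    const Edge &fe = adj[loc[e].first][loc[e].second];
    eflow[e] = adj[fe.to][fe.rev].cap;  // flow sent = reverse residual
  }
  return List::create(_["flow"] = eflow, _["total_flow"] = flow,
                      _["total_cost"] = total_cost);
}

//' @noRd
// [[Rcpp::export(name = ".sinkhorn_core")]]
List sinkhorn_core(NumericVector mu, NumericVector nu, NumericMatrix C,
                   double lambda, double eps, double tol, int max_iter) {
  const int n = mu.size(), m = nu.size();
  if (C.nrow() != n || C.ncol() != m) stop("cost matrix dimension mismatch");
  std::vector<double> f(n, 0.0), g(m, 0.0), lmu(n), lnu(m);
  double mass_mu = 0.0, mass_nu = 0.0;
  for (int i = 0; i < n; ++i) {
    if (mu[i] <= 0) stop("measure weights must be positive");
    lmu[i] = std::log(mu[i]);
    mass_mu += mu[i];
  }
  for (int j = 0; j < m; ++j) {
    if (nu[j] <= 0) stop("measure weights must be positive");
    lnu[j] = std::log(nu[j]);
    mass_nu += nu[j];
  }

  std::vector<double> Tmu(n, 0.0), Tnu(m, 0.0);
  bool converged = false;
  int it = 0;

  // log-sum-exp of (h[k] - C(row/col))/eps along one axis
  while (it < max_iter) {
    ++it;
    // f-update: f_i = min(lambda, eps * (log mu_i - lse_j((g_j - C_ij)/eps)))
    // Tmu then holds the row prox target min(mu_i, e^{lambda/eps} (Kv)_i).
    for (int i = 0; i < n; ++i) {
      double mx = -std::numeric_limits<double>::infinity();
      for (int j = 0; j < m; ++j) {
        double v = (g[j] - C(i, j)) / eps;
        if (v > mx) mx = v;
      }
      double acc = 0.0;
      for (int j = 0; j < m; ++j) acc += std::exp((g[j] - C(i, j)) / eps - mx);
      double lse = mx + std::log(acc);
      f[i] = std::min(lambda, eps * (lmu[i] - lse));
      Tmu[i] = std::exp(f[i] / eps + lse);
    }
    // g-update, symmetric; columns of the plan match Tnu exactly afterwards
    for (int j = 0; j < m; ++j) {
      double mx = -std::numeric_limits<double>::infinity();
      for (int i = 0; i < n; ++i) {
        double v = (f[i] - C(i, j)) / eps;
        if (v > mx) mx = v;
      }
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += std::exp((f[i] - C(i, j)) / eps - mx);
      double lse = mx + std::log(acc);
      g[j] = std::min(lambda, eps * (lnu[j] - lse));
      Tnu[j] = std::exp(g[j] / eps + lse);
    }
    // Joint convergence: the g-update rescaled the columns, so re-measure the
    // row marginals and compare with the f-update's prox target. At a joint
    // fixed point the two coincide; the gap is the marginal violation.
    double viol = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = -std::numeric_limits<double>::infinity();
      for (int j = 0; j < m; ++j) {
        double v = (g[j] - C(i, j)) / eps;
        if (v > mx) mx = v;
      }
      double acc = 0.0;
      for (int j = 0; j < m; ++j) acc += std::exp((g[j] - C(i, j)) / eps - mx);
      double lse = mx + std::log(acc);
      double row_now = std::exp(f[i] / eps + lse);
      viol = std::max(viol, std::fabs(row_now - Tmu[i]));
      Tmu[i] = row_now;
    }
    if (viol < tol) {
      converged = true;
      break;
    }
  }

  // Transport-part objective on the resulting plan; entropy term excluded.
  NumericMatrix T(n, m);
  double transport = 0.0, moved = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double tij = std::exp((f[i] + g[j] - C(i, j)) / eps);
      T(i, j) = tij;
      transport += tij * C(i, j);
      moved += tij;
    }
  double cost = transport + lambda * std::max(0.0, mass_mu - moved) +
                lambda * std::max(0.0, mass_nu - moved);

  return List::create(_["cost"] = cost, _["plan"] = T,
                      _["converged"] = converged, _["iterations"] = it,
                      _["mu_marginal"] = NumericVector(Tmu.begin(), Tmu.end()),
                      _["nu_marginal"] = NumericVector(Tnu.begin(), Tnu.end()));
}
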