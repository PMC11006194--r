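#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Compiled Moran trajectory engine. Sampling uses R's RNG (unif_rand), so
// trajectories are reproducible under set.seed() from R. Each step samples
// one replacement event by a linear inverse-CDF scan, recomputed from the
// current configuration; nothing is cached across steps.

struct Graph {
  int N;
  std::vector<std::vector<int> > nbr;    // 0-based neighbour indices
  std::vector<std::vector<double> > nbw; // matching edge weights
  std::vector<double> deg;               // weighted degrees
};

static Graph build_graph(const List& nbr, const List& nbw, const NumericVector& deg) {
  Graph g;
  g.N = nbr.size();
  g.nbr.resize(g.N);
  g.nbw.resize(g.N);
  g.deg.resize(g.N);
  for (int i = 0; i < g.N; ++i) {
    IntegerVector ni = nbr[i];
    NumericVector wi = nbw[i];
    g.nbr[i].assign(ni.begin(), ni.end());
    for (size_t j = 0; j < g.nbr[i].size(); ++j) g.nbr[i][j] -= 1; // to 0-based
    g.nbw[i].assign(wi.begin(), wi.end());
    g.deg[i] = deg[i];
  }
  return g;
}

// One Moran step; mutates `mut` and the mutant count `k`.
static inline void moran_step_c(const Graph& g, std::vector<char>& mut, int& k,
                                bool bd, double r) {
  int u, v;
  if (bd) {
    // Birth: fitness-proportional reproducer u.
    double F = (g.N - k) + r * k;
    double x = unif_rand() * F, acc = 0.0;
    u = g.N - 1;
    for (int i = 0; i < g.N; ++i) {
      acc += mut[i] ? r : 1.0;
      if (x <= acc) { u = i; break; }
    }
    // death: weight-proportional neighbour v of u.
    const std::vector<int>& nb = g.nbr[u];
    const std::vector<double>& wv = g.nbw[u];
    double y = unif_rand() * g.deg[u];
    acc = 0.0;
    v = nb.back();
    for (size_t j = 0; j < nb.size(); ++j) {
      acc += wv[j];
      if (y <= acc) { v = nb[j]; break; }
    }
  } else {
    // death: uniform v.
    v = (int)(unif_rand() * g.N);
    if (v >= g.N) v = g.N - 1;
    // Birth: neighbours compete with fitness x weight.
    const std::vector<int>& nb = g.nbr[v];
    const std::vector<double>& wv = g.nbw[v];
    double tot = 0.0;
    for (size_t j = 0; j < nb.size(); ++j)
      tot += (mut[nb[j]] ? r : 1.0) * wv[j];
    double y = unif_rand() * tot, acc = 0.0;
    u = nb.back();
    for (size_t j = 0; j < nb.size(); ++j) {
      acc += (mut[nb[j]] ? r : 1.0) * wv[j];
      if (y <= acc) { u = nb[j]; break; }
    }
  }
  if (mut[u] != mut[v]) {
    mut[v] = mut[u];
    k += mut[u] ? 1 : -1;
  }
}

// [[Rcpp::export]]
List mc_fixation_cpp(List nbr, List nbw, NumericVector deg, bool bd, double r,
                     List inits, double max_steps) {
  Graph g = build_graph(nbr, nbw, deg);
  int reps = inits.size();
  IntegerVector outcome(reps);
  NumericVector steps(reps);
  for (int rep = 0; rep < reps; ++rep) {
    std::vector<char> mut(g.N, 0);
    IntegerVector s0 = inits[rep];
    int k = 0;
    for (int i = 0; i < s0.size(); ++i) {
      int node = s0[i] - 1;
      if (!mut[node]) { mut[node] = 1; ++k; }
    }
    double st = 0.0;
    while (k > 0 && k < g.N && st < max_steps) {
      moran_step_c(g, mut, k, bd, r);
      st += 1.0;
    }
    steps[rep] = st;
    outcome[rep] = (k == g.N) ? 1 : (k == 0 ? 0 : NA_INTEGER);
    if ((rep & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["outcome"] = outcome, _["steps"] = steps);
}

// First-event survival: from a single mutant at u0 (1-based), run until the
// mutant count first changes; report 1 if it increased (the mutant lineage
// survived its first configuration-changing event), 0 otherwise.
// [[Rcpp::export]]
IntegerVector mc_first_event_cpp(List nbr, List nbw, NumericVector deg, bool bd,
                                 double r, int u0, int reps) {
  Graph g = build_graph(nbr, nbw, deg);
  IntegerVector out(reps);
  for (int rep = 0; rep < reps; ++rep) {
    std::vector<char> mut(g.N, 0);
    mut[u0 - 1] = 1;
    int k = 1;
    while (k == 1) moran_step_c(g, mut, k, bd, r);
    out[rep] = (k == 2) ? 1 : 0;
    if ((rep & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
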