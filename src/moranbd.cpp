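#include <Rcpp.h>
#include <set>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---- exact solver support -------------------------------------------------

// Sparse triplets of the one-step transition matrix of the Moran Bd process
// over all 2^n mutant configurations (state = bitmask, 0-based bits).
// Row/col indices returned 1-based (state mask + 1). Includes lazy
// self-transitions (like replacing like). Absorbing rows (empty/full) get a
// single unit self-loop.
// [[Rcpp::export]]
List cpp_transition_triplets(int n, List adj, double r) {
  int nstates = 1 << n;
  std::vector<std::vector<int>> out(n);
  for (int u = 0; u < n; ++u) out[u] = as<std::vector<int>>(adj[u]);

  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(nstates * (n + 1));
  tj.reserve(nstates * (n + 1));
  tx.reserve(nstates * (n + 1));

  std::vector<double> acc(nstates, 0.0);
  std::vector<int> touched;
  touched.reserve(2 * n);

  int full = nstates - 1;
  for (int S = 0; S < nstates; ++S) {
    if (S == 0 || S == full) {
      ti.push_back(S + 1); tj.push_back(S + 1); tx.push_back(1.0);
      continue;
    }
    int m = 0;
    for (int u = 0; u < n; ++u) if (S >> u & 1) ++m;
    double F = r * m + (n - m);
    for (int u = 0; u < n; ++u) {
      bool mu = (S >> u) & 1;
      double w = (mu ? r : 1.0) / F;
      int deg = (int)out[u].size();
      double p = w / deg;
      for (int j = 0; j < deg; ++j) {
        int v = out[u][j];
        int T = mu ? (S | (1 << v)) : (S & ~(1 << v));
        if (acc[T] == 0.0) touched.push_back(T);
        acc[T] += p;
      }
    }
    for (size_t k = 0; k < touched.size(); ++k) {
      int T = touched[k];
      ti.push_back(S + 1); tj.push_back(T + 1); tx.push_back(acc[T]);
      acc[T] = 0.0;
    }
    touched.clear();
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}

// ---- enumeration ----------------------------------------------------------

static inline bool scc_check(int n, const int *outmask, const int *inmask) {
  int fullmask = (1 << n) - 1;
  // every node needs an out- and an in-edge
  for (int u = 0; u < n; ++u)
    if (outmask[u] == 0 || inmask[u] == 0) return false;
  // forward reachability from node 0
  int reach = 1, prev = 0;
  while (reach != prev) {
    prev = reach;
    for (int u = 0; u < n; ++u)
      if (reach >> u & 1) reach |= outmask[u];
  }
  if (reach != fullmask) return false;
  // backward reachability from node 0
  reach = 1; prev = 0;
  while (reach != prev) {
    prev = reach;
    for (int u = 0; u < n; ++u)
      if (reach >> u & 1) reach |= inmask[u];
  }
  return reach == fullmask;
}

static void all_perms(int n, std::vector<std::vector<int>> &perms) {
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  do { perms.push_back(p); } while (std::next_permutation(p.begin(), p.end()));
}

// Canonical key of a digraph on n nodes: the adjacency matrix read as an
// n*n-bit integer (bit u*n+v set iff edge u->v), minimized over all node
// permutations. Two digraphs are isomorphic iff their keys agree.
// [[Rcpp::export]]
double cpp_canonical_key(int n, IntegerMatrix edges) {
  if (n > 7) stop("canonical key limited to n <= 7");
  std::vector<std::vector<int>> perms;
  all_perms(n, perms);
  uint64_t best = UINT64_MAX;
  int ne = edges.nrow();
  for (size_t pi = 0; pi < perms.size(); ++pi) {
    const std::vector<int> &p = perms[pi];
    uint64_t key = 0;
    for (int e = 0; e < ne; ++e) {
      int u = p[edges(e, 0)], v = p[edges(e, 1)];
      key |= ((uint64_t)1) << (u * n + v);
    }
    if (key < best) best = key;
  }
  return (double)best;
}

// Exhaustive isomorphism-free enumeration of strongly connected digraphs on
// n nodes: iterate all 2^(n(n-1)) labeled edge sets, filter by strong
// connectivity, canonicalize over all n! permutations. Returns the sorted
// canonical keys (one per isomorphism class).
// [[Rcpp::export]]
NumericVector cpp_enumerate_scc(int n) {
  if (n < 2 || n > 6) stop("enumeration limited to 2 <= n <= 6");
  int nslots = n * (n - 1);
  // slot s -> ordered pair (u, v)
  std::vector<int> su(nslots), sv(nslots);
  {
    int s = 0;
    for (int u = 0; u < n; ++u)
      for (int v = 0; v < n; ++v)
        if (u != v) { su[s] = u; sv[s] = v; ++s; }
  }
  std::vector<std::vector<int>> perms;
  all_perms(n, perms);
  int np = (int)perms.size();
  // slotmap[p][s]: bit position of slot s after applying permutation p
  std::vector<std::vector<int>> slotmap(np, std::vector<int>(nslots));
  for (int p = 0; p < np; ++p)
    for (int s = 0; s < nslots; ++s)
      slotmap[p][s] = perms[p][su[s]] * n + perms[p][sv[s]];

  std::set<uint64_t> keys;
  std::vector<int> outmask(n), inmask(n), setslots;
  setslots.reserve(nslots);
  uint64_t total = ((uint64_t)1) << nslots;
  for (uint64_t mask = 0; mask < total; ++mask) {
    if ((mask & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    std::fill(outmask.begin(), outmask.end(), 0);
    std::fill(inmask.begin(), inmask.end(), 0);
    setslots.clear();
    for (int s = 0; s < nslots; ++s) {
      if (mask >> s & 1) {
        outmask[su[s]] |= 1 << sv[s];
        inmask[sv[s]] |= 1 << su[s];
        setslots.push_back(s);
      }
    }
    if (!scc_check(n, outmask.data(), inmask.data())) continue;
    uint64_t best = UINT64_MAX;
    for (int p = 0; p < np; ++p) {
      uint64_t key = 0;
      const std::vector<int> &sm = slotmap[p];
      for (size_t k = 0; k < setslots.size(); ++k)
        key |= ((uint64_t)1) << sm[setslots[k]];
      if (key < best) best = key;
    }
    keys.insert(best);
  }
  NumericVector res(keys.size());
  int i = 0;
  for (std::set<uint64_t>::iterator it = keys.begin(); it != keys.end(); ++it)
    res[i++] = (double)*it;
  return res;
}

// ---- simulation -----------------------------------------------------------

// Batch of independent Moran Bd trajectories. Uses R's RNG stream (seed with
// set.seed() before the call). start: 0-based mutant nodes; if
// uniform_start, each run instead starts from one uniformly chosen node.
// Returns a matrix with columns (outcome, steps): outcome 1 = fixed,
// 0 = extinct, -1 = censored at step_cap. Steps count every Bd event,
// including lazy self-replacements.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_runs(int n, List adj, double r,
                                IntegerVector start, bool uniform_start,
                                int n_runs, double step_cap) {
  std::vector<std::vector<int>> out(n);
  for (int u = 0; u < n; ++u) out[u] = as<std::vector<int>>(adj[u]);
  NumericMatrix res(n_runs, 2);

  std::vector<int> type(n), mut(n), resid(n), pos(n);
  for (int run = 0; run < n_runs; ++run) {
    int m = 0;
    std::fill(type.begin(), type.end(), 0);
    if (uniform_start) {
      int s = (int)(unif_rand() * n); if (s >= n) s = n - 1;
      type[s] = 1;
    } else {
      for (int k = 0; k < start.size(); ++k) type[start[k]] = 1;
    }
    int nm = 0, nr = 0;
    for (int u = 0; u < n; ++u) {
      if (type[u]) { mut[nm] = u; pos[u] = nm; ++nm; }
      else { resid[nr] = u; pos[u] = nr; ++nr; }
    }
    m = nm;
    double steps = 0.0;
    int outcome;
    for (;;) {
      if (m == 0) { outcome = 0; break; }
      if (m == n) { outcome = 1; break; }
      if (steps >= step_cap) { outcome = -1; break; }
      double F = r * m + (n - m);
      double x = unif_rand() * F;
      int parent;
      if (x < r * m) {
        int idx = (int)(x / r); if (idx >= m) idx = m - 1;
        parent = mut[idx];
      } else {
        int idx = (int)(x - r * m); if (idx >= n - m) idx = n - m - 1;
        parent = resid[idx];
      }
      const std::vector<int> &nb = out[parent];
      int deg = (int)nb.size();
      int j = (int)(unif_rand() * deg); if (j >= deg) j = deg - 1;
      int v = nb[j];
      steps += 1.0;
      if (type[v] != type[parent]) {
        if (type[v]) {
          // mutant at v dies: remove from mut list, add to resid
          int pv = pos[v], last = mut[m - 1];
          mut[pv] = last; pos[last] = pv;
          resid[n - m] = v; pos[v] = n - m;
          type[v] = 0; --m;
        } else {
          int pv = pos[v], last = resid[n - m - 1];
          resid[pv] = last; pos[last] = pv;
          mut[m] = v; pos[v] = m;
          type[v] = 1; ++m;
        }
      }
    }
    res(run, 0) = outcome;
    res(run, 1) = steps;
  }
  return res;
}
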