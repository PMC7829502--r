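// Generalized Louvain heuristic on a dense supra-modularity matrix.
//
// The R side assembles B with intra-layer blocks A_s - gamma * k k'/2m_s
// and inter-layer ordinal coupling omega on same-node, adjacent-layer
// entries; this file only maximizes sum_{ij} B_ij delta(M_i, M_j).
// Randomness comes from a self-contained splitmix64 generator so that a
// given seed reproduces the same partition on every platform.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// Fisher-Yates permutation of 0..n-1 driven by splitmix64.
static void rand_perm(std::vector<int> &perm, uint64_t &state) {
  const int n = (int)perm.size();
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(splitmix64(state) % (uint64_t)(i + 1));
    std::swap(perm[i], perm[j]);
  }
}

// Greedy move phase on a dense matrix. comm is modified in place.
// Returns true when at least one move was accepted. Accepted moves have
// gain > tol, so the objective is strictly non-decreasing.
static bool move_phase(const std::vector<double> &B, int n,
                       std::vector<int> &comm, uint64_t &rng,
                       int max_sweeps, double tol) {
  std::vector<int> perm(n);
  std::vector<double> wt(n, 0.0);
  std::vector<int> touched;
  touched.reserve(n);
  bool any_move = false;
  for (int sweep = 0; ; ++sweep) {
    if (sweep >= max_sweeps)
      stop("Louvain move phase did not converge within %d sweeps; "
           "input is pathological", max_sweeps);
    rand_perm(perm, rng);
    bool moved = false;
    for (int t = 0; t < n; ++t) {
      const int i = perm[t];
      touched.clear();
      const double *row = &B[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double w = row[j];
        if (w == 0.0) continue;
        const int c = comm[j];
        if (wt[c] == 0.0 && std::find(touched.begin(), touched.end(), c)
              == touched.end())
          touched.push_back(c);
        wt[c] += w;
      }
      const int cur = comm[i];
      // own community weight (may be absent from touched if empty/zero)
      if (std::find(touched.begin(), touched.end(), cur) == touched.end())
        touched.push_back(cur);
      std::sort(touched.begin(), touched.end());
      const double wcur = wt[cur];
      int best = cur;
      double best_gain = tol;   // a move must beat the current community
      for (size_t u = 0; u < touched.size(); ++u) {
        const int c = touched[u];
        if (c == cur) continue;
        const double gain = wt[c] - wcur;
        if (gain > best_gain) { best = c; best_gain = gain; }
        // ties: ascending scan with strict '>' keeps the lowest id
      }
      if (best != cur) {
        comm[i] = best;
        moved = true;
        any_move = true;
      }
      for (size_t u = 0; u < touched.size(); ++u) wt[touched[u]] = 0.0;
    }
    if (!moved) break;
  }
  return any_move;
}

// Relabel communities to consecutive 0..m-1 (ascending original id).
static int relabel(std::vector<int> &comm) {
  std::vector<int> ids(comm);
  std::sort(ids.begin(), ids.end());
  ids.erase(std::unique(ids.begin(), ids.end()), ids.end());
  std::vector<int> map_(comm.size(), -1);
  for (size_t k = 0; k < ids.size(); ++k) map_[ids[k]] = (int)k;
  for (size_t i = 0; i < comm.size(); ++i) comm[i] = map_[comm[i]];
  return (int)ids.size();
}

// [[Rcpp::export(name = ".genlouvain_cpp")]]
List genlouvain_cpp(NumericMatrix B, double two_mu, double seed,
                    int max_sweeps = 100, double tol = 1e-10) {
  const int n0 = B.nrow();
  if (B.ncol() != n0) stop("B must be square");
  uint64_t rng = (uint64_t)seed * 0x9e3779b97f4a7c15ULL + 1ULL;

  // working copy at the current aggregation level
  std::vector<double> Bcur((size_t)n0 * n0);
  for (int j = 0; j < n0; ++j)
    for (int i = 0; i < n0; ++i)
      Bcur[(size_t)i * n0 + j] = B(i, j);

  std::vector<int> assign(n0);              // original node -> community
  for (int i = 0; i < n0; ++i) assign[i] = i;
  int n = n0;

  for (int level = 0; level < 100; ++level) {
    std::vector<int> comm(n);
    for (int i = 0; i < n; ++i) comm[i] = i;
    bool improved = move_phase(Bcur, n, comm, rng, max_sweeps, tol);
    int m = relabel(comm);
    for (int i = 0; i < n0; ++i) assign[i] = comm[assign[i]];
    if (!improved || m == n) break;
    // aggregate: communities become the nodes of the next level
    std::vector<double> Bnew((size_t)m * m, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        Bnew[(size_t)comm[i] * m + comm[j]] += Bcur[(size_t)i * n + j];
    Bcur.swap(Bnew);
    n = m;
  }

  // objective on the original matrix, normalized by 2*mu
  double total = 0.0;
  for (int i = 0; i < n0; ++i) {
    for (int j = 0; j < n0; ++j) {
      if (assign[i] == assign[j]) total += B(i, j);
    }
  }
  IntegerVector labels(n0);
  for (int i = 0; i < n0; ++i) labels[i] = assign[i] + 1;
  return List::create(_["labels"] = labels,
                      _["q"] = total / two_mu);
}
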