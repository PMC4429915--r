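#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Ranked sequences are integer vectors; NA_INTEGER marks an absent event.
// Event universes are capped at 64 so conflict graphs fit in uint64_t
// adjacency masks.

static inline int popcnt(uint64_t x) {
#ifdef __GNUC__
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

static inline int lowbit(uint64_t x) {
#ifdef __GNUC__
  return __builtin_ctzll(x);
#else
  int i = 0; while (!((x >> i) & 1ULL)) ++i; return i;
#endif
}

// Build the conflict graph between two sequences: vertices are events, an
// edge joins events i,j whose pair relation (before/simultaneous/after) is
// defined in both sequences and differs. Returns number of edges.
static int build_conflicts(const int* a, const int* b, int n,
                           std::vector<uint64_t>& adj) {
  int m = 0;
  for (int i = 0; i < n; ++i) adj[i] = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] == NA_INTEGER || b[i] == NA_INTEGER) continue;
    for (int j = i + 1; j < n; ++j) {
      if (a[j] == NA_INTEGER || b[j] == NA_INTEGER) continue;
      int ra = (a[i] < a[j]) ? -1 : (a[i] > a[j] ? 1 : 0);
      int rb = (b[i] < b[j]) ? -1 : (b[i] > b[j] ? 1 : 0);
      if (ra != rb) {
        adj[i] |= (1ULL << j);
        adj[j] |= (1ULL << i);
        ++m;
      }
    }
  }
  return m;
}

static void remove_vertex(std::vector<uint64_t>& adj, int v) {
  uint64_t nb = adj[v];
  while (nb) {
    int u = lowbit(nb);
    nb &= nb - 1;
    adj[u] &= ~(1ULL << v);
  }
  adj[v] = 0;
}

// greedy matching lower bound on vertex cover size
static int matching_bound(const std::vector<uint64_t>& adj, int n) {
  uint64_t used = 0;
  int m = 0;
  for (int i = 0; i < n; ++i) {
    if ((used >> i) & 1ULL) continue;
    uint64_t nb = adj[i] & ~used;
    if (nb) {
      int j = lowbit(nb);
      used |= (1ULL << i) | (1ULL << j);
      ++m;
    }
  }
  return m;
}

// exact minimum vertex cover by branch and bound with degree-1 reduction
static void mvc_search(std::vector<uint64_t>& adj, int n, int depth, int& best) {
  // degree-1 reduction: the neighbour of a pendant vertex is in some MVC
  bool reduced = true;
  while (reduced) {
    reduced = false;
    for (int i = 0; i < n; ++i) {
      if (adj[i] && popcnt(adj[i]) == 1) {
        int w = lowbit(adj[i]);
        remove_vertex(adj, w);
        ++depth;
        if (depth >= best) return;
        reduced = true;
      }
    }
  }
  int v = -1, dv = 0;
  for (int i = 0; i < n; ++i) {
    int d = popcnt(adj[i]);
    if (d > dv) { dv = d; v = i; }
  }
  if (v < 0) { if (depth < best) best = depth; return; }
  if (depth + matching_bound(adj, n) >= best) return;
  // branch 1: v in the cover
  {
    std::vector<uint64_t> adj2(adj);
    remove_vertex(adj2, v);
    mvc_search(adj2, n, depth + 1, best);
  }
  // branch 2: v not in the cover => all its neighbours are
  {
    if (depth + dv < best) {
      std::vector<uint64_t> adj2(adj);
      uint64_t nb = adj[v];
      while (nb) {
        int u = lowbit(nb);
        nb &= nb - 1;
        remove_vertex(adj2, u);
      }
      mvc_search(adj2, n, depth + dv, best);
    }
  }
}

static int mvc_size(std::vector<uint64_t> adj, int n) {
  // greedy upper bound
  std::vector<uint64_t> g(adj);
  int ub = 0;
  for (;;) {
    int v = -1, dv = 0;
    for (int i = 0; i < n; ++i) {
      int d = popcnt(g[i]);
      if (d > dv) { dv = d; v = i; }
    }
    if (v < 0) break;
    remove_vertex(g, v);
    ++ub;
  }
  int best = ub;
  mvc_search(adj, n, 0, best);
  return best;
}

static void check_n(int n) {
  if (n > 64) stop("event universes larger than 64 are not supported");
}

static inline int seq_cost(const int* a, const int* b, int n,
                           std::vector<uint64_t>& adj) {
  if (!build_conflicts(a, b, n, adj)) return 0;
  return mvc_size(adj, n);
}

// [[Rcpp::export]]
int cpp_pars_cost(IntegerVector a, IntegerVector b) {
  int n = a.size();
  if (b.size() != n) stop("sequences have different lengths");
  check_n(n);
  std::vector<uint64_t> adj(n);
  return seq_cost(&a[0], &b[0], n, adj);
}

// changed event pairs, 1-based two-column matrix (i < j)
// [[Rcpp::export]]
IntegerMatrix cpp_changed_pairs(IntegerVector a, IntegerVector b) {
  int n = a.size();
  if (b.size() != n) stop("sequences have different lengths");
  check_n(n);
  std::vector<uint64_t> adj(n);
  build_conflicts(&a[0], &b[0], n, adj);
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    uint64_t nb = adj[i] >> (i + 1) << (i + 1);
    while (nb) {
      int j = lowbit(nb);
      nb &= nb - 1;
      ii.push_back(i + 1);
      jj.push_back(j + 1);
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}

// fitness of each candidate row against every neighbour row (sum of costs)
// [[Rcpp::export]]
IntegerVector cpp_fitness(IntegerMatrix pop, IntegerMatrix neigh) {
  int n = pop.ncol();
  if (neigh.ncol() != n) stop("sequence lengths differ");
  check_n(n);
  int np = pop.nrow(), nn = neigh.nrow();
  IntegerVector out(np);
  std::vector<int> cand(n), nb(n);
  std::vector<uint64_t> adj(n);
  for (int p = 0; p < np; ++p) {
    int tot = 0;
    for (int k = 0; k < n; ++k) cand[k] = pop(p, k);
    for (int q = 0; q < nn; ++q) {
      for (int k = 0; k < n; ++k) nb[k] = neigh(q, k);
      tot += seq_cost(&cand[0], &nb[0], n, adj);
    }
    out[p] = tot;
  }
  return out;
}

// cost matrix between rows of A and rows of B
// [[Rcpp::export]]
IntegerMatrix cpp_cost_matrix(IntegerMatrix A, IntegerMatrix B) {
  int n = A.ncol();
  if (B.ncol() != n) stop("sequence lengths differ");
  check_n(n);
  int na = A.nrow(), nbr = B.nrow();
  IntegerMatrix out(na, nbr);
  std::vector<int> ra(n), rb(n);
  std::vector<uint64_t> adj(n);
  for (int i = 0; i < na; ++i) {
    for (int k = 0; k < n; ++k) ra[k] = A(i, k);
    for (int j = 0; j < nbr; ++j) {
      for (int k = 0; k < n; ++k) rb[k] = B(j, k);
      out(i, j) = seq_cost(&ra[0], &rb[0], n, adj);
    }
  }
  return out;
}

// enumerate all vertex covers of minimum size k, capped; each exactly once
static void enum_covers(const std::vector<uint64_t>& adj, int n,
                        uint64_t included, uint64_t excluded, int k,
                        std::vector<uint64_t>& out, int cap) {
  if ((int)out.size() >= cap) return;
  int u = -1;
  for (int i = 0; i < n; ++i) {
    if (adj[i]) { u = i; break; }
  }
  if (u < 0) {
    out.push_back(included);
    return;
  }
  int used = popcnt(included);
  if (used >= k) return;
  if (!((excluded >> u) & 1ULL)) {
    std::vector<uint64_t> adj2(adj);
    remove_vertex(adj2, u);
    enum_covers(adj2, n, included | (1ULL << u), excluded, k, out, cap);
  }
  {
    uint64_t nb = adj[u];
    if (!(nb & excluded) && used + popcnt(nb) <= k) {
      std::vector<uint64_t> adj2(adj);
      uint64_t rest = nb;
      while (rest) {
        int w = lowbit(rest);
        rest &= rest - 1;
        remove_vertex(adj2, w);
      }
      enum_covers(adj2, n, included | nb, excluded | (1ULL << u), k, out, cap);
    }
  }
}

// all minimum vertex covers of the conflict graph, as 1-based event indices
// [[Rcpp::export]]
List cpp_min_covers(IntegerVector a, IntegerVector b, int cap) {
  int n = a.size();
  if (b.size() != n) stop("sequences have different lengths");
  check_n(n);
  if (cap < 1) stop("cap must be >= 1");
  std::vector<uint64_t> adj(n);
  if (!build_conflicts(&a[0], &b[0], n, adj)) {
    return List::create(IntegerVector(0));
  }
  int k = mvc_size(adj, n);
  std::vector<uint64_t> covers;
  enum_covers(adj, n, 0ULL, 0ULL, k, covers, cap);
  List out(covers.size());
  for (size_t c = 0; c < covers.size(); ++c) {
    uint64_t m = covers[c];
    IntegerVector v(popcnt(m));
    int p = 0;
    while (m) {
      int i = lowbit(m);
      m &= m - 1;
      v[p++] = i + 1;
    }
    out[c] = v;
  }
  return out;
}

// dense re-ranking of each row, preserving order and ties among present events
// [[Rcpp::export]]
IntegerMatrix cpp_canon_rows(IntegerMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<int> levels;
  for (int r = 0; r < nr; ++r) {
    levels.clear();
    for (int c = 0; c < nc; ++c) {
      int v = x(r, c);
      if (v != NA_INTEGER) levels.push_back(v);
    }
    std::sort(levels.begin(), levels.end());
    levels.erase(std::unique(levels.begin(), levels.end()), levels.end());
    for (int c = 0; c < nc; ++c) {
      int v = x(r, c);
      if (v == NA_INTEGER) {
        out(r, c) = NA_INTEGER;
      } else {
        out(r, c) = (int)(std::lower_bound(levels.begin(), levels.end(), v) -
                          levels.begin()) + 1;
      }
    }
  }
  return out;
}
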