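// Weighted Fitch parsimony engine: scoring, exhaustive enumeration of
// unrooted binary topologies, heuristic search (random addition sequence +
// NNI/SPR/TBR branch swapping + optional ratchet), and SPR graph utilities.
//
// State codes used throughout (per taxon x character):
//   1 = {0}      observed state 0
//   2 = {1}      observed state 1
//   3 = {0,1}    missing ("?" unknown or "-" inapplicable; identical in
//                optimization, distinguished only in storage upstream)

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <map>
#include <random>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Unrooted tree over n taxa. Nodes 0..n-1 are leaves, n..2n-3 internal.
// adj[i] holds up to 3 neighbors, -1 marks an empty slot. During stepwise
// addition only a subset of leaves is placed; next_internal tracks the first
// unused internal id.
// ---------------------------------------------------------------------------
struct UTree {
  int n;                                    // capacity in taxa
  int next_internal;                        // first free internal node id
  std::vector<std::array<int, 3>> adj;
  explicit UTree(int n_) : n(n_), next_internal(n_) {
    adj.assign(2 * n_ - 2, {-1, -1, -1});
  }
};

static inline void add_half(UTree& t, int u, int v) {
  for (int k = 0; k < 3; ++k)
    if (t.adj[u][k] == -1) { t.adj[u][k] = v; return; }
  stop("internal error: node degree overflow");
}
static inline void add_edge(UTree& t, int u, int v) {
  add_half(t, u, v);
  add_half(t, v, u);
}
static inline void rm_half(UTree& t, int u, int v) {
  for (int k = 0; k < 3; ++k)
    if (t.adj[u][k] == v) { t.adj[u][k] = -1; return; }
  stop("internal error: missing adjacency");
}
static inline void rm_edge(UTree& t, int u, int v) {
  rm_half(t, u, v);
  rm_half(t, v, u);
}
static inline void repl_half(UTree& t, int u, int oldv, int newv) {
  for (int k = 0; k < 3; ++k)
    if (t.adj[u][k] == oldv) { t.adj[u][k] = newv; return; }
  stop("internal error: missing adjacency (replace)");
}
static inline int degree(const UTree& t, int u) {
  int d = 0;
  for (int k = 0; k < 3; ++k) d += (t.adj[u][k] != -1);
  return d;
}

// Start a tree on three placed taxa.
static UTree start_tree(int n, int a, int b, int c) {
  UTree t(n);
  int x = t.next_internal++;
  add_edge(t, x, a);
  add_edge(t, x, b);
  add_edge(t, x, c);
  return t;
}

// Insert leaf `tax` into edge (u,v); returns the new internal node.
static int insert_leaf(UTree& t, int tax, int u, int v) {
  int w = t.next_internal++;
  rm_edge(t, u, v);
  add_edge(t, u, w);
  add_edge(t, w, v);
  add_edge(t, w, tax);
  return w;
}
static void undo_insert_leaf(UTree& t, int tax, int u, int v, int w) {
  rm_edge(t, u, w);
  rm_edge(t, w, v);
  rm_edge(t, w, tax);
  add_edge(t, u, v);
  t.next_internal--;
}

// All edges (u < v) of the current tree.
static std::vector<std::pair<int, int>> edge_list(const UTree& t) {
  std::vector<std::pair<int, int>> e;
  int m = (int)t.adj.size();
  for (int u = 0; u < m; ++u)
    for (int k = 0; k < 3; ++k) {
      int v = t.adj[u][k];
      if (v > u) e.push_back({u, v});
    }
  return e;
}

// ---------------------------------------------------------------------------
// Scoring. Root on the edge incident to the lowest placed leaf; all internal
// nodes are then strictly binary, so plain Fitch is exact.
// ---------------------------------------------------------------------------
typedef std::vector<std::vector<uint8_t>> StateTable;  // [taxon][char]

struct Scorer {
  const StateTable& st;
  const std::vector<double>& w;
  int C;
  long long evaluations = 0;
  Scorer(const StateTable& st_, const std::vector<double>& w_)
      : st(st_), w(w_), C((int)st_[0].size()) {}

  double score(const UTree& t, int root_leaf) {
    ++evaluations;
    int m = (int)t.adj.size();
    int r = t.adj[root_leaf][0];
    // preorder by DFS; reversed gives a postorder
    std::vector<int> order;
    order.reserve(m);
    std::vector<int> parent(m, -2);
    std::vector<int> stk;
    stk.push_back(r);
    parent[r] = root_leaf;
    while (!stk.empty()) {
      int u = stk.back();
      stk.pop_back();
      order.push_back(u);
      for (int k = 0; k < 3; ++k) {
        int v = t.adj[u][k];
        if (v != -1 && v != parent[u]) {
          parent[v] = u;
          stk.push_back(v);
        }
      }
    }
    std::vector<std::vector<uint8_t>> sets(m);
    double total = 0.0;
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int u = order[i];
      if (u < t.n) { continue; }  // leaf sets read directly from st
      std::vector<uint8_t> cur;
      bool first = true;
      for (int k = 0; k < 3; ++k) {
        int v = t.adj[u][k];
        if (v == -1 || v == parent[u]) continue;
        const std::vector<uint8_t>& sv = (v < t.n) ? st[v] : sets[v];
        if (first) {
          cur = sv;
          first = false;
        } else {
          for (int j = 0; j < C; ++j) {
            uint8_t a = cur[j] & sv[j];
            if (a) cur[j] = a;
            else {
              cur[j] = cur[j] | sv[j];
              total += w[j];
            }
          }
        }
      }
      sets[u] = std::move(cur);
    }
    const std::vector<uint8_t>& rl = st[root_leaf];
    const std::vector<uint8_t>& rs = sets[r];
    for (int j = 0; j < C; ++j)
      if (!(rs[j] & rl[j])) total += w[j];
    return total;
  }
};

// ---------------------------------------------------------------------------
// Canonical Newick (sorted children, taxa as t<i>, rooted on leaf 0's edge).
// Valid Newick, and identical strings iff identical unrooted topologies.
// ---------------------------------------------------------------------------
static std::string canon_rec(const UTree& t, int u, int par) {
  if (u < t.n) return "t" + std::to_string(u);
  std::vector<std::string> parts;
  for (int k = 0; k < 3; ++k) {
    int v = t.adj[u][k];
    if (v != -1 && v != par) parts.push_back(canon_rec(t, v, u));
  }
  std::sort(parts.begin(), parts.end());
  std::string s = "(";
  for (size_t i = 0; i < parts.size(); ++i) {
    if (i) s += ",";
    s += parts[i];
  }
  s += ")";
  return s;
}
static std::string canonical(const UTree& t) {
  int r = t.adj[0][0];
  return "(t0," + canon_rec(t, r, 0) + ");";
}

// ---------------------------------------------------------------------------
// Conversions with R
// ---------------------------------------------------------------------------
static StateTable states_from_R(const IntegerMatrix& S) {
  int n = S.nrow(), C = S.ncol();
  StateTable st(n, std::vector<uint8_t>(C));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < C; ++j) {
      int v = S(i, j);
      if (v < 1 || v > 3) stop("state codes must be 1, 2 or 3");
      st[i][j] = (uint8_t)v;
    }
  return st;
}

// Build an unrooted UTree from an ape edge matrix (tips 1..nTip, internal
// nTip+1..; basal node of degree >= 3 after unrooting). Tree must be binary.
static UTree utree_from_edges(const IntegerMatrix& edge, int nTip) {
  int nnode = 0;
  for (int i = 0; i < edge.nrow(); ++i)
    nnode = std::max(nnode, std::max(edge(i, 0), edge(i, 1)));
  UTree t(nTip);
  if (nnode - nTip != nTip - 2)
    stop("expected an unrooted binary tree with n-2 internal nodes");
  t.next_internal = 2 * nTip - 2;
  for (int i = 0; i < edge.nrow(); ++i) {
    int a = edge(i, 0), b = edge(i, 1);
    int u = (a <= nTip) ? a - 1 : nTip + (a - nTip - 1);
    int v = (b <= nTip) ? b - 1 : nTip + (b - nTip - 1);
    add_edge(t, u, v);
  }
  for (int u = 0; u < nTip; ++u)
    if (degree(t, u) != 1) stop("leaf with degree != 1; tree not binary unrooted");
  for (int u = nTip; u < 2 * nTip - 2; ++u)
    if (degree(t, u) != 3) stop("internal node with degree != 3; tree not binary unrooted");
  return t;
}

// ---------------------------------------------------------------------------
// Neighborhoods
// ---------------------------------------------------------------------------
static void subtree_nodes(const UTree& t, int s, int p, std::vector<char>& in) {
  std::fill(in.begin(), in.end(), 0);
  std::vector<int> stk{s};
  in[s] = 1;
  std::vector<int> par((int)t.adj.size(), -2);
  par[s] = p;
  while (!stk.empty()) {
    int u = stk.back();
    stk.pop_back();
    for (int k = 0; k < 3; ++k) {
      int v = t.adj[u][k];
      if (v != -1 && v != par[u]) {
        par[v] = u;
        in[v] = 1;
        stk.push_back(v);
      }
    }
  }
}

// SPR: prune the subtree on the s-side of edge (s,p) (p must be internal),
// regraft into every edge of the remaining component.
static std::vector<UTree> spr_neighbors(const UTree& t) {
  std::vector<UTree> out;
  auto edges = edge_list(t);
  int m = (int)t.adj.size();
  std::vector<char> in(m, 0);
  for (auto& e : edges) {
    for (int dir = 0; dir < 2; ++dir) {
      int s = dir ? e.second : e.first;
      int p = dir ? e.first : e.second;
      if (p < t.n) continue;  // pruning everything but one leaf: no target edge
      subtree_nodes(t, s, p, in);
      // p's two other neighbors q, r rejoin after the prune
      int q = -1, r = -1;
      for (int k = 0; k < 3; ++k) {
        int v = t.adj[p][k];
        if (v != -1 && v != s) (q == -1 ? q : r) = v;
      }
      for (auto& f : edges) {
        int x = f.first, y = f.second;
        if (in[x] || in[y]) continue;
        if (x == p || y == p) continue;  // edges through p vanish
        // regrafting into (q,r) recreates the original tree
        if ((x == q && y == r) || (x == r && y == q)) continue;
        UTree nt = t;
        rm_half(nt, p, s);  // s still points to p; p regains s below
        rm_edge(nt, p, q);
        rm_edge(nt, p, r);
        add_edge(nt, q, r);
        rm_edge(nt, x, y);
        add_edge(nt, x, p);
        add_edge(nt, p, y);
        add_half(nt, p, s);
        out.push_back(std::move(nt));
      }
    }
  }
  return out;
}

// NNI: swap subtrees across each internal edge (two per edge).
static std::vector<UTree> nni_neighbors(const UTree& t) {
  std::vector<UTree> out;
  auto edges = edge_list(t);
  for (auto& e : edges) {
    int u = e.first, v = e.second;
    if (u < t.n || v < t.n) continue;
    int a = -1, b = -1, c = -1, d = -1;
    for (int k = 0; k < 3; ++k) {
      int x = t.adj[u][k];
      if (x != -1 && x != v) (a == -1 ? a : b) = x;
      int y = t.adj[v][k];
      if (y != -1 && y != u) (c == -1 ? c : d) = y;
    }
    int swaps[2] = {c, d};
    for (int z : swaps) {
      UTree nt = t;
      repl_half(nt, u, b, z);
      repl_half(nt, v, z, b);
      repl_half(nt, b, u, v);
      repl_half(nt, z, v, u);
      out.push_back(std::move(nt));
    }
  }
  return out;
}

// TBR: bisect each edge, suppress the cut endpoints, reconnect every edge
// (or lone leaf) of one component to every edge (or lone leaf) of the other.
static std::vector<UTree> tbr_neighbors(const UTree& t) {
  std::vector<UTree> out;
  auto edges = edge_list(t);
  int m = (int)t.adj.size();
  std::vector<char> inA(m, 0);
  for (auto& e : edges) {
    int u = e.first, v = e.second;
    subtree_nodes(t, u, v, inA);
    UTree base = t;
    rm_edge(base, u, v);
    std::vector<int> freed;
    int au = u, av = v;  // attachment anchors if a side is a lone leaf
    if (u >= t.n) {      // suppress u
      int q = -1, r = -1;
      for (int k = 0; k < 3; ++k) {
        int x = base.adj[u][k];
        if (x != -1) (q == -1 ? q : r) = x;
      }
      rm_edge(base, u, q);
      rm_edge(base, u, r);
      add_edge(base, q, r);
      freed.push_back(u);
      au = -1;
    }
    if (v >= t.n) {
      int q = -1, r = -1;
      for (int k = 0; k < 3; ++k) {
        int x = base.adj[v][k];
        if (x != -1) (q == -1 ? q : r) = x;
      }
      rm_edge(base, v, q);
      rm_edge(base, v, r);
      add_edge(base, q, r);
      freed.push_back(v);
      av = -1;
    }
    // collect edges of each component in `base`
    std::vector<std::pair<int, int>> eA, eB;
    for (int x = 0; x < m; ++x)
      for (int k = 0; k < 3; ++k) {
        int y = base.adj[x][k];
        if (y > x) {
          if (inA[x]) eA.push_back({x, y});
          else eB.push_back({x, y});
        }
      }
    // enumerate attachment pairs
    size_t nA = (au != -1) ? 1 : eA.size();
    size_t nB = (av != -1) ? 1 : eB.size();
    for (size_t ia = 0; ia < nA; ++ia)
      for (size_t ib = 0; ib < nB; ++ib) {
        UTree nt = base;
        size_t fi = 0;
        int endA, endB;
        if (au != -1) endA = au;
        else {
          int w = freed[fi++];
          int x = eA[ia].first, y = eA[ia].second;
          rm_edge(nt, x, y);
          add_edge(nt, x, w);
          add_edge(nt, w, y);
          endA = w;
        }
        if (av != -1) endB = av;
        else {
          int w = freed[fi++];
          int x = eB[ib].first, y = eB[ib].second;
          rm_edge(nt, x, y);
          add_edge(nt, x, w);
          add_edge(nt, w, y);
          endB = w;
        }
        add_edge(nt, endA, endB);
        out.push_back(std::move(nt));
      }
  }
  return out;
}

static std::vector<UTree> neighbors_of(const UTree& t, int swap) {
  if (swap == 0) return nni_neighbors(t);
  if (swap == 1) return spr_neighbors(t);
  return tbr_neighbors(t);
}

// ---------------------------------------------------------------------------
// Exhaustive search
// ---------------------------------------------------------------------------
struct ExhaustState {
  Scorer* sc;
  int n;
  double best;
  std::set<std::string> best_trees;
  long long count = 0;
};

static void exhaust_rec(UTree& t, int next_tax, ExhaustState& es) {
  if (next_tax == es.n) {
    ++es.count;
    double s = es.sc->score(t, 0);
    if (s < es.best - 1e-9) {
      es.best = s;
      es.best_trees.clear();
      es.best_trees.insert(canonical(t));
    } else if (s < es.best + 1e-9) {
      es.best_trees.insert(canonical(t));
    }
    return;
  }
  auto edges = edge_list(t);
  for (auto& e : edges) {
    int w = insert_leaf(t, next_tax, e.first, e.second);
    exhaust_rec(t, next_tax + 1, es);
    undo_insert_leaf(t, next_tax, e.first, e.second, w);
  }
}

// [[Rcpp::export]]
List exhaustive_search_cpp(IntegerMatrix S, NumericVector w) {
  int n = S.nrow();
  if (n < 4) stop("need at least 4 taxa");
  StateTable st = states_from_R(S);
  std::vector<double> wt(w.begin(), w.end());
  Scorer sc(st, wt);
  UTree t = start_tree(n, 0, 1, 2);
  ExhaustState es;
  es.sc = &sc;
  es.n = n;
  es.best = R_PosInf;
  exhaust_rec(t, 3, es);
  CharacterVector trees(es.best_trees.size());
  int i = 0;
  for (auto& s : es.best_trees) trees[i++] = s;
  return List::create(_["best_score"] = es.best, _["trees"] = trees,
                      _["n_topologies"] = (double)es.count,
                      _["evaluations"] = (double)sc.evaluations);
}

// ---------------------------------------------------------------------------
// Heuristic search
// ---------------------------------------------------------------------------
static UTree stepwise_addition(const StateTable& st, Scorer& sc,
                               const std::vector<int>& order, std::mt19937& rng) {
  int n = (int)st.size();
  UTree t = start_tree(n, order[0], order[1], order[2]);
  int root_leaf = std::min(order[0], std::min(order[1], order[2]));
  for (int i = 3; i < n; ++i) {
    int tax = order[i];
    auto edges = edge_list(t);
    double best = R_PosInf;
    std::vector<int> argbest;
    for (int ei = 0; ei < (int)edges.size(); ++ei) {
      int wnode = insert_leaf(t, tax, edges[ei].first, edges[ei].second);
      double s = sc.score(t, root_leaf);
      undo_insert_leaf(t, tax, edges[ei].first, edges[ei].second, wnode);
      if (s < best - 1e-9) {
        best = s;
        argbest.clear();
        argbest.push_back(ei);
      } else if (s < best + 1e-9) {
        argbest.push_back(ei);
      }
    }
    std::uniform_int_distribution<int> pick(0, (int)argbest.size() - 1);
    int ei = argbest[pick(rng)];
    insert_leaf(t, tax, edges[ei].first, edges[ei].second);
    root_leaf = std::min(root_leaf, tax);
  }
  return t;
}

// Hill-climb with best-improvement sweeps under weights in sc.
static double swap_to_optimum(UTree& t, Scorer& sc, int swap, std::mt19937& rng) {
  double cur = sc.score(t, 0);
  for (;;) {
    auto nb = neighbors_of(t, swap);
    double best = cur;
    std::vector<int> argbest;
    for (int i = 0; i < (int)nb.size(); ++i) {
      double s = sc.score(nb[i], 0);
      if (s < best - 1e-9) {
        best = s;
        argbest.clear();
        argbest.push_back(i);
      } else if (s < best + 1e-9 && best < cur - 1e-9) {
        argbest.push_back(i);
      }
    }
    if (best >= cur - 1e-9) return cur;
    std::uniform_int_distribution<int> pick(0, (int)argbest.size() - 1);
    t = nb[argbest[pick(rng)]];
    cur = best;
  }
}

// [[Rcpp::export]]
List heuristic_search_cpp(IntegerMatrix S, NumericVector w, int nrep, int swap,
                          int ratchet, int seed, int maxtrees) {
  int n = S.nrow();
  if (n < 4) stop("need at least 4 taxa");
  StateTable st = states_from_R(S);
  std::vector<double> wt(w.begin(), w.end());
  Scorer sc(st, wt);
  std::mt19937 rng((uint32_t)seed);

  double global_best = R_PosInf;
  std::map<std::string, UTree> pool;  // canonical -> tree, all at global_best

  auto consider = [&](const UTree& t, double s) {
    if (s < global_best - 1e-9) {
      global_best = s;
      pool.clear();
    }
    if (s < global_best + 1e-9 && (int)pool.size() < maxtrees)
      pool.emplace(canonical(t), t);
  };

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int rep = 0; rep < nrep; ++rep) {
    std::shuffle(order.begin(), order.end(), rng);
    UTree t = stepwise_addition(st, sc, order, rng);
    double s = swap_to_optimum(t, sc, swap, rng);
    consider(t, s);
    for (int it = 0; it < ratchet; ++it) {
      // perturb: quadruple the weight of ~25% of the characters
      std::vector<double> wp = wt;
      std::uniform_real_distribution<double> u01(0.0, 1.0);
      for (size_t j = 0; j < wp.size(); ++j)
        if (u01(rng) < 0.25) wp[j] *= 4.0;
      Scorer scp(st, wp);
      UTree tp = t;
      swap_to_optimum(tp, scp, swap, rng);
      double sp = swap_to_optimum(tp, sc, swap, rng);
      sc.evaluations += scp.evaluations;
      if (sp < s + 1e-9) {
        t = tp;
        s = sp;
        consider(t, s);
      }
    }
  }

  // plateau expansion: collect equal-score neighbors of the MP trees so the
  // returned set reflects alternative equally parsimonious arrangements
  bool truncated = false;
  std::vector<UTree> frontier;
  for (auto& kv : pool) frontier.push_back(kv.second);
  while (!frontier.empty() && (int)pool.size() < maxtrees) {
    std::vector<UTree> next;
    for (auto& t : frontier) {
      if ((int)pool.size() >= maxtrees) { truncated = true; break; }
      auto nb = neighbors_of(t, swap);
      for (auto& x : nb) {
        if ((int)pool.size() >= maxtrees) { truncated = true; break; }
        double s = sc.score(x, 0);
        if (s < global_best - 1e-9) {
          // a neighbor beats the pool: restart pooling from it
          global_best = s;
          pool.clear();
          pool.emplace(canonical(x), x);
          next.clear();
          next.push_back(x);
        } else if (s < global_best + 1e-9) {
          std::string c = canonical(x);
          if (!pool.count(c)) {
            pool.emplace(c, x);
            next.push_back(x);
          }
        }
      }
    }
    frontier = std::move(next);
  }
  if ((int)pool.size() >= maxtrees) truncated = true;

  CharacterVector trees(pool.size());
  int i = 0;
  for (auto& kv : pool) trees[i++] = kv.first;
  return List::create(_["best_score"] = global_best, _["trees"] = trees,
                      _["evaluations"] = (double)sc.evaluations,
                      _["truncated"] = truncated);
}

// ---------------------------------------------------------------------------
// Fitch/Sankoff scoring of an arbitrary (possibly multifurcating) tree given
// as an ape edge matrix in postorder. Exact for hard polytomies via DP.
// Returns per-character minimal step counts (unweighted).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector sankoff_steps_cpp(IntegerMatrix edge, int nTip, IntegerMatrix S) {
  int C = S.ncol();
  int maxnode = 0;
  for (int i = 0; i < edge.nrow(); ++i)
    maxnode = std::max(maxnode, std::max(edge(i, 0), edge(i, 1)));
  const double BIG = 1e18;
  NumericVector out(C);
  std::vector<double> c0(maxnode + 1), c1(maxnode + 1);
  for (int j = 0; j < C; ++j) {
    for (int v = 0; v <= maxnode; ++v) { c0[v] = 0.0; c1[v] = 0.0; }
    for (int v = 1; v <= nTip; ++v) {
      int code = S(v - 1, j);
      c0[v] = (code & 1) ? 0.0 : BIG;
      c1[v] = (code & 2) ? 0.0 : BIG;
    }
    for (int i = 0; i < edge.nrow(); ++i) {
      int p = edge(i, 0), ch = edge(i, 1);
      c0[p] += std::min(c0[ch], c1[ch] + 1.0);
      c1[p] += std::min(c1[ch], c0[ch] + 1.0);
    }
    int root = edge(edge.nrow() - 1, 0);
    double s = std::min(c0[root], c1[root]);
    out[j] = (s >= BIG / 2) ? NA_REAL : s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// SPR graph utilities on unrooted binary trees (ape edge matrix input).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
CharacterVector spr_neighbors_cpp(IntegerMatrix edge, int nTip) {
  UTree t = utree_from_edges(edge, nTip);
  auto nb = spr_neighbors(t);
  std::set<std::string> seen;
  for (auto& x : nb) seen.insert(canonical(x));
  seen.erase(canonical(t));
  CharacterVector out(seen.size());
  int i = 0;
  for (auto& s : seen) out[i++] = s;
  return out;
}

// Exact SPR distance by breadth-first search from t1 until t2 is reached.
// Returns -1 if the distance exceeds maxdepth.
// [[Rcpp::export]]
int spr_bfs_cpp(IntegerMatrix edge1, IntegerMatrix edge2, int nTip, int maxdepth) {
  UTree t1 = utree_from_edges(edge1, nTip);
  UTree t2 = utree_from_edges(edge2, nTip);
  std::string target = canonical(t2);
  if (canonical(t1) == target) return 0;
  std::set<std::string> visited{canonical(t1)};
  std::vector<UTree> frontier{t1};
  for (int d = 1; d <= maxdepth; ++d) {
    std::vector<UTree> next;
    for (auto& t : frontier) {
      auto nb = spr_neighbors(t);
      for (auto& x : nb) {
        std::string c = canonical(x);
        if (c == target) return d;
        if (visited.insert(c).second) next.push_back(std::move(x));
      }
    }
    if (next.empty()) break;
    frontier = std::move(next);
  }
  return -1;
}

// Canonical form of an unrooted binary tree (for dedup/isomorphism checks).
// [[Rcpp::export]]
String canonical_cpp(IntegerMatrix edge, int nTip) {
  UTree t = utree_from_edges(edge, nTip);
  return canonical(t);
}
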