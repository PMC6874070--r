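// Core routines on unlabeled rooted bifurcating tree shapes.
//
// A shape is identified by its canonical unlabeled newick string: a leaf is
// the empty string, an internal node is "(A,B)" with children ordered by
// (leaf count, key), smaller first.  Keys exposed to R carry a trailing ';'.

#include <Rcpp.h>
#include <algorithm>
#include <cctype>
#include <cstring>
#include <functional>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- parsing

struct PTree {
  std::vector<int> kid1, kid2, parent, nl;
  int root;
  int nnode() const { return (int)kid1.size(); }
};

static void nwk_error(const char* msg, size_t pos) {
  stop("newick parse error at position %d: %s", (int)pos + 1, msg);
}

// Tolerant newick reader: labels, branch lengths and whitespace are accepted
// and discarded; multifurcations are an error (shapes are bifurcating).
static PTree parse_newick(const std::string& s) {
  PTree t;
  size_t pos = 0, n = s.size();
  auto skip_ws = [&]() {
    while (pos < n && std::isspace((unsigned char)s[pos])) ++pos;
  };
  auto skip_label = [&]() {  // label and/or :length up to a delimiter
    while (pos < n) {
      char c = s[pos];
      if (c == '(') nwk_error("unexpected '('", pos);
      if (c == ',' || c == ')' || c == ';') break;
      ++pos;
    }
  };
  std::function<int()> node = [&]() -> int {
    skip_ws();
    int id = t.nnode();
    t.kid1.push_back(-1);
    t.kid2.push_back(-1);
    t.parent.push_back(-1);
    t.nl.push_back(0);
    if (pos < n && s[pos] == '(') {
      ++pos;
      int a = node();
      skip_ws();
      if (pos >= n || s[pos] != ',')
        nwk_error("expected ',' (unbranched internal node?)", pos);
      ++pos;
      int b = node();
      skip_ws();
      if (pos < n && s[pos] == ',')
        nwk_error("multifurcating node: shapes must be strictly bifurcating",
                    pos);
      if (pos >= n || s[pos] != ')') nwk_error("expected ')'", pos);
      ++pos;
      skip_label();
      t.kid1[id] = a;
      t.kid2[id] = b;
      t.parent[a] = id;
      t.parent[b] = id;
      t.nl[id] = t.nl[a] + t.nl[b];
    } else {
      skip_label();
      t.nl[id] = 1;
    }
    return id;
  };
  t.root = node();
  skip_ws();
  if (pos < n && s[pos] == ';') ++pos;
  skip_ws();
  if (pos != n) nwk_error("trailing characters after tree", pos);
  return t;
}

// ------------------------------------------------------- canonical strings

static std::string canon_pair(const std::string& a, int na,
                              const std::string& b, int nb) {
  if (na < nb || (na == nb && a <= b)) return "(" + a + "," + b + ")";
  return "(" + b + "," + a + ")";
}

// canonical key of every subtree (leaf -> "")
static std::vector<std::string> subtree_keys(const PTree& t) {
  std::vector<std::string> key(t.nnode());
  std::function<void(int)> rec = [&](int v) {
    if (t.kid1[v] < 0) return;  // leaf: ""
    rec(t.kid1[v]);
    rec(t.kid2[v]);
    key[v] = canon_pair(key[t.kid1[v]], t.nl[t.kid1[v]], key[t.kid2[v]],
                        t.nl[t.kid2[v]]);
  };
  rec(t.root);
  return key;
}

// [[Rcpp::export]]
std::string cpp_canonical_newick(std::string text) {
  PTree t = parse_newick(text);
  return subtree_keys(t)[t.root] + ";";
}

// [[Rcpp::export]]
int cpp_leaf_count(std::string text) {
  PTree t = parse_newick(text);
  return t.nl[t.root];
}

// ------------------------------------------------------------ enumeration

// All canonical shapes on l leaves, byte-sorted.  Recursive product over
// root splits {k, l-k}; each unordered pair of subshapes arises exactly once.
// [[Rcpp::export]]
CharacterVector cpp_enumerate_shapes(int l) {
  if (l < 1) stop("leaf count must be a positive integer");
  std::vector<std::vector<std::string>> lev(l + 1);
  lev[1].push_back("");
  for (int m = 2; m <= l; ++m) {
    for (int k = 1; k <= m / 2; ++k) {
      const std::vector<std::string>& A = lev[k];
      const std::vector<std::string>& B = lev[m - k];
      if (k < m - k) {
        for (size_t i = 0; i < A.size(); ++i)
          for (size_t j = 0; j < B.size(); ++j)
            lev[m].push_back("(" + A[i] + "," + B[j] + ")");
      } else {  // equal split: unordered pairs, lexicographically smaller first
        for (size_t i = 0; i < A.size(); ++i)
          for (size_t j = i; j < B.size(); ++j)
            lev[m].push_back("(" + std::min(A[i], B[j]) + "," +
                             std::max(A[i], B[j]) + ")");
      }
    }
  }
  std::sort(lev[l].begin(), lev[l].end());
  CharacterVector out(lev[l].size());
  for (size_t i = 0; i < lev[l].size(); ++i) out[i] = lev[l][i] + ";";
  return out;
}

// ------------------------------------------------------------- statistics

// Raw per-shape aggregates; normalizations are applied on the R side.
// Columns: leaves, sum|r-s|, sum depth, sum depth^2, I2 sum, B1 (root
// excluded), B2, cherries.
// [[Rcpp::export]]
NumericMatrix cpp_shape_stats(CharacterVector keys) {
  int n = keys.size();
  NumericMatrix out(n, 8);
  colnames(out) = CharacterVector::create("leaves", "sum_imb", "sum_depth",
                                          "sum_depth2", "i2_sum", "b1", "b2",
                                          "cherries");
  for (int i = 0; i < n; ++i) {
    PTree t = parse_newick(std::string(keys[i]));
    int nn = t.nnode();
    std::vector<int> depth(nn, 0), height(nn, 0);
    // depths by preorder (parents precede children in creation order)
    for (int v = 0; v < nn; ++v)
      if (t.parent[v] >= 0) depth[v] = depth[t.parent[v]] + 1;
    // heights by reverse creation order (children created after parents)
    for (int v = nn - 1; v >= 0; --v)
      if (t.kid1[v] >= 0)
        height[v] = 1 + std::max(height[t.kid1[v]], height[t.kid2[v]]);
    double sum_imb = 0, sum_d = 0, sum_d2 = 0, i2 = 0, b1 = 0, b2 = 0;
    double cherries = 0;
    for (int v = 0; v < nn; ++v) {
      if (t.kid1[v] < 0) {  // leaf
        sum_d += depth[v];
        sum_d2 += (double)depth[v] * depth[v];
        b2 += depth[v] / std::pow(2.0, depth[v]);
      } else {
        int r = t.nl[t.kid1[v]], s = t.nl[t.kid2[v]];
        sum_imb += std::abs(r - s);
        if (r + s > 2) i2 += std::abs(r - s) / (double)(r + s - 2);
        if (t.parent[v] >= 0) b1 += 1.0 / height[v];
        if (r == 1 && s == 1) cherries += 1;
      }
    }
    out(i, 0) = t.nl[t.root];
    out(i, 1) = sum_imb;
    out(i, 2) = sum_d;
    out(i, 3) = sum_d2;
    out(i, 4) = i2;
    out(i, 5) = b1;
    out(i, 6) = b2;
    out(i, 7) = cherries;
  }
  return out;
}

// ------------------------------------------------------------- NNI moves

// Canonical keys (without ';') of all shapes one rooted NNI move away.
// For each internal edge (u = parent, v = internal child) with w the sibling
// of v and {a, b} the children of v, the two alternative configurations put
// w next to b (keeping a up) or next to a (keeping b up).
static std::vector<std::string> neighbor_keys(const PTree& t,
                                              const std::vector<std::string>& key) {
  std::vector<std::string> out;
  for (int v = 0; v < t.nnode(); ++v) {
    if (t.kid1[v] < 0) continue;  // leaf
    int u = t.parent[v];
    if (u < 0) continue;  // no edge above the root
    int w = (t.kid1[u] == v) ? t.kid2[u] : t.kid1[u];
    int a = t.kid1[v], b = t.kid2[v];
    for (int cfg = 0; cfg < 2; ++cfg) {
      int keep = cfg == 0 ? a : b;
      int go = cfg == 0 ? b : a;
      std::string inner = canon_pair(key[w], t.nl[w], key[go], t.nl[go]);
      std::string s =
          canon_pair(key[keep], t.nl[keep], inner, t.nl[w] + t.nl[go]);
      int cur = u, snl = t.nl[u];
      while (t.parent[cur] >= 0) {  // rebuild the spine up to the root
        int p = t.parent[cur];
        int sib = (t.kid1[p] == cur) ? t.kid2[p] : t.kid1[p];
        s = canon_pair(s, snl, key[sib], t.nl[sib]);
        snl += t.nl[sib];
        cur = p;
      }
      out.push_back(s);
    }
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_nni_neighbors(std::string text) {
  PTree t = parse_newick(text);
  std::vector<std::string> key = subtree_keys(t);
  std::vector<std::string> nb = neighbor_keys(t, key);
  std::string self = key[t.root];
  CharacterVector out;
  for (size_t i = 0; i < nb.size(); ++i)
    if (nb[i] != self) out.push_back(nb[i] + ";");
  return out;
}

// Edge list {i < j} (1-based into `keys`, which must be the full sorted
// shape space) of the NNI Cayley graph.
// [[Rcpp::export]]
IntegerMatrix cpp_cayley_edges(CharacterVector keys) {
  int n = keys.size();
  std::unordered_map<std::string, int> index;
  index.reserve(n * 2);
  std::vector<std::string> kv(n);
  for (int i = 0; i < n; ++i) {
    kv[i] = std::string(keys[i]);
    index[kv[i]] = i;
  }
  std::vector<std::pair<int, int>> edges;
  for (int i = 0; i < n; ++i) {
    PTree t = parse_newick(kv[i]);
    std::vector<std::string> key = subtree_keys(t);
    std::vector<std::string> nb = neighbor_keys(t, key);
    const std::string& self = key[t.root];
    for (size_t k = 0; k < nb.size(); ++k) {
      if (nb[k] == self) continue;
      std::unordered_map<std::string, int>::iterator it =
          index.find(nb[k] + ";");
      if (it == index.end())
        stop("internal consistency error: NNI neighbor of shape %d is not in "
             "the enumerated space (enumeration/move mismatch)", i + 1);
      int j = it->second;
      edges.push_back(std::make_pair(std::min(i, j), std::max(i, j)));
    }
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  std::sort(edges.begin(), edges.end());
  edges.erase(std::unique(edges.begin(), edges.end()), edges.end());
  IntegerMatrix out(edges.size(), 2);
  for (size_t e = 0; e < edges.size(); ++e) {
    out(e, 0) = edges[e].first + 1;
    out(e, 1) = edges[e].second + 1;
  }
  return out;
}

// ----------------------------------------------------------------- BFS

struct CSR {
  std::vector<int> off, adj;
};

static CSR build_csr(int n, const IntegerMatrix& edges) {
  CSR g;
  int m = edges.nrow();
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    ++deg[edges(e, 0) - 1];
    ++deg[edges(e, 1) - 1];
  }
  g.off.assign(n + 1, 0);
  for (int v = 0; v < n; ++v) g.off[v + 1] = g.off[v] + deg[v];
  g.adj.assign(2 * (size_t)m, 0);
  std::vector<int> cur(g.off.begin(), g.off.end() - 1);
  for (int e = 0; e < m; ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    g.adj[cur[i]++] = j;
    g.adj[cur[j]++] = i;
  }
  return g;
}

static void bfs_from(const CSR& g, int n, int src, std::vector<int>& dist,
                     std::vector<int>& queue) {
  std::fill(dist.begin(), dist.end(), -1);
  int head = 0, tail = 0;
  dist[src] = 0;
  queue[tail++] = src;
  while (head < tail) {
    int v = queue[head++];
    int dv = dist[v] + 1;
    for (int k = g.off[v]; k < g.off[v + 1]; ++k) {
      int w = g.adj[k];
      if (dist[w] < 0) {
        dist[w] = dv;
        queue[tail++] = w;
      }
    }
  }
}

// All-pairs shortest-path matrix (unweighted).  Unreachable pairs are NA.
// [[Rcpp::export]]
IntegerMatrix cpp_bfs_distances(int n, IntegerMatrix edges) {
  CSR g = build_csr(n, edges);
  IntegerMatrix D(n, n);
  std::vector<int> dist(n), queue(n);
  for (int s = 0; s < n; ++s) {
    bfs_from(g, n, s, dist, queue);
    for (int v = 0; v < n; ++v)
      D(v, s) = dist[v] < 0 ? NA_INTEGER : dist[v];
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return D;
}

// Y' Ds Y for Ds the elementwise-squared distance matrix, streamed one BFS
// row at a time so Ds is never materialized (the memory bottleneck at large
// leaf counts).
// [[Rcpp::export]]
NumericMatrix cpp_ds_crossprod(int n, IntegerMatrix edges, NumericMatrix Y) {
  if (Y.nrow() != n) stop("nrow(Y) must equal the number of shapes");
  int k = Y.ncol();
  CSR g = build_csr(n, edges);
  std::vector<int> dist(n), queue(n);
  std::vector<double> w(k);
  // row-major copy of Y so the k values of one shape are contiguous
  std::vector<double> Yt((size_t)n * k);
  for (int c = 0; c < k; ++c)
    for (int v = 0; v < n; ++v) Yt[(size_t)v * k + c] = Y(v, c);
  NumericMatrix M(k, k);
  for (int s = 0; s < n; ++s) {
    bfs_from(g, n, s, dist, queue);
    std::fill(w.begin(), w.end(), 0.0);
    // single streaming pass: w[c] = sum_v d(s,v)^2 * Y[v, c]
    for (int v = 0; v < n; ++v) {
      if (dist[v] < 0)
        stop("graph is disconnected: no path between shapes %d and %d", s + 1,
             v + 1);
      double dd = (double)dist[v] * dist[v];
      const double* yv = &Yt[(size_t)v * k];
      for (int c = 0; c < k; ++c) w[c] += dd * yv[c];
    }
    const double* ys = &Yt[(size_t)s * k];
    for (int c = 0; c < k; ++c)
      for (int d = 0; d < k; ++d) M(c, d) += ys[c] * w[d];
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  // enforce exact symmetry
  for (int c = 0; c < k; ++c)
    for (int d = c + 1; d < k; ++d) {
      double m = (M(c, d) + M(d, c)) / 2.0;
      M(c, d) = m;
      M(d, c) = m;
    }
  return M;
}

// --------------------------------------------------------- random shapes

static std::string key_from_arrays(const std::vector<int>& kid1,
                                   const std::vector<int>& kid2,
                                   const std::vector<int>& nl, int root) {
  std::function<std::string(int)> rec = [&](int v) -> std::string {
    if (kid1[v] < 0) return std::string("");
    return canon_pair(rec(kid1[v]), nl[kid1[v]], rec(kid2[v]), nl[kid2[v]]);
  };
  return rec(root) + ";";
}

static void fill_nl(std::vector<int>& nl, const std::vector<int>& kid1,
                    const std::vector<int>& kid2, int root) {
  std::function<int(int)> rec = [&](int v) -> int {
    if (kid1[v] < 0) return nl[v] = 1;
    return nl[v] = rec(kid1[v]) + rec(kid2[v]);
  };
  rec(root);
}

// Yule: split a uniformly chosen extant lineage until l tips.
static std::string random_yule(int l) {
  std::vector<int> kid1(1, -1), kid2(1, -1);
  std::vector<int> tips(1, 0);
  while ((int)tips.size() < l) {
    int pick = (int)(unif_rand() * tips.size());
    if (pick >= (int)tips.size()) pick = tips.size() - 1;
    int v = tips[pick];
    int a = kid1.size();
    kid1.push_back(-1); kid2.push_back(-1);
    kid1.push_back(-1); kid2.push_back(-1);
    kid1[v] = a; kid2[v] = a + 1;
    tips[pick] = a;
    tips.push_back(a + 1);
  }
  std::vector<int> nl(kid1.size(), 0);
  fill_nl(nl, kid1, kid2, 0);
  return key_from_arrays(kid1, kid2, nl, 0);
}

// PDA: sequential uniform insertion over the 2k-1 attachment positions (all
// 2k-2 edges plus the position above the root), which makes every labeled
// rooted topology equally likely; labels are then dropped.
static std::string random_pda(int l) {
  std::vector<int> kid1, kid2, parent;
  int root = 0;
  kid1.push_back(-1); kid2.push_back(-1); parent.push_back(-1);
  std::vector<int> nonroot;  // nodes below an edge
  for (int k = 1; k < l; ++k) {
    int npos = (int)nonroot.size() + 1;  // == 2k-1
    int pick = (int)(unif_rand() * npos);
    if (pick >= npos) pick = npos - 1;
    int m = kid1.size();  // new internal node
    kid1.push_back(-1); kid2.push_back(-1); parent.push_back(-1);
    int tnew = kid1.size();  // new tip
    kid1.push_back(-1); kid2.push_back(-1); parent.push_back(m);
    if (pick == npos - 1) {  // above the root
      kid1[m] = root; kid2[m] = tnew;
      parent[root] = m;
      nonroot.push_back(root);
      root = m;
    } else {
      int c = nonroot[pick];
      int p = parent[c];
      if (kid1[p] == c) kid1[p] = m; else kid2[p] = m;
      parent[m] = p;
      kid1[m] = c; kid2[m] = tnew;
      parent[c] = m;
      nonroot.push_back(m);
    }
    nonroot.push_back(tnew);
  }
  std::vector<int> nl(kid1.size(), 0);
  fill_nl(nl, kid1, kid2, root);
  return key_from_arrays(kid1, kid2, nl, root);
}

// [[Rcpp::export]]
CharacterVector cpp_random_shapes(int l, std::string model, int n) {
  if (l < 1) stop("leaf count must be a positive integer");
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (l == 1) { out[i] = ";"; continue; }
    if (model == "yule")
      out[i] = random_yule(l);
    else if (model == "pda")
      out[i] = random_pda(l);
    else
      stop("unknown model '%s' (use \"yule\" or \"pda\")", model.c_str());
  }
  return out;
}
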