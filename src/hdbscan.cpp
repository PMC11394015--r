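#include <Rcpp.h>
#include <functional>
#include <vector>
#include <stack>
#include <algorithm>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Minimum spanning tree of the complete mutual-reachability graph
// d_mreach(a, b) = max(core[a], core[b], d(a, b)), by Prim's algorithm.
// O(n^2) time, O(n) memory; distances computed on the fly. Deterministic:
// ties resolved toward the smaller vertex index.
// [[Rcpp::export]]
List prim_mutual_reachability_mst(NumericVector x, NumericVector y,
                                  NumericVector core) {
  const int n = x.size();
  if (n < 2) stop("need at least 2 points for an MST");
  std::vector<bool> in_tree(n, false);
  std::vector<double> best(n, std::numeric_limits<double>::infinity());
  std::vector<int> best_from(n, -1);

  IntegerVector efrom(n - 1), eto(n - 1);
  NumericVector ew(n - 1);

  int current = 0;
  in_tree[0] = true;
  for (int it = 0; it < n - 1; ++it) {
    const double cx = x[current], cy = y[current], ccore = core[current];
    for (int j = 0; j < n; ++j) {
      if (in_tree[j]) continue;
      const double dx = cx - x[j], dy = cy - y[j];
      double w = std::sqrt(dx * dx + dy * dy);
      if (ccore > w) w = ccore;
      if (core[j] > w) w = core[j];
      if (w < best[j]) { best[j] = w; best_from[j] = current; }
    }
    int next = -1;
    double next_w = std::numeric_limits<double>::infinity();
    for (int j = 0; j < n; ++j) {
      if (!in_tree[j] && best[j] < next_w) { next_w = best[j]; next = j; }
    }
    efrom[it] = best_from[next];
    eto[it] = next;
    ew[it] = next_w;
    in_tree[next] = true;
    current = next;
  }
  return List::create(_["from"] = efrom, _["to"] = eto, _["weight"] = ew);
}

namespace {

struct CondensedCluster {
  int parent;              // parent cluster id, -1 for root
  double birth_lambda;
  double stability;
  std::vector<int> children;       // child cluster ids
  std::vector<int> fallout_points; // points leaving this cluster directly
};

// collect leaf point ids under single-linkage node `node`
void collect_leaves(int node, int n, const std::vector<int>& left,
                    const std::vector<int>& right, std::vector<int>& out) {
  std::stack<int> st;
  st.push(node);
  while (!st.empty()) {
    int v = st.top(); st.pop();
    if (v < n) { out.push_back(v); continue; }
    st.push(left[v - n]);
    st.push(right[v - n]);
  }
}

inline double to_lambda(double d) {
  if (d <= 0) return 1e12;  // duplicate points: effectively infinite density
  double l = 1.0 / d;
  return l > 1e12 ? 1e12 : l;
}

}  // namespace

// HDBSCAN cluster extraction from a mutual-reachability MST: single-linkage
// hierarchy -> condensed tree at min_cluster_size -> excess-of-mass cluster
// selection (the root is never selectable, i.e. allow_single_cluster = FALSE).
// Returns 1-based cluster labels, NA for noise.
// [[Rcpp::export]]
IntegerVector hdbscan_labels_from_mst(IntegerVector efrom, IntegerVector eto,
                                      NumericVector ew, int n,
                                      int min_cluster_size) {
  const int m = efrom.size();
  if (m != n - 1) stop("MST must have n - 1 edges");
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2");

  // sort edges ascending by weight (stable: insertion order breaks ties)
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return ew[a] < ew[b]; });

  // single-linkage hierarchy: internal nodes n .. 2n-2
  std::vector<int> left(n - 1), right(n - 1), size(n - 1);
  std::vector<double> dist(n - 1);
  std::vector<int> uf_parent(2 * n - 1);          // union-find -> current root node
  for (int i = 0; i < 2 * n - 1; ++i) uf_parent[i] = i;
  std::function<int(int)> find = [&](int v) {
    while (uf_parent[v] != v) { uf_parent[v] = uf_parent[uf_parent[v]]; v = uf_parent[v]; }
    return v;
  };
  for (int i = 0; i < m; ++i) {
    int e = ord[i];
    int ra = find(efrom[e]), rb = find(eto[e]);
    int node = n + i;
    left[i] = ra; right[i] = rb; dist[i] = ew[e];
    size[i] = (ra < n ? 1 : size[ra - n]) + (rb < n ? 1 : size[rb - n]);
    uf_parent[ra] = node; uf_parent[rb] = node;
  }

  // condense the hierarchy
  std::vector<CondensedCluster> clusters;
  std::vector<double> fallout_lambda_of;  // parallel to fallout order below
  std::vector<int> point_parent(n, -1);
  std::vector<double> point_lambda(n, 0.0);

  clusters.push_back({-1, 0.0, 0.0, {}, {}});
  const int root_node = 2 * n - 2;

  std::stack<std::pair<int, int>> st;  // (single-linkage node, cluster id)
  st.push({root_node, 0});
  while (!st.empty()) {
    int node = st.top().first;
    int cl = st.top().second;
    st.pop();
    // walk down chains that keep the same cluster identity
    while (true) {
      if (node < n) {
        // a bare leaf as cluster continuation cannot occur (mcs >= 2), but a
        // root that is a leaf can for n == 1; guard anyway
        point_parent[node] = cl;
        point_lambda[node] = 1e12;
        break;
      }
      const int i = node - n;
      const double lambda = to_lambda(dist[i]);
      const int l = left[i], r = right[i];
      const int ls = (l < n) ? 1 : size[l - n];
      const int rs = (r < n) ? 1 : size[r - n];
      const bool lbig = ls >= min_cluster_size, rbig = rs >= min_cluster_size;
      if (lbig && rbig) {
        // true split: two new clusters
        for (int side = 0; side < 2; ++side) {
          int child_node = side == 0 ? l : r;
          int id = (int)clusters.size();
          clusters.push_back({cl, lambda, 0.0, {}, {}});
          clusters[cl].children.push_back(id);
          st.push({child_node, id});
        }
        break;
      } else if (!lbig && !rbig) {
        // cluster dies: every point below falls out here
        std::vector<int> leaves;
        collect_leaves(node, n, left, right, leaves);
        for (int p : leaves) { point_parent[p] = cl; point_lambda[p] = lambda; }
        break;
      } else {
        // shed the small side, continue as the same cluster down the big side
        int small_node = lbig ? r : l;
        std::vector<int> leaves;
        collect_leaves(small_node, n, left, right, leaves);
        for (int p : leaves) { point_parent[p] = cl; point_lambda[p] = lambda; }
        node = lbig ? l : r;
      }
    }
  }

  const int ncl = (int)clusters.size();
  if (ncl == 1) {
    // no split survived min_cluster_size: everything is noise
    IntegerVector lab(n, NA_INTEGER);
    return lab;
  }

  // stability: sum over members of (lambda_leave - lambda_birth); a child
  // cluster contributes (lambda_child_birth - lambda_birth) * child_size
  std::vector<int> cluster_npoints(ncl, 0);
  for (int p = 0; p < n; ++p) cluster_npoints[point_parent[p]]++;
  // child subtree point counts
  std::vector<int> subtree_points(ncl, 0);
  for (int c = ncl - 1; c >= 0; --c) {
    subtree_points[c] += cluster_npoints[c];
    if (clusters[c].parent >= 0) subtree_points[clusters[c].parent] += subtree_points[c];
  }
  for (int p = 0; p < n; ++p) {
    int c = point_parent[p];
    clusters[c].stability += point_lambda[p] - clusters[c].birth_lambda;
  }
  for (int c = 1; c < ncl; ++c) {
    int par = clusters[c].parent;
    clusters[par].stability +=
        (clusters[c].birth_lambda - clusters[par].birth_lambda) * subtree_points[c];
  }

  // excess-of-mass selection, children first (ids increase downward)
  std::vector<bool> selected(ncl, false);
  std::vector<double> sc_stability(ncl);
  for (int c = 0; c < ncl; ++c) sc_stability[c] = clusters[c].stability;
  for (int c = ncl - 1; c >= 1; --c) {
    if (clusters[c].children.empty()) { selected[c] = true; continue; }
    double child_sum = 0.0;
    for (int ch : clusters[c].children) child_sum += sc_stability[ch];
    if (sc_stability[c] >= child_sum) {
      selected[c] = true;
      // deselect all descendants
      std::stack<int> ds;
      for (int ch : clusters[c].children) ds.push(ch);
      while (!ds.empty()) {
        int v = ds.top(); ds.pop();
        selected[v] = false;
        for (int ch : clusters[v].children) ds.push(ch);
      }
    } else {
      sc_stability[c] = child_sum;
    }
  }
  selected[0] = false;  // root never selectable

  // deterministic labels in cluster-id order
  std::vector<int> label_of(ncl, NA_INTEGER);
  int next_label = 1;
  for (int c = 1; c < ncl; ++c)
    if (selected[c]) label_of[c] = next_label++;

  IntegerVector lab(n, NA_INTEGER);
  for (int p = 0; p < n; ++p) {
    int c = point_parent[p];
    while (c >= 0 && !selected[c]) c = clusters[c].parent;
    if (c >= 0) lab[p] = label_of[c];
  }
  return lab;
}

// Neighbour counts from a subset of focal points to all points (self
// excluded), cumulated over a radius grid: counts[k] = sum over focal i of
// #{j != i : d_ij <= r_k}. Used by the border-method (minus-sampling)
// estimator of Ripley's K.
// [[Rcpp::export]]
NumericVector ripley_k_counts_focal(NumericVector x, NumericVector y,
                                    IntegerVector focal0, NumericVector r) {
  const int n = x.size(), nf = focal0.size(), nr = r.size();
  const double rmax = r[nr - 1];
  // histogram over 1-unit-resolution bins would lose exactness; bin per grid
  std::vector<double> cnt(nr, 0.0);
  for (int fi = 0; fi < nf; ++fi) {
    const int i = focal0[fi];
    const double xi = x[i], yi = y[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xi - x[j], dy = yi - y[j];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d > rmax) continue;
      // first grid index with r >= d
      int k = (int)(std::lower_bound(r.begin(), r.end(), d) - r.begin());
      if (k < nr) cnt[k] += 1.0;
    }
  }
  NumericVector out(nr);
  double acc = 0.0;
  for (int k = 0; k < nr; ++k) { acc += cnt[k]; out[k] = acc; }
  return out;
}

// Ripley's K for one point set, no edge correction:
// K(r) = area * sum_{i != j} 1(d_ij <= r) / (n (n - 1)).
// [[Rcpp::export]]
NumericVector ripley_k_counts(NumericVector x, NumericVector y,
                              NumericVector r) {
  const int n = x.size(), nr = r.size();
  NumericVector counts(nr);
  std::vector<double> d;
  d.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      d.push_back(std::sqrt(dx * dx + dy * dy));
    }
  std::sort(d.begin(), d.end());
  for (int k = 0; k < nr; ++k) {
    // ordered pairs: twice the number of unordered pairs within r
    counts[k] = 2.0 * (std::upper_bound(d.begin(), d.end(), r[k]) - d.begin());
  }
  return counts;
}
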