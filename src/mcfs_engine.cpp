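#include <Rcpp.h>
#include <map>
#include <utility>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Binary-class CART-style trees grown by impurity decrease, plus the
// Monte Carlo projection loop that aggregates relative importance (RI)
// and path co-occurrence interdependencies (ID). All randomness comes
// from R's RNG stream so results reproduce from set.seed().
//
// Split search uses the presorted-feature scan: each feature's global
// sort order is computed once per dataset; at a node, candidate
// boundaries are found by one pass over that order restricted to the
// node's membership mask.

namespace {

inline double entropy2(double c0, double c1) {
  double n = c0 + c1;
  if (n <= 0.0) return 0.0;
  double h = 0.0;
  if (c0 > 0.0) { double p = c0 / n; h -= p * std::log2(p); }
  if (c1 > 0.0) { double p = c1 / n; h -= p * std::log2(p); }
  return h;
}

inline double gini2(double c0, double c1) {
  double n = c0 + c1;
  if (n <= 0.0) return 0.0;
  double p0 = c0 / n, p1 = c1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

inline double impurity(double c0, double c1, bool use_gini) {
  return use_gini ? gini2(c0, c1) : entropy2(c0, c1);
}

typedef std::vector<std::vector<int> > SortOrder;

SortOrder presort(const NumericMatrix& X) {
  int n = X.nrow(), p = X.ncol();
  SortOrder order(p);
  for (int f = 0; f < p; ++f) {
    std::vector<int>& o = order[f];
    o.resize(n);
    for (int i = 0; i < n; ++i) o[i] = i;
    const double* col = &X(0, f);
    std::sort(o.begin(), o.end(),
              [col](int a, int b) { return col[a] < col[b]; });
  }
  return order;
}

struct Tree {
  std::vector<int> feature;      // 0-based column in X, -1 at leaves
  std::vector<double> threshold; // split: x <= threshold goes left
  std::vector<double> ig;        // impurity decrease at internal nodes
  std::vector<int> count;        // training samples reaching the node
  std::vector<int> parent;       // -1 at root
  std::vector<int> depth;
  std::vector<int> left, right;  // -1 at leaves
  std::vector<int> pred;         // majority class at the node

  int n_internal() const {
    int k = 0;
    for (size_t i = 0; i < feature.size(); ++i) if (feature[i] >= 0) ++k;
    return k;
  }
};

struct SplitResult {
  bool found;
  int feature;
  double threshold;
  double gain;
};

// Per-node view: for every candidate feature, the node's member rows in
// that feature's sorted order (partitioned down from the parent, so no
// re-sorting below the root).
typedef std::vector<std::vector<int> > NodeLists;

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  const SortOrder& order;
  std::vector<int> feats;          // sorted ascending (tie-break rule)
  std::vector<uint8_t> in_node;    // scratch mask for the root filter
  double eps, max_depth;
  int min_split;
  bool use_gini;

  Grower(const NumericMatrix& X_, const IntegerVector& y_,
         const SortOrder& order_, const std::vector<int>& feats_,
         double eps_, double max_depth_, int min_split_, bool use_gini_)
    : X(X_), y(y_), order(order_), feats(feats_),
      in_node(X_.nrow(), 0), eps(eps_), max_depth(max_depth_),
      min_split(min_split_), use_gini(use_gini_) {
    std::sort(feats.begin(), feats.end());
  }

  // Best axis-aligned split over the node's sorted member lists.
  // Thresholds are midpoints between consecutive distinct sorted values;
  // ties in gain resolve to the lowest feature index, then the lowest
  // threshold (features ascending, thresholds ascending, strict >).
  SplitResult best_split(const NodeLists& lists, int n,
                         double tot0, double tot1) {
    SplitResult best{false, -1, 0.0, 0.0};
    double h_parent = impurity(tot0, tot1, use_gini);
    if (h_parent <= 0.0) return best;

    for (size_t fi = 0; fi < feats.size(); ++fi) {
      int f = feats[fi];
      const double* col = &X(0, f);
      const std::vector<int>& rows = lists[fi];
      double l0 = 0.0, l1 = 0.0, prev_val = 0.0;
      int seen = 0;
      for (int row : rows) {
        double val = col[row];
        if (seen > 0 && val > prev_val) {
          double nl = l0 + l1, nr = n - nl;
          double gain = h_parent -
            (nl / n) * impurity(l0, l1, use_gini) -
            (nr / n) * impurity(tot0 - l0, tot1 - l1, use_gini);
          if (gain > best.gain) {
            best.found = true;
            best.feature = f;
            best.threshold = 0.5 * (prev_val + val);
            best.gain = gain;
          }
        }
        (y[row] == 0 ? l0 : l1) += 1.0;
        prev_val = val;
        ++seen;
      }
    }
    return best;
  }

  int new_node(Tree& tr, const std::vector<int>& idx, int depth, int parent) {
    int node = (int)tr.feature.size();
    double c0 = 0.0, c1 = 0.0;
    for (int i : idx) (y[i] == 0 ? c0 : c1) += 1.0;
    tr.feature.push_back(-1);
    tr.threshold.push_back(NA_REAL);
    tr.ig.push_back(0.0);
    tr.count.push_back((int)idx.size());
    tr.parent.push_back(parent);
    tr.depth.push_back(depth);
    tr.left.push_back(-1);
    tr.right.push_back(-1);
    tr.pred.push_back(c1 > c0 ? 1 : 0); // tie -> lower class label
    return node;
  }

  void split_node(Tree& tr, int node, const std::vector<int>& idx,
                  const NodeLists& lists) {
    if ((int)idx.size() < min_split) return;
    double c0 = 0.0, c1 = 0.0;
    for (int i : idx) (y[i] == 0 ? c0 : c1) += 1.0;
    if (c0 == 0.0 || c1 == 0.0) return;             // pure
    if ((double)tr.depth[node] >= max_depth) return; // depth cap

    SplitResult sp = best_split(lists, (int)idx.size(), c0, c1);
    if (!sp.found || sp.gain <= eps) return;

    std::vector<int> lidx, ridx;
    lidx.reserve(idx.size());
    ridx.reserve(idx.size());
    for (int i : idx) {
      if (X(i, sp.feature) <= sp.threshold) lidx.push_back(i);
      else ridx.push_back(i);
    }
    if (lidx.empty() || ridx.empty()) return;

    tr.feature[node] = sp.feature;
    tr.threshold[node] = sp.threshold;
    tr.ig[node] = sp.gain;

    // stable-partition each feature's sorted member list into children
    const double* scol = &X(0, sp.feature);
    NodeLists llists(feats.size()), rlists(feats.size());
    for (size_t fi = 0; fi < feats.size(); ++fi) {
      llists[fi].reserve(lidx.size());
      rlists[fi].reserve(ridx.size());
      for (int row : lists[fi]) {
        if (scol[row] <= sp.threshold) llists[fi].push_back(row);
        else rlists[fi].push_back(row);
      }
    }

    int lnode = new_node(tr, lidx, tr.depth[node] + 1, node);
    tr.left[node] = lnode;
    split_node(tr, lnode, lidx, llists);

    int rnode = new_node(tr, ridx, tr.depth[node] + 1, node);
    tr.right[node] = rnode;
    split_node(tr, rnode, ridx, rlists);
  }

  Tree build(const std::vector<int>& rows) {
    Tree tr;
    for (int i : rows) in_node[i] = 1;
    NodeLists lists(feats.size());
    for (size_t fi = 0; fi < feats.size(); ++fi) {
      lists[fi].reserve(rows.size());
      for (int row : order[feats[fi]])
        if (in_node[row]) lists[fi].push_back(row);
    }
    for (int i : rows) in_node[i] = 0;
    int root = new_node(tr, rows, 0, -1);
    split_node(tr, root, rows, lists);
    return tr;
  }
};

int predict_one(const Tree& tr, const NumericMatrix& X, int row) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    node = (X(row, tr.feature[node]) <= tr.threshold[node]) ? tr.left[node]
                                                            : tr.right[node];
  }
  return tr.pred[node];
}

// Balanced accuracy on held-out rows; requires both classes present.
double weighted_acc(const Tree& tr, const NumericMatrix& X,
                    const IntegerVector& y, const std::vector<int>& rows) {
  double ok0 = 0.0, n0 = 0.0, ok1 = 0.0, n1 = 0.0;
  for (int i : rows) {
    int pr = predict_one(tr, X, i);
    if (y[i] == 0) { n0 += 1.0; if (pr == 0) ok0 += 1.0; }
    else           { n1 += 1.0; if (pr == 1) ok1 += 1.0; }
  }
  if (n0 == 0.0 || n1 == 0.0) return NA_REAL;
  return 0.5 * (ok0 / n0 + ok1 / n1);
}

List tree_to_list(const Tree& tr, double wacc) {
  int k = (int)tr.feature.size();
  IntegerVector feature(k), count(k), parent(k), depth(k), left(k), right(k), pred(k);
  NumericVector threshold(k), ig(k);
  for (int i = 0; i < k; ++i) {
    feature[i] = tr.feature[i] >= 0 ? tr.feature[i] + 1 : NA_INTEGER;
    threshold[i] = tr.threshold[i];
    ig[i] = tr.ig[i];
    count[i] = tr.count[i];
    parent[i] = tr.parent[i] >= 0 ? tr.parent[i] + 1 : NA_INTEGER;
    depth[i] = tr.depth[i];
    left[i] = tr.left[i] >= 0 ? tr.left[i] + 1 : NA_INTEGER;
    right[i] = tr.right[i] >= 0 ? tr.right[i] + 1 : NA_INTEGER;
    pred[i] = tr.pred[i];
  }
  return List::create(
    _["feature"] = feature, _["threshold"] = threshold, _["ig"] = ig,
    _["count"] = count, _["parent"] = parent, _["depth"] = depth,
    _["left"] = left, _["right"] = right, _["pred"] = pred,
    _["wacc"] = wacc);
}

// Draw k distinct integers from 0..n-1 (partial Fisher-Yates, R RNG).
void sample_k(std::vector<int>& pool, int k, std::vector<int>& out) {
  int n = (int)pool.size();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)std::floor(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
  }
  out.assign(pool.begin(), pool.begin() + k);
}

void shuffle_all(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_build_tree(NumericMatrix X, IntegerVector y, IntegerVector rows,
                    IntegerVector feats, double eps, double max_depth,
                    int min_split, bool use_gini) {
  std::vector<int> ridx(rows.begin(), rows.end());
  std::vector<int> fidx(feats.begin(), feats.end());
  for (int& r : ridx) --r; // 1-based from R
  for (int& f : fidx) --f;
  SortOrder order = presort(X);
  Grower g(X, y, order, fidx, eps, max_depth, min_split, use_gini);
  Tree tr = g.build(ridx);
  return tree_to_list(tr, NA_REAL);
}

// [[Rcpp::export]]
IntegerVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"], pred = tree["pred"];
  NumericVector threshold = tree["threshold"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      int f = feature[node] - 1;
      node = (X(i, f) <= threshold[node]) ? left[node] - 1 : right[node] - 1;
    }
    out[i] = pred[node];
  }
  return out;
}

// The Monte Carlo projection loop: s feature subsets x t stratified
// train/test splits, streaming RI and ID accumulation. Each ordered
// feature pair is credited once per tree with its strongest
// ancestor-descendant contribution, wAcc^u * IG(n) *
// (count(n)/count(root))^v / dist (the structure-analysis weights that
// drive RI, divided by path distance); the count-only variant
// (id_ig_weighted = false) takes 1/dist. Edge counts tally the number
// of trees in which the pair co-occurs on a path.
// [[Rcpp::export]]
List cpp_run_mcfs(NumericMatrix X, IntegerVector y, int s, int m, int t,
                  double u, double v, double split_fraction,
                  double max_depth, int min_split, double eps, bool use_gini,
                  bool id_ig_weighted, bool keep_trees) {
  int n = X.nrow(), p = X.ncol();
  std::vector<int> idx0, idx1;
  for (int i = 0; i < n; ++i) (y[i] == 0 ? idx0 : idx1).push_back(i);
  int n0 = (int)idx0.size(), n1 = (int)idx1.size();
  if (n0 < 2 || n1 < 2)
    stop("each class needs at least 2 samples for stratified splitting");
  if (m > p) stop("m (%d) exceeds the number of features (%d)", m, p);

  int n0tr = std::min(n0 - 1, std::max(1, (int)std::lround(split_fraction * n0)));
  int n1tr = std::min(n1 - 1, std::max(1, (int)std::lround(split_fraction * n1)));

  SortOrder order = presort(X);
  NumericVector ri(p);
  IntegerVector sampled(p);
  NumericVector wacc_all(s * t);
  std::map<std::pair<int, int>, std::pair<double, long> > edges;
  int n_degenerate = 0;
  List trees(keep_trees ? s * t : 0);

  std::vector<int> fpool(p), feats, train, test;
  for (int i = 0; i < p; ++i) fpool[i] = i;

  int tree_i = 0;
  for (int si = 0; si < s; ++si) {
    sample_k(fpool, m, feats);
    for (int f : feats) sampled[f] += 1;
    Grower grower(X, y, order, feats, eps, max_depth, min_split, use_gini);
    for (int ti = 0; ti < t; ++ti) {
      shuffle_all(idx0);
      shuffle_all(idx1);
      train.clear(); test.clear();
      train.insert(train.end(), idx0.begin(), idx0.begin() + n0tr);
      train.insert(train.end(), idx1.begin(), idx1.begin() + n1tr);
      test.insert(test.end(), idx0.begin() + n0tr, idx0.end());
      test.insert(test.end(), idx1.begin() + n1tr, idx1.end());

      Tree tr = grower.build(train);
      double wacc = weighted_acc(tr, X, y, test);
      wacc_all[tree_i] = wacc;
      int n_int = tr.n_internal();
      if (n_int == 0) ++n_degenerate;

      if (n_int > 0 && !ISNA(wacc)) {
        double wu = std::pow(wacc, u);
        double rootc = (double)tr.count[0];
        std::map<std::pair<int, int>, double> tree_best;
        for (size_t nd = 0; nd < tr.feature.size(); ++nd) {
          if (tr.feature[nd] < 0) continue;
          double node_w = tr.ig[nd] * std::pow(tr.count[nd] / rootc, v);
          ri[tr.feature[nd]] += wu * node_w;
          // interdependencies: every ancestor split on this node's path
          int a = tr.parent[nd];
          while (a >= 0) {
            if (tr.feature[a] >= 0) {
              int dist = tr.depth[nd] - tr.depth[a];
              double contrib = (id_ig_weighted ? wu * node_w : 1.0) / dist;
              std::pair<int, int> key(tr.feature[a], tr.feature[nd]);
              std::map<std::pair<int, int>, double>::iterator it =
                tree_best.find(key);
              if (it == tree_best.end()) tree_best[key] = contrib;
              else if (contrib > it->second) it->second = contrib;
            }
            a = tr.parent[a];
          }
        }
        for (std::map<std::pair<int, int>, double>::iterator it =
               tree_best.begin(); it != tree_best.end(); ++it) {
          std::pair<double, long>& e = edges[it->first];
          e.first += it->second;
          e.second += 1;
        }
      }
      if (keep_trees) trees[tree_i] = tree_to_list(tr, wacc);
      ++tree_i;
      if (tree_i % 4096 == 0) Rcpp::checkUserInterrupt();
    }
  }

  int ne = (int)edges.size();
  IntegerVector efrom(ne), eto(ne), ecount(ne);
  NumericVector eweight(ne);
  int k = 0;
  for (std::map<std::pair<int, int>, std::pair<double, long> >::iterator it =
         edges.begin(); it != edges.end(); ++it, ++k) {
    efrom[k] = it->first.first + 1;
    eto[k] = it->first.second + 1;
    eweight[k] = it->second.first;
    ecount[k] = (int)it->second.second;
  }

  List out = List::create(
    _["ri"] = ri, _["sampled"] = sampled, _["wacc"] = wacc_all,
    _["n_degenerate"] = n_degenerate,
    _["edge_from"] = efrom, _["edge_to"] = eto,
    _["edge_weight"] = eweight, _["edge_count"] = ecount);
  if (keep_trees) out["trees"] = trees;
  return out;
}
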