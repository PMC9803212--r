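// Stochastic gradient boosting for a Bernoulli response with small
// regression trees grown best-first, as used for presence/background
// species distribution models.  Trees are returned as flat node tables so
// the fitted model is a plain R list that can be serialized as text.
//
// Node table layout (one row per node, 1-based child indices, row 1 = root):
//   col 0: split variable (1-based; 0 for a terminal node)
//   col 1: split threshold (x <= thr goes left)
//   col 2: left child row   (0 for terminal)
//   col 3: right child row  (0 for terminal)
//   col 4: fitted value on the link scale (terminal nodes only)
//   col 5: squared-error reduction achieved by this split (0 for terminal)
//
// All randomness comes from R's RNG (unif_rand) so set.seed() on the R side
// makes every fit exactly reproducible.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Leaf {
  std::vector<int> rows;     // bagged row indices in this leaf
  int    best_var  = -1;     // 0-based; -1 when no admissible split
  double best_thr  = 0.0;
  double best_gain = 0.0;
  int    node_row  = 0;      // row in the output node table (0-based)
};

struct SplitSearch {
  const NumericMatrix& X;
  const std::vector<double>& z;
  int min_node;

  // Best split of `rows` by squared-error reduction of the working
  // response.  Ties broken by lowest variable index then lowest threshold
  // (strict > comparison while scanning in ascending order).
  void search(Leaf& leaf) const {
    const std::vector<int>& rows = leaf.rows;
    const int n = static_cast<int>(rows.size());
    leaf.best_var = -1; leaf.best_gain = 0.0;
    if (n < 2 * min_node) return;

    double ztot = 0.0;
    for (int r : rows) ztot += z[r];

    std::vector<int> ord(rows);
    std::vector<double> xv(n);
    for (int j = 0; j < X.ncol(); ++j) {
      for (int i = 0; i < n; ++i) xv[i] = X(rows[i], j);
      // sort row indices of this leaf by predictor j
      std::vector<int> idx(n);
      for (int i = 0; i < n; ++i) idx[i] = i;
      std::stable_sort(idx.begin(), idx.end(),
                       [&](int a, int b) { return xv[a] < xv[b]; });
      double zl = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        zl += z[rows[idx[k]]];
        const double xk = xv[idx[k]], xk1 = xv[idx[k + 1]];
        if (xk == xk1) continue;               // not a boundary
        const int nl = k + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        const double zr = ztot - zl;
        const double gain =
            zl * zl / nl + zr * zr / nr - ztot * ztot / n;
        if (gain > leaf.best_gain) {
          leaf.best_gain = gain;
          leaf.best_var  = j;
          leaf.best_thr  = 0.5 * (xk + xk1);
        }
      }
    }
  }
};

// Newton step for the Bernoulli deviance in a terminal node:
//   sum(z) / sum(p (1 - p))  with z = y - p.
double newton_value(const std::vector<int>& rows,
                    const std::vector<double>& z,
                    const std::vector<double>& w) {
  double num = 0.0, den = 0.0;
  for (int r : rows) { num += z[r]; den += w[r]; }
  if (den < 1e-12) return 0.0;
  double v = num / den;
  // guard against wild steps in nearly pure nodes
  if (v >  4.0) v =  4.0;
  if (v < -4.0) v = -4.0;
  return v;
}

// Grow one tree best-first to at most `tc` splits; returns the node table
// and updates F (link-scale fit, all rows) in place by lr * fitted value.
NumericMatrix grow_tree(const NumericMatrix& X,
                        const std::vector<double>& z,
                        const std::vector<double>& w,
                        const std::vector<int>& bag,
                        int tc, int min_node, double lr,
                        std::vector<double>& F) {
  SplitSearch searcher{X, z, min_node};

  std::vector<Leaf> leaves;
  Leaf root; root.rows = bag; root.node_row = 0;
  searcher.search(root);
  leaves.push_back(std::move(root));

  // node storage grows as we split; start with the root
  std::vector<std::array<double, 6>> nodes;
  nodes.push_back({0.0, 0.0, 0.0, 0.0, 0.0, 0.0});

  int splits = 0;
  while (splits < tc) {
    // leaf with the largest gain; first encountered wins ties
    int best = -1; double bg = 0.0;
    for (size_t i = 0; i < leaves.size(); ++i)
      if (leaves[i].best_var >= 0 && leaves[i].best_gain > bg) {
        bg = leaves[i].best_gain; best = static_cast<int>(i);
      }
    if (best < 0) break;                       // no admissible split left

    Leaf parent = leaves[best];
    leaves.erase(leaves.begin() + best);

    Leaf lo, hi;
    for (int r : parent.rows) {
      if (X(r, parent.best_var) <= parent.best_thr) lo.rows.push_back(r);
      else                                          hi.rows.push_back(r);
    }
    lo.node_row = static_cast<int>(nodes.size());
    nodes.push_back({0.0, 0.0, 0.0, 0.0, 0.0, 0.0});
    hi.node_row = static_cast<int>(nodes.size());
    nodes.push_back({0.0, 0.0, 0.0, 0.0, 0.0, 0.0});

    auto& pn = nodes[parent.node_row];
    pn[0] = parent.best_var + 1;
    pn[1] = parent.best_thr;
    pn[2] = lo.node_row + 1;
    pn[3] = hi.node_row + 1;
    pn[5] = parent.best_gain;

    searcher.search(lo);
    searcher.search(hi);
    leaves.push_back(std::move(lo));
    leaves.push_back(std::move(hi));
    ++splits;
  }

  for (const Leaf& lf : leaves)
    nodes[lf.node_row][4] = newton_value(lf.rows, z, w);

  // update F for ALL rows (bagged and out-of-bag) by routing through the tree
  const int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    int cur = 0;
    while (nodes[cur][0] > 0.0) {
      const int j = static_cast<int>(nodes[cur][0]) - 1;
      cur = (X(i, j) <= nodes[cur][1])
              ? static_cast<int>(nodes[cur][2]) - 1
              : static_cast<int>(nodes[cur][3]) - 1;
    }
    F[i] += lr * nodes[cur][4];
  }

  NumericMatrix out(static_cast<int>(nodes.size()), 6);
  for (size_t i = 0; i < nodes.size(); ++i)
    for (int j = 0; j < 6; ++j) out(i, j) = nodes[i][j];
  return out;
}

// partial Fisher-Yates draw of m indices out of n, driven by R's RNG
std::vector<int> sample_rows(int n, int m) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int j = 0; j < m; ++j) {
    int k = j + static_cast<int>(unif_rand() * (n - j));
    if (k >= n) k = n - 1;
    std::swap(idx[j], idx[k]);
  }
  idx.resize(m);
  return idx;
}

double mean_bernoulli_deviance(const std::vector<double>& F,
                               const NumericVector& y) {
  const double eps = 1e-12;
  double s = 0.0;
  const int n = static_cast<int>(F.size());
  for (int i = 0; i < n; ++i) {
    double p = 1.0 / (1.0 + std::exp(-F[i]));
    if (p < eps) p = eps;
    if (p > 1.0 - eps) p = 1.0 - eps;
    s += -2.0 * (y[i] * std::log(p) + (1.0 - y[i]) * std::log(1.0 - p));
  }
  return s / n;
}

int route(const NumericMatrix& tree, const NumericMatrix& X, int i) {
  int cur = 0;
  while (tree(cur, 0) > 0.0) {
    const int j = static_cast<int>(tree(cur, 0)) - 1;
    cur = (X(i, j) <= tree(cur, 1))
            ? static_cast<int>(tree(cur, 2)) - 1
            : static_cast<int>(tree(cur, 3)) - 1;
  }
  return cur;
}

} // namespace

// [[Rcpp::export(name = ".cpp_fit_brt")]]
List cpp_fit_brt(NumericMatrix X, NumericVector y,
                 int n_trees, int tc, double lr, double bag_fraction,
                 int min_node,
                 NumericMatrix Xv, NumericVector yv,
                 int step, int patience) {
  const int n = X.nrow();
  const bool has_valid = Xv.nrow() > 0;

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  if (ybar <= 0.0 || ybar >= 1.0)
    stop("response must contain both classes");
  const double intercept = std::log(ybar / (1.0 - ybar));

  std::vector<double> F(n, intercept);
  std::vector<double> Fv(Xv.nrow(), intercept);
  std::vector<double> z(n), w(n);

  const int m = std::max(1, static_cast<int>(std::ceil(bag_fraction * n)));

  List trees(n_trees);
  std::vector<double> trace;
  std::vector<int> trace_trees;
  double best_dev = R_PosInf;
  int since_best = 0;
  int fitted = 0;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      const double p = 1.0 / (1.0 + std::exp(-F[i]));
      z[i] = y[i] - p;
      w[i] = p * (1.0 - p);
    }
    std::vector<int> bag =
        (m >= n) ? sample_rows(n, n) : sample_rows(n, m);
    NumericMatrix tree = grow_tree(X, z, w, bag, tc, min_node, lr, F);

    // route validation rows through the new tree
    if (has_valid) {
      for (int i = 0; i < Xv.nrow(); ++i)
        Fv[i] += lr * tree(route(tree, Xv, i), 4);
    }
    trees[t] = tree;
    fitted = t + 1;

    if (has_valid && fitted % step == 0) {
      const double dev = mean_bernoulli_deviance(Fv, yv);
      trace.push_back(dev);
      trace_trees.push_back(fitted);
      if (dev < best_dev - 1e-10) { best_dev = dev; since_best = 0; }
      else if (++since_best >= patience) break;
    }
  }

  List kept(fitted);
  for (int t = 0; t < fitted; ++t) kept[t] = trees[t];

  return List::create(
      _["intercept"]   = intercept,
      _["trees"]       = kept,
      _["n_trees"]     = fitted,
      _["valid_trees"] = wrap(trace_trees),
      _["valid_dev"]   = wrap(trace));
}

// [[Rcpp::export(name = ".cpp_fit_tree")]]
NumericMatrix cpp_fit_tree(NumericMatrix X, NumericVector z_in,
                           NumericVector w_in, int tc, int min_node) {
  const int n = X.nrow();
  std::vector<double> z(z_in.begin(), z_in.end());
  std::vector<double> w(w_in.begin(), w_in.end());
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  std::vector<double> F(n, 0.0);   // throwaway; lr = 0 leaves F unchanged
  return grow_tree(X, z, w, all, tc, min_node, 0.0, F);
}

// [[Rcpp::export(name = ".cpp_predict_brt")]]
NumericVector cpp_predict_brt(List trees, double intercept, double lr,
                              NumericMatrix X, int n_trees) {
  const int n = X.nrow();
  const int nt = std::min<int>(n_trees, trees.size());
  NumericVector F(n, intercept);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i)
      F[i] += lr * tree(route(tree, X, i), 4);
  }
  return F;   // link scale; R side applies plogis
}
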