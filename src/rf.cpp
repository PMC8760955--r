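// Random forest over binary (one-hot) features.
//
// CART-style trees: Gini impurity, bootstrap resampling, sqrt(p) feature
// subsampling at each node, grown to purity (min_split = 2). Scores are the
// per-leaf positive-class fraction averaged across trees. All randomness is
// drawn from R's RNG so set.seed() on the R side makes training reproducible.
//
// Features must be 0/1; splits send x == 0 left, x == 1 right. This is all the
// one-hot encoding of aligned antibody sequences requires, and it keeps split
// search to a single counting pass per candidate feature.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tree {
  // feature[i] >= 0: internal node splitting on that column (0-based);
  // feature[i] == -1: leaf, value[i] = positive-class fraction.
  std::vector<int> feature;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> value;
};

inline double gini(double n_pos, double n) {
  if (n <= 0.0) return 0.0;
  const double p = n_pos / n;
  return 2.0 * p * (1.0 - p);
}

// One uniform integer in [0, n) from R's RNG.
inline int runif_int(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

class TreeBuilder {
public:
  TreeBuilder(const IntegerMatrix& X, const IntegerVector& y, int mtry,
              int min_split, std::vector<double>& importance)
      : X_(X), y_(y), n_(X.nrow()), p_(X.ncol()), mtry_(mtry),
        min_split_(min_split), importance_(importance), seen_(p_, -1) {}

  Tree build(const std::vector<int>& boot) {
    tree_ = Tree();
    n_boot_ = static_cast<double>(boot.size());
    std::vector<int> idx(boot);
    grow(idx);
    return tree_;
  }

private:
  int new_node() {
    tree_.feature.push_back(-1);
    tree_.left.push_back(-1);
    tree_.right.push_back(-1);
    tree_.value.push_back(0.0);
    return static_cast<int>(tree_.feature.size()) - 1;
  }

  int grow(std::vector<int>& idx) {
    const int node = new_node();
    const int n = static_cast<int>(idx.size());
    int n_pos = 0;
    for (int i = 0; i < n; ++i) n_pos += y_[idx[i]];
    const double leaf_value = static_cast<double>(n_pos) / n;

    if (n < min_split_ || n_pos == 0 || n_pos == n) {
      tree_.value[node] = leaf_value;
      return node;
    }

    // Sample mtry distinct candidate features.
    int best_f = -1, best_n1 = 0, best_pos1 = 0;
    double best_dec = 1e-12;
    const double g_parent = gini(n_pos, n);
    for (int draw = 0, got = 0; got < mtry_ && draw < 8 * mtry_ + 64; ++draw) {
      const int f = runif_int(p_);
      if (seen_[f] == stamp_) continue;
      seen_[f] = stamp_;
      picked_.push_back(f);
      ++got;
      int n1 = 0, pos1 = 0;
      for (int i = 0; i < n; ++i) {
        if (X_(idx[i], f)) {
          ++n1;
          pos1 += y_[idx[i]];
        }
      }
      if (n1 == 0 || n1 == n) continue;
      const int n0 = n - n1, pos0 = n_pos - pos1;
      const double dec = g_parent -
          (n0 * gini(pos0, n0) + n1 * gini(pos1, n1)) / n;
      if (dec > best_dec) {
        best_dec = dec;
        best_f = f;
        best_n1 = n1;
        best_pos1 = pos1;
      }
    }
    // Reset the dedup stamps we used at this node.
    for (size_t i = 0; i < picked_.size(); ++i) seen_[picked_[i]] = -1;
    picked_.clear();

    if (best_f < 0) {  // no admissible split among candidates
      tree_.value[node] = leaf_value;
      return node;
    }

    importance_[best_f] += best_dec * n / n_boot_;

    std::vector<int> idx_left, idx_right;
    idx_left.reserve(n - best_n1);
    idx_right.reserve(best_n1);
    for (int i = 0; i < n; ++i) {
      if (X_(idx[i], best_f)) idx_right.push_back(idx[i]);
      else idx_left.push_back(idx[i]);
    }
    std::vector<int>().swap(idx);  // free before recursing

    tree_.feature[node] = best_f;
    tree_.left[node] = grow(idx_left);
    tree_.right[node] = grow(idx_right);
    (void)best_pos1;
    return node;
  }

  const IntegerMatrix& X_;
  const IntegerVector& y_;
  const int n_, p_, mtry_, min_split_;
  std::vector<double>& importance_;
  std::vector<int> seen_;
  std::vector<int> picked_;
  Tree tree_;
  double n_boot_;
  static const int stamp_ = 1;
};

List tree_to_list(const Tree& t) {
  return List::create(_["feature"] = wrap(t.feature), _["left"] = wrap(t.left),
                      _["right"] = wrap(t.right), _["value"] = wrap(t.value));
}

Tree tree_from_list(const List& l) {
  Tree t;
  t.feature = as<std::vector<int> >(l["feature"]);
  t.left = as<std::vector<int> >(l["left"]);
  t.right = as<std::vector<int> >(l["right"]);
  t.value = as<std::vector<double> >(l["value"]);
  return t;
}

inline double tree_predict_row(const Tree& t, const IntegerMatrix& X, int row) {
  int node = 0;
  while (t.feature[node] >= 0) {
    node = X(row, t.feature[node]) ? t.right[node] : t.left[node];
  }
  return t.value[node];
}

}  // namespace

//' @useDynLib abhumanize, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(IntegerMatrix X, IntegerVector y, int n_trees, int mtry,
            int min_split) {
  const int n = X.nrow(), p = X.ncol();
  if (n_trees < 1) stop("n_trees must be >= 1");
  if (mtry < 1 || mtry > p) stop("mtry must be in [1, ncol(X)]");
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  for (int i = 0; i < n; ++i) {
    if (y[i] != 0 && y[i] != 1) stop("y must be 0/1");
  }

  RNGScope scope;
  std::vector<double> importance(p, 0.0);
  List trees(n_trees);
  TreeBuilder builder(X, y, mtry, min_split, importance);
  std::vector<int> boot(n);
  for (int b = 0; b < n_trees; ++b) {
    for (int i = 0; i < n; ++i) boot[i] = runif_int(n);
    trees[b] = tree_to_list(builder.build(boot));
  }

  double total = 0.0;
  for (int j = 0; j < p; ++j) total += importance[j];
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = total > 0 ? importance[j] / total : 0.0;

  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["n_features"] = p);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(List forest, IntegerMatrix X) {
  const List trees = forest["trees"];
  const int p_expect = as<int>(forest["n_features"]);
  if (X.ncol() != p_expect) stop("feature count mismatch: model expects %d, got %d",
                                 p_expect, X.ncol());
  const int n = X.nrow(), n_trees = trees.size();
  std::vector<Tree> ts;
  ts.reserve(n_trees);
  for (int b = 0; b < n_trees; ++b) ts.push_back(tree_from_list(trees[b]));

  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int b = 0; b < n_trees; ++b) s += tree_predict_row(ts[b], X, i);
    out[i] = s / n_trees;
  }
  return out;
}
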