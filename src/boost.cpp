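// Depth-limited gradient-boosted trees for binary classification
// (logistic loss, Newton leaf values), plus exact path-dependent Shapley
// attributions. Deterministic: no row/feature subsampling, ties broken by
// lowest feature index then lowest threshold.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Tree {
  std::vector<int> feature, left, right;   // feature = -1 for leaves
  std::vector<double> threshold, value, cover;
};

static const double EPS_H = 1e-16;

static int build_node(const NumericMatrix &X,
                      const std::vector<std::vector<int> > &order,
                      const std::vector<double> &grad,
                      const std::vector<double> &hess,
                      std::vector<char> &in_node,
                      const std::vector<int> &rows,
                      int depth, int max_depth, int min_leaf,
                      double min_gain, Tree &tree) {
  const int p = X.ncol();
  double G = 0, H = 0;
  for (int r : rows) { G += grad[r]; H += hess[r]; }

  int best_f = -1; double best_thr = 0, best_gain = min_gain;
  if (depth < max_depth && (int)rows.size() >= 2 * min_leaf) {
    for (int r : rows) in_node[r] = 1;
    for (int j = 0; j < p; ++j) {
      double GL = 0, HL = 0; int nL = 0;
      double prev = 0; bool have_prev = false;
      for (int k = 0; k < (int)order[j].size(); ++k) {
        int r = order[j][k];
        if (!in_node[r]) continue;
        double xv = X(r, j);
        if (have_prev && xv > prev && nL >= min_leaf &&
            (int)rows.size() - nL >= min_leaf) {
          double GR = G - GL, HR = H - HL;
          double gain = GL * GL / (HL + EPS_H) + GR * GR / (HR + EPS_H) -
                        G * G / (H + EPS_H);
          if (gain > best_gain + 1e-12) {
            best_gain = gain; best_f = j; best_thr = 0.5 * (prev + xv);
          }
        }
        GL += grad[r]; HL += hess[r]; ++nL;
        prev = xv; have_prev = true;
      }
    }
    for (int r : rows) in_node[r] = 0;
  }

  int id = (int)tree.feature.size();
  tree.feature.push_back(-1); tree.threshold.push_back(0);
  tree.left.push_back(-1); tree.right.push_back(-1);
  tree.value.push_back(-G / (H + EPS_H));
  tree.cover.push_back((double)rows.size());
  if (best_f < 0) return id;

  std::vector<int> lrows, rrows;
  for (int r : rows)
    (X(r, best_f) < best_thr ? lrows : rrows).push_back(r);
  tree.feature[id] = best_f; tree.threshold[id] = best_thr;
  int l = build_node(X, order, grad, hess, in_node, lrows, depth + 1,
                     max_depth, min_leaf, min_gain, tree);
  int r = build_node(X, order, grad, hess, in_node, rrows, depth + 1,
                     max_depth, min_leaf, min_gain, tree);
  tree.left[id] = l; tree.right[id] = r;
  return id;
}

static double tree_predict(const Tree &t, const NumericMatrix &X, int row) {
  int id = 0;
  while (t.feature[id] >= 0)
    id = (X(row, t.feature[id]) < t.threshold[id]) ? t.left[id] : t.right[id];
  return t.value[id];
}

static List tree_to_list(const Tree &t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value), _["cover"] = wrap(t.cover));
}

static Tree tree_from_list(const List &l) {
  Tree t;
  t.feature = as<std::vector<int> >(l["feature"]);
  t.threshold = as<std::vector<double> >(l["threshold"]);
  t.left = as<std::vector<int> >(l["left"]);
  t.right = as<std::vector<int> >(l["right"]);
  t.value = as<std::vector<double> >(l["value"]);
  t.cover = as<std::vector<double> >(l["cover"]);
  return t;
}

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, int nrounds,
                 double learning_rate, int max_depth, int min_leaf,
                 double min_gain) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<int> > order(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    std::vector<int> &o = order[j];
    for (int i = 0; i < n; ++i) o[i] = i;
    std::stable_sort(o.begin(), o.end(),
                     [&](int a, int b) { return X(a, j) < X(b, j); });
  }
  std::vector<double> margin(n, 0.0), grad(n), hess(n);
  std::vector<char> in_node(n, 0);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  List trees(nrounds);
  for (int m = 0; m < nrounds; ++m) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-margin[i]));
      grad[i] = pr - y[i];
      hess[i] = std::max(pr * (1.0 - pr), 1e-16);
    }
    Tree t;
    build_node(X, order, grad, hess, in_node, all, 0, max_depth, min_leaf,
               min_gain, t);
    for (int i = 0; i < n; ++i)
      margin[i] += learning_rate * tree_predict(t, X, i);
    trees[m] = tree_to_list(t);
  }
  return List::create(_["trees"] = trees,
                      _["learning_rate"] = learning_rate,
                      _["n_features"] = p);
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  double lr = model["learning_rate"];
  const int n = X.nrow();
  NumericVector margin(n);
  for (int m = 0; m < trees.size(); ++m) {
    Tree t = tree_from_list(trees[m]);
    for (int i = 0; i < n; ++i) margin[i] += lr * tree_predict(t, X, i);
  }
  return margin;
}

// expected tree output when features in S follow x and the rest are
// marginalized by training cover (path-dependent expectation)
static double cond_exp(const Tree &t, int id, const NumericMatrix &X, int row,
                       const std::vector<char> &inS) {
  int f = t.feature[id];
  if (f < 0) return t.value[id];
  if (inS[f])
    return cond_exp(t, (X(row, f) < t.threshold[id]) ? t.left[id] : t.right[id],
                    X, row, inS);
  int l = t.left[id], r = t.right[id];
  double cl = t.cover[l], cr = t.cover[r];
  return (cl * cond_exp(t, l, X, row, inS) +
          cr * cond_exp(t, r, X, row, inS)) / (cl + cr);
}

// [[Rcpp::export(name = ".gbt_shap_cpp")]]
NumericMatrix gbt_shap_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  double lr = model["learning_rate"];
  const int n = X.nrow(), p = model["n_features"];
  NumericMatrix phi(n, p);
  std::vector<char> inS(p, 0);
  for (int m = 0; m < trees.size(); ++m) {
    Tree t = tree_from_list(trees[m]);
    std::vector<int> U;
    for (size_t id = 0; id < t.feature.size(); ++id)
      if (t.feature[id] >= 0 &&
          std::find(U.begin(), U.end(), t.feature[id]) == U.end())
        U.push_back(t.feature[id]);
    const int u = (int)U.size();
    if (u == 0) continue;
    std::vector<double> fact(u + 1, 1.0);
    for (int k = 1; k <= u; ++k) fact[k] = fact[k - 1] * k;
    for (int row = 0; row < n; ++row) {
      // v(S) for all subsets of U, bitmask-indexed
      std::vector<double> v(1 << u);
      for (int mask = 0; mask < (1 << u); ++mask) {
        for (int k = 0; k < u; ++k) inS[U[k]] = (mask >> k) & 1;
        v[mask] = cond_exp(t, 0, X, row, inS);
        for (int k = 0; k < u; ++k) inS[U[k]] = 0;
      }
      for (int k = 0; k < u; ++k) {
        double contrib = 0;
        for (int mask = 0; mask < (1 << u); ++mask) {
          if ((mask >> k) & 1) continue;
          int s = 0;
          for (int b = 0; b < u; ++b) s += (mask >> b) & 1;
          double w = fact[s] * fact[u - s - 1] / fact[u];
          contrib += w * (v[mask | (1 << k)] - v[mask]);
        }
        phi(row, U[k]) += lr * contrib;
      }
    }
  }
  return phi;
}
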