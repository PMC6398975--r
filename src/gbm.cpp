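// A small gradient-boosted tree learner (Bernoulli deviance, logit link)
// used as the sensitivity-analysis emulator: trees with a fixed number of
// greedy best-first splits ("tree complexity"), shrinkage, stochastic bag
// fraction, Newton leaf values, and split-gain relative influence. The
// staged k-fold cross-validation used to choose the number of trees is run
// in lockstep across folds so fitting stops soon after the held-out
// deviance bottoms out.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat, left, right;   // feat = -1 for leaves
  std::vector<double> thr, val;
};

inline double sigmoid(double f) { return 1.0 / (1.0 + std::exp(-f)); }

inline int tree_leaf(const Tree& t, const double* x, int n, int p, int row) {
  int node = 0;
  while (t.feat[node] >= 0)
    node = x[(size_t)t.feat[node] * n + row] <= t.thr[node]
             ? t.left[node] : t.right[node];
  return node;
}

struct Fitter {
  int n = 0, p = 0;
  std::vector<double> X;          // column-major copy of training rows
  std::vector<double> y, f;
  double f0 = 0;
  int nsplits = 5, minnode = 10;
  double shrink = 0.01, bagfrac = 0.75;
  std::vector<std::vector<int> > sorted;  // per feature: rows by value
  std::vector<Tree> trees;
  std::vector<double> importance;

  void init(const NumericMatrix& Xall, const NumericVector& yall,
            const std::vector<int>& rows, int nsplits_, double shrink_,
            double bagfrac_, int minnode_) {
    n = (int)rows.size(); p = Xall.ncol();
    nsplits = nsplits_; shrink = shrink_; bagfrac = bagfrac_;
    minnode = minnode_;
    X.resize((size_t)n * p); y.resize(n);
    for (int i = 0; i < n; ++i) y[i] = yall[rows[i]];
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < n; ++i)
        X[(size_t)j * n + i] = Xall(rows[i], j);
    double ybar = 0;
    for (int i = 0; i < n; ++i) ybar += y[i];
    ybar /= n;
    ybar = std::min(std::max(ybar, 1e-6), 1 - 1e-6);
    f0 = std::log(ybar / (1 - ybar));
    f.assign(n, f0);
    importance.assign(p, 0.0);
    sorted.assign(p, std::vector<int>());
    for (int j = 0; j < p; ++j) {
      sorted[j].resize(n);
      for (int i = 0; i < n; ++i) sorted[j][i] = i;
      const double* col = &X[(size_t)j * n];
      std::sort(sorted[j].begin(), sorted[j].end(),
                [col](int a, int b) { return col[a] < col[b]; });
    }
  }

  void grow_tree() {
    // bag
    const int nb = std::max(minnode * 2, (int)std::floor(bagfrac * n));
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < nb; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
    }
    std::vector<int> leaf_of(n, -1);
    for (int i = 0; i < nb; ++i) leaf_of[idx[i]] = 0;

    std::vector<double> r(n), h(n);
    for (int i = 0; i < n; ++i) {
      double pr = sigmoid(f[i]);
      r[i] = y[i] - pr;
      h[i] = std::max(pr * (1 - pr), 1e-12);
    }

    Tree t;
    t.feat.push_back(-1); t.thr.push_back(0);
    t.left.push_back(-1); t.right.push_back(-1); t.val.push_back(0);
    int n_leaves = 1;

    // per-leaf totals
    std::vector<double> tot_r(1, 0), tot_h(1, 0);
    std::vector<int> tot_n(1, 0);
    for (int i = 0; i < nb; ++i) {
      tot_r[0] += r[idx[i]]; tot_h[0] += h[idx[i]]; ++tot_n[0];
    }

    for (int round = 0; round < nsplits; ++round) {
      const int L = n_leaves;
      std::vector<double> best_gain(L, 0), best_thr(L, 0);
      std::vector<int> best_feat(L, -1);
      std::vector<double> sl_r(L), sl_h(L), last_x(L);
      std::vector<int> sl_n(L);
      // map leaf id (node index) -> dense 0..L-1
      std::vector<int> leaf_nodes;
      std::vector<int> dense(t.feat.size(), -1);
      for (size_t nd = 0; nd < t.feat.size(); ++nd)
        if (t.feat[nd] == -1) {
          dense[nd] = (int)leaf_nodes.size();
          leaf_nodes.push_back((int)nd);
        }
      for (int j = 0; j < p; ++j) {
        const double* col = &X[(size_t)j * n];
        std::fill(sl_r.begin(), sl_r.end(), 0.0);
        std::fill(sl_h.begin(), sl_h.end(), 0.0);
        std::fill(sl_n.begin(), sl_n.end(), 0);
        std::fill(last_x.begin(), last_x.end(), R_NegInf);
        for (int k = 0; k < n; ++k) {
          const int i = sorted[j][k];
          if (leaf_of[i] < 0) continue;
          const int dl = dense[leaf_of[i]];
          const double xv = col[i];
          const int li = leaf_nodes[dl];
          // candidate split between previous member and this one
          if (sl_n[dl] >= minnode && tot_n[li] - sl_n[dl] >= minnode &&
              xv > last_x[dl]) {
            const double rr = tot_r[li] - sl_r[dl];
            const double rh = tot_h[li] - sl_h[dl];
            const double gain = sl_r[dl] * sl_r[dl] / sl_h[dl] +
                                rr * rr / rh -
                                tot_r[li] * tot_r[li] / tot_h[li];
            if (gain > best_gain[dl]) {
              best_gain[dl] = gain;
              best_feat[dl] = j;
              best_thr[dl] = 0.5 * (last_x[dl] + xv);
            }
          }
          sl_r[dl] += r[i]; sl_h[dl] += h[i]; ++sl_n[dl];
          last_x[dl] = xv;
        }
      }
      // split the leaf with the largest gain
      int pick = -1; double g = 0;
      for (int dl = 0; dl < L; ++dl)
        if (best_feat[dl] >= 0 && best_gain[dl] > g) {
          g = best_gain[dl]; pick = dl;
        }
      if (pick < 0) break;
      const int node = leaf_nodes[pick];
      const int jf = best_feat[pick];
      const double thr = best_thr[pick];
      importance[jf] += g;
      const int lc = (int)t.feat.size(), rc = lc + 1;
      t.feat[node] = jf; t.thr[node] = thr;
      t.left[node] = lc; t.right[node] = rc;
      for (int c = 0; c < 2; ++c) {
        t.feat.push_back(-1); t.thr.push_back(0);
        t.left.push_back(-1); t.right.push_back(-1); t.val.push_back(0);
        tot_r.push_back(0); tot_h.push_back(0); tot_n.push_back(0);
      }
      const double* col = &X[(size_t)jf * n];
      for (int i = 0; i < n; ++i)
        if (leaf_of[i] == node) {
          const int child = col[i] <= thr ? lc : rc;
          leaf_of[i] = child;
          tot_r[child] += r[i]; tot_h[child] += h[i]; ++tot_n[child];
        }
      ++n_leaves;
    }

    for (size_t nd = 0; nd < t.feat.size(); ++nd)
      if (t.feat[nd] == -1)
        t.val[nd] = tot_n[nd] > 0 ? tot_r[nd] / (tot_h[nd] + 1e-12) : 0.0;

    // update f for all samples (in- and out-of-bag)
    for (int i = 0; i < n; ++i)
      f[i] += shrink * t.val[tree_leaf(t, X.data(), n, p, i)];
    trees.push_back(std::move(t));
  }
};

List export_model(const Fitter& fit, int n_trees) {
  List tl(n_trees);
  for (int k = 0; k < n_trees; ++k) {
    const Tree& t = fit.trees[k];
    tl[k] = List::create(
      _["feat"] = IntegerVector(t.feat.begin(), t.feat.end()),
      _["thr"] = NumericVector(t.thr.begin(), t.thr.end()),
      _["left"] = IntegerVector(t.left.begin(), t.left.end()),
      _["right"] = IntegerVector(t.right.begin(), t.right.end()),
      _["val"] = NumericVector(t.val.begin(), t.val.end()));
  }
  return List::create(
    _["f0"] = fit.f0, _["shrinkage"] = fit.shrink,
    _["n_trees"] = n_trees, _["trees"] = tl,
    _["importance"] = NumericVector(fit.importance.begin(),
                                    fit.importance.end()));
}

Tree tree_from_list(const List& tl) {
  Tree t;
  t.feat = as<std::vector<int> >(tl["feat"]);
  t.thr = as<std::vector<double> >(tl["thr"]);
  t.left = as<std::vector<int> >(tl["left"]);
  t.right = as<std::vector<int> >(tl["right"]);
  t.val = as<std::vector<double> >(tl["val"]);
  return t;
}

double pooled_deviance(const std::vector<double>& fhat,
                       const std::vector<double>& yv) {
  double dev = 0;
  for (size_t i = 0; i < yv.size(); ++i) {
    double pr = std::min(std::max(sigmoid(fhat[i]), 1e-12), 1 - 1e-12);
    dev += yv[i] * std::log(pr) + (1 - yv[i]) * std::log(1 - pr);
  }
  return -2.0 * dev / (double)yv.size();
}

}  // namespace

// [[Rcpp::export]]
List cpp_gbm_fit(NumericMatrix X, NumericVector y, int n_trees, int n_splits,
                 double shrinkage, double bag_fraction, int min_node) {
  Fitter fit;
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  fit.init(X, y, rows, n_splits, shrinkage, bag_fraction, min_node);
  for (int k = 0; k < n_trees; ++k) fit.grow_tree();
  return export_model(fit, n_trees);
}

// [[Rcpp::export]]
NumericVector cpp_gbm_predict_link(List model, NumericMatrix X,
                                   int n_trees) {
  const int n = X.nrow(), p = X.ncol();
  const double shrink = as<double>(model["shrinkage"]);
  List tl = model["trees"];
  if (n_trees < 0 || n_trees > tl.size()) n_trees = tl.size();
  std::vector<double> Xc((size_t)n * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) Xc[(size_t)j * n + i] = X(i, j);
  NumericVector out(n, as<double>(model["f0"]));
  for (int k = 0; k < n_trees; ++k) {
    Tree t = tree_from_list(tl[k]);
    for (int i = 0; i < n; ++i)
      out[i] += shrink * t.val[tree_leaf(t, Xc.data(), n, p, i)];
  }
  return out;
}

// Lockstep k-fold staged CV: grow `step` trees per fold per stage, track the
// pooled held-out deviance, stop once it has not improved for `patience`
// trees (or at max_trees). Returns the deviance curve, the chosen tree
// count, and pooled held-out link predictions at that count.
// [[Rcpp::export]]
List cpp_gbm_cv(NumericMatrix X, NumericVector y, IntegerVector fold_id,
                int max_trees, int step, int patience, int n_splits,
                double shrinkage, double bag_fraction, int min_node) {
  const int n = X.nrow();
  int K = 0;
  for (int i = 0; i < n; ++i) K = std::max(K, fold_id[i] + 1);
  std::vector<Fitter> fits(K);
  std::vector<std::vector<int> > test_rows(K);
  std::vector<std::vector<double> > test_f(K);
  for (int k = 0; k < K; ++k) {
    std::vector<int> tr;
    for (int i = 0; i < n; ++i)
      (fold_id[i] == k ? test_rows[k] : tr).push_back(i);
    fits[k].init(X, y, tr, n_splits, shrinkage, bag_fraction, min_node);
    test_f[k].assign(test_rows[k].size(), fits[k].f0);
  }
  // column-major copy of the full X for held-out traversal
  const int p = X.ncol();
  std::vector<double> Xc((size_t)n * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) Xc[(size_t)j * n + i] = X(i, j);

  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> curve, heldout_best;
  std::vector<int> counts;
  std::vector<double> fhat(n);
  double best_dev = R_PosInf;
  int best_count = 0, count = 0;

  while (count < max_trees) {
    for (int k = 0; k < K; ++k) {
      const size_t from = fits[k].trees.size();
      for (int s = 0; s < step; ++s) fits[k].grow_tree();
      for (size_t ti = from; ti < fits[k].trees.size(); ++ti) {
        const Tree& t = fits[k].trees[ti];
        for (size_t m = 0; m < test_rows[k].size(); ++m)
          test_f[k][m] += shrinkage *
            t.val[tree_leaf(t, Xc.data(), n, p, test_rows[k][m])];
      }
    }
    count += step;
    for (int k = 0; k < K; ++k)
      for (size_t m = 0; m < test_rows[k].size(); ++m)
        fhat[test_rows[k][m]] = test_f[k][m];
    const double dev = pooled_deviance(fhat, yv);
    curve.push_back(dev);
    counts.push_back(count);
    if (dev < best_dev) {
      best_dev = dev; best_count = count;
      heldout_best = fhat;
    }
    if (count - best_count >= patience) break;
  }

  return List::create(
    _["n_trees"] = best_count,
    _["cv_deviance"] = best_dev,
    _["counts"] = IntegerVector(counts.begin(), counts.end()),
    _["curve"] = NumericVector(curve.begin(), curve.end()),
    _["heldout_link"] = NumericVector(heldout_best.begin(),
                                      heldout_best.end()));
}
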