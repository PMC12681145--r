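// Stagewise gradient boosting of shallow regression trees with Bernoulli loss.
// Trees are grown best-first with a fixed number of splits (the "tree
// complexity"), leaf values are single Newton steps on the bagged rows, and
// the whole ensemble state lives behind an external pointer so that R can
// grow folds in lockstep while tracking held-out deviance per tree.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double x) {
  // numerically stable log(1 + exp(x))
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct Node {
  int var;      // -1 for leaf
  double split; // x <= split goes left
  int left, right;
  double value; // leaf prediction, already scaled by the learning rate
};

struct Split {
  int var = -1;
  double split = 0.0;
  double gain = -1.0; // SSE reduction; < 0 means no valid split
};

class Booster {
public:
  int n, p;
  std::vector<double> X;  // column-major n x p
  std::vector<int> y;
  std::vector<std::vector<int>> order; // per variable, rows sorted by value
  std::vector<double> F;               // current link-scale fit, all rows
  double init_f;
  // optional validation set
  int nv;
  std::vector<double> Xv;
  std::vector<int> yv;
  std::vector<double> Fv;
  std::vector<double> valid_dev; // mean Bernoulli deviance after each tree
  // hyperparameters
  double lr, bag_frac;
  int n_splits, min_obs;
  std::mt19937 rng;
  // model
  std::vector<std::vector<Node>> trees;
  std::vector<double> var_gain; // accumulated split-gain per variable

  // scratch
  std::vector<double> z, w;     // gradient and hessian, bagged rows only
  std::vector<char> in_bag;
  std::vector<int> node_of;     // node index per row, -1 if not in bag

  Booster(NumericMatrix Xm, IntegerVector ym, double lr_, int n_splits_,
          double bag_frac_, int min_obs_, int seed,
          NumericMatrix Xvm, IntegerVector yvm)
      : n(Xm.nrow()), p(Xm.ncol()), lr(lr_), bag_frac(bag_frac_),
        n_splits(n_splits_), min_obs(min_obs_), rng(seed) {
    X.assign(Xm.begin(), Xm.end());
    y.assign(ym.begin(), ym.end());
    double ybar = 0.0;
    for (int i = 0; i < n; ++i) ybar += y[i];
    ybar /= n;
    ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
    init_f = std::log(ybar / (1.0 - ybar));
    F.assign(n, init_f);
    nv = Xvm.nrow();
    if (nv > 0) {
      Xv.assign(Xvm.begin(), Xvm.end());
      yv.assign(yvm.begin(), yvm.end());
      Fv.assign(nv, init_f);
    }
    order.resize(p);
    std::vector<std::pair<double, int>> tmp(n);
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i) tmp[i] = {X[(size_t)j * n + i], i};
      std::sort(tmp.begin(), tmp.end());
      order[j].resize(n);
      for (int i = 0; i < n; ++i) order[j][i] = tmp[i].second;
    }
    var_gain.assign(p, 0.0);
    z.assign(n, 0.0);
    w.assign(n, 0.0);
    in_bag.assign(n, 0);
    node_of.assign(n, -1);
  }

  double xval(int i, int j) const { return X[(size_t)j * n + i]; }

  // Flat arena of per-node sorted row lists: variable j occupies
  // arena[j*bag_n .. (j+1)*bag_n); every node is the same contiguous
  // (offset, count) subrange in each variable's segment, kept consistent by
  // stable in-place partitioning.
  std::vector<int> arena, part_tmp;
  int arena_bag_n = 0;

  Split best_split(int off, int cnt) {
    Split best;
    int n_leaf = cnt;
    if (n_leaf < 2 * min_obs) return best;
    double sum_tot = 0.0;
    {
      const int* r0 = &arena[off];
      for (int k = 0; k < cnt; ++k) sum_tot += z[r0[k]];
    }
    for (int j = 0; j < p; ++j) {
      double sum_l = 0.0;
      int n_l = 0;
      double prev_x = -std::numeric_limits<double>::infinity();
      bool have_prev = false;
      const int* rj = &arena[(size_t)j * arena_bag_n + off];
      for (int k = 0; k < cnt; ++k) {
        int i = rj[k];
        double xv = xval(i, j);
        if (have_prev && xv > prev_x && n_l >= min_obs &&
            (n_leaf - n_l) >= min_obs) {
          double sum_r = sum_tot - sum_l;
          double gain = sum_l * sum_l / n_l +
                        sum_r * sum_r / (n_leaf - n_l) -
                        sum_tot * sum_tot / n_leaf;
          if (gain > best.gain) {
            best.gain = gain;
            best.var = j;
            best.split = 0.5 * (prev_x + xv);
          }
        }
        sum_l += z[i];
        n_l += 1;
        prev_x = xv;
        have_prev = true;
      }
    }
    return best;
  }

  void grow(int n_new) {
    int bag_n = std::max(1, (int)std::floor(bag_frac * n));
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = i;
    for (int t = 0; t < n_new; ++t) {
      // bag: partial Fisher-Yates without replacement
      std::fill(in_bag.begin(), in_bag.end(), 0);
      for (int i = 0; i < bag_n; ++i) {
        std::uniform_int_distribution<int> u(i, n - 1);
        std::swap(rows[i], rows[u(rng)]);
        in_bag[rows[i]] = 1;
      }
      // gradients on bagged rows
      for (int i = 0; i < n; ++i) {
        if (in_bag[i]) {
          double pi = 1.0 / (1.0 + std::exp(-F[i]));
          z[i] = y[i] - pi;
          w[i] = pi * (1.0 - pi);
          node_of[i] = 0;
        } else {
          node_of[i] = -1;
        }
      }
      std::vector<Node> tree;
      tree.push_back({-1, 0.0, -1, -1, 0.0}); // root as leaf
      arena_bag_n = bag_n;
      arena.resize((size_t)p * bag_n);
      part_tmp.resize(bag_n);
      for (int j = 0; j < p; ++j) {
        int* seg = &arena[(size_t)j * bag_n];
        int k = 0;
        for (int i : order[j])
          if (in_bag[i]) seg[k++] = i;
      }
      std::vector<int> node_off{0}, node_cnt{bag_n};
      std::vector<Split> leaf_best{best_split(0, bag_n)};
      for (int s = 0; s < n_splits; ++s) {
        int pick = -1;
        double g = 0.0;
        for (size_t L = 0; L < leaf_best.size(); ++L)
          if (tree[L].var == -1 && leaf_best[L].gain > g) {
            g = leaf_best[L].gain;
            pick = (int)L;
          }
        if (pick < 0) break;
        Split sp = leaf_best[pick];
        int li = (int)tree.size(), ri = li + 1;
        tree.push_back({-1, 0.0, -1, -1, 0.0});
        tree.push_back({-1, 0.0, -1, -1, 0.0});
        tree[pick].var = sp.var;
        tree[pick].split = sp.split;
        tree[pick].left = li;
        tree[pick].right = ri;
        var_gain[sp.var] += sp.gain;
        // stable in-place partition of the node's subrange in every segment
        int off = node_off[pick], cnt = node_cnt[pick];
        int nl = 0;
        for (int j = 0; j < p; ++j) {
          int* seg = &arena[(size_t)j * bag_n + off];
          int kl = 0, kr = 0;
          for (int k = 0; k < cnt; ++k) {
            int i = seg[k];
            if (xval(i, sp.var) <= sp.split) {
              seg[kl++] = i;
              if (j == 0) node_of[i] = li;
            } else {
              part_tmp[kr++] = i;
              if (j == 0) node_of[i] = ri;
            }
          }
          std::copy(part_tmp.begin(), part_tmp.begin() + kr, seg + kl);
          nl = kl;
        }
        node_off.push_back(off); node_cnt.push_back(nl);
        node_off.push_back(off + nl); node_cnt.push_back(cnt - nl);
        leaf_best.push_back(best_split(off, nl));
        leaf_best.push_back(best_split(off + nl, cnt - nl));
        leaf_best[pick] = Split();
      }
      // Newton leaf values
      std::vector<double> sum_z(tree.size(), 0.0), sum_w(tree.size(), 0.0);
      for (int i = 0; i < n; ++i) {
        if (node_of[i] < 0) continue;
        sum_z[node_of[i]] += z[i];
        sum_w[node_of[i]] += w[i];
      }
      for (size_t L = 0; L < tree.size(); ++L) {
        if (tree[L].var != -1) continue;
        double v = (sum_w[L] > 1e-10) ? sum_z[L] / sum_w[L] : 0.0;
        tree[L].value = lr * v;
      }
      // update fits (all training rows, plus validation)
      for (int i = 0; i < n; ++i) F[i] += predict_tree(tree, &X[0], n, i);
      if (nv > 0) {
        double dev = 0.0;
        for (int i = 0; i < nv; ++i) {
          Fv[i] += predict_tree(tree, &Xv[0], nv, i);
          dev += -2.0 * (yv[i] * Fv[i] - softplus(Fv[i]));
        }
        valid_dev.push_back(dev / nv);
      }
      trees.push_back(std::move(tree));
    }
  }

  static double predict_tree(const std::vector<Node>& tree, const double* Xp,
                             int nrow, int i) {
    int node = 0;
    while (tree[node].var != -1) {
      double xv = Xp[(size_t)tree[node].var * nrow + i];
      node = (xv <= tree[node].split) ? tree[node].left : tree[node].right;
    }
    return tree[node].value;
  }
};

// [[Rcpp::export]]
SEXP booster_create(NumericMatrix X, IntegerVector y, double lr, int n_splits,
                    double bag_frac, int min_obs, int seed,
                    NumericMatrix Xvalid, IntegerVector yvalid) {
  Booster* b = new Booster(X, y, lr, n_splits, bag_frac, min_obs, seed,
                           Xvalid, yvalid);
  XPtr<Booster> ptr(b, true);
  return ptr;
}

// [[Rcpp::export]]
void booster_grow(SEXP ptr, int n_new) {
  XPtr<Booster> b(ptr);
  b->grow(n_new);
}

// [[Rcpp::export]]
int booster_n_trees(SEXP ptr) {
  XPtr<Booster> b(ptr);
  return (int)b->trees.size();
}

// [[Rcpp::export]]
NumericVector booster_valid_dev(SEXP ptr) {
  XPtr<Booster> b(ptr);
  return wrap(b->valid_dev);
}

// [[Rcpp::export]]
NumericVector booster_train_fit(SEXP ptr) {
  XPtr<Booster> b(ptr);
  return wrap(b->F);
}

// [[Rcpp::export]]
List booster_export(SEXP ptr, int n_trees) {
  XPtr<Booster> b(ptr);
  n_trees = std::min(n_trees, (int)b->trees.size());
  int total = 0;
  for (int t = 0; t < n_trees; ++t) total += (int)b->trees[t].size();
  NumericMatrix nodes(total, 5); // var, split, left, right, value
  IntegerVector tree_start(n_trees + 1);
  int row = 0;
  for (int t = 0; t < n_trees; ++t) {
    tree_start[t] = row;
    for (const Node& nd : b->trees[t]) {
      nodes(row, 0) = nd.var;
      nodes(row, 1) = nd.split;
      nodes(row, 2) = nd.left;
      nodes(row, 3) = nd.right;
      nodes(row, 4) = nd.value;
      ++row;
    }
  }
  tree_start[n_trees] = row;
  return List::create(_["nodes"] = nodes, _["tree_start"] = tree_start,
                      _["init_f"] = b->init_f,
                      _["var_gain"] = wrap(b->var_gain));
}

// [[Rcpp::export]]
NumericVector boost_predict_link(NumericMatrix nodes, IntegerVector tree_start,
                                 double init_f, NumericMatrix X, int n_trees) {
  int n = X.nrow();
  int nt = tree_start.size() - 1;
  if (n_trees > 0 && n_trees < nt) nt = n_trees;
  NumericVector out(n, init_f);
  const double* Xp = X.begin();
  for (int t = 0; t < nt; ++t) {
    int off = tree_start[t];
    for (int i = 0; i < n; ++i) {
      int node = off;
      while ((int)nodes(node, 0) != -1) {
        double xv = Xp[(size_t)((int)nodes(node, 0)) * n + i];
        node = off + ((xv <= nodes(node, 1)) ? (int)nodes(node, 2)
                                             : (int)nodes(node, 3));
      }
      out[i] += nodes(node, 4);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector longest_run_rows(LogicalMatrix m) {
  // per-row length of the longest run of TRUE
  int nr = m.nrow(), nc = m.ncol();
  NumericVector best(nr, 0.0);
  std::vector<int> cur(nr, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (m(i, j)) {
        if (++cur[i] > best[i]) best[i] = cur[i];
      } else {
        cur[i] = 0;
      }
    }
  return best;
}
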