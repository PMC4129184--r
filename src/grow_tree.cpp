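#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Recursive deviance-split tree growing for a binary outcome with a fixed
// per-observation offset.  Every node model is an intercept-only logistic
// GLM with the offset held at coefficient one; split goodness is the parent
// deviance minus the summed child deviances.  Kept in C++ because replicate
// studies grow tens of thousands of trees.

static const double ETA_CAP = 30.0;
static const double PROB_EPS = 1e-10;
static const double BETA_CAP = 35.0;

static inline double clampp(double mu) {
  if (mu < PROB_EPS) return PROB_EPS;
  if (mu > 1.0 - PROB_EPS) return 1.0 - PROB_EPS;
  return mu;
}

struct NodeFit {
  double beta;
  double dev;
};

// one pass: deviance, score and information at coefficient b
static void node_stats(const int* y, const double* off,
                       const std::vector<int>& rows,
                       double b, double& dev, double& num, double& den) {
  dev = 0.0; num = 0.0; den = 0.0;
  for (size_t k = 0; k < rows.size(); ++k) {
    int i = rows[k];
    double eta = off[i] + b;
    if (eta > ETA_CAP) eta = ETA_CAP;
    if (eta < -ETA_CAP) eta = -ETA_CAP;
    double mu = clampp(1.0 / (1.0 + std::exp(-eta)));
    num += y[i] - mu;
    den += mu * (1.0 - mu);
    dev += (y[i] == 1) ? -2.0 * std::log(mu) : -2.0 * std::log(1.0 - mu);
  }
}

static NodeFit fit_node(const int* y, const double* off,
                        const std::vector<int>& rows) {
  double b = 0.0, dev, num, den;
  node_stats(y, off, rows, b, dev, num, den);
  for (int it = 0; it < 50; ++it) {
    if (den < 1e-12) break;
    double bn = b + num / den;
    if (bn > BETA_CAP) bn = BETA_CAP;
    if (bn < -BETA_CAP) bn = -BETA_CAP;
    double devn, numn, denn;
    node_stats(y, off, rows, bn, devn, numn, denn);
    int h = 0;
    while (devn > dev + 1e-12 && h < 20) {      // step halving, rare
      bn = 0.5 * (b + bn);
      node_stats(y, off, rows, bn, devn, numn, denn);
      ++h;
    }
    double rel = std::fabs(dev - devn) / (std::fabs(devn) + 0.1);
    b = bn; dev = devn; num = numn; den = denn;
    if (rel < 1e-8) break;
  }
  NodeFit f; f.beta = b; f.dev = dev;
  return f;
}

// subsets of {0,..,L-1} that contain level 0, proper, in lexicographic
// order of their sorted element lists (depth-first extension order)
static void lex_subsets(int L, std::vector<int>& masks) {
  // iterative DFS: stack of (mask, last element added)
  std::vector<std::pair<int,int> > stack;
  stack.push_back(std::make_pair(1, 0));
  while (!stack.empty()) {
    std::pair<int,int> top = stack.back(); stack.pop_back();
    int mask = top.first, last = top.second;
    if (mask != (1 << L) - 1) masks.push_back(mask);
    // push children in reverse so the smallest extension is visited first
    for (int e = L - 1; e > last; --e)
      stack.push_back(std::make_pair(mask | (1 << e), e));
  }
}

struct TreeAcc {
  std::vector<int> parent, left, right, var, is_subset, n;
  std::vector<double> threshold, dev, beta;
  std::vector<int> mask;
  std::vector<int> row_leaf;
  const int* y;
  const double* off;
  const NumericMatrix* Z;
  const int* types;      // 0 ordered, 1 unordered
  const int* nlev;
  int minsize;
  double gain_tol;
};

static int new_node(TreeAcc& a, int parent_id, int nrows, double dv, double bt) {
  a.parent.push_back(parent_id);
  a.left.push_back(NA_INTEGER);
  a.right.push_back(NA_INTEGER);
  a.var.push_back(NA_INTEGER);
  a.is_subset.push_back(0);
  a.threshold.push_back(NA_REAL);
  a.mask.push_back(NA_INTEGER);
  a.n.push_back(nrows);
  a.dev.push_back(dv);
  a.beta.push_back(bt);
  return (int) a.parent.size();   // 1-based id
}

static int grow(TreeAcc& a, std::vector<int>& rows, int parent_id) {
  NodeFit pf = fit_node(a.y, a.off, rows);
  int id = new_node(a, parent_id, (int) rows.size(), pf.dev, pf.beta);

  int p = a.Z->ncol();
  double best_gain = a.gain_tol;
  int best_var = -1, best_mask = 0, best_subset = 0;
  double best_thr = 0.0;

  if ((int) rows.size() >= 2 * a.minsize && p > 0) {
    std::vector<int> lrows, rrows;
    for (int v = 0; v < p; ++v) {
      const double* zc = &(*a.Z)(0, v);
      if (a.types[v] == 0) {
        // ordered: thresholds at midpoints of distinct observed values
        std::vector<double> vals;
        vals.reserve(rows.size());
        for (size_t k = 0; k < rows.size(); ++k) vals.push_back(zc[rows[k]]);
        std::sort(vals.begin(), vals.end());
        vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
        for (size_t t = 0; t + 1 < vals.size(); ++t) {
          double thr = 0.5 * (vals[t] + vals[t + 1]);
          lrows.clear(); rrows.clear();
          for (size_t k = 0; k < rows.size(); ++k) {
            int i = rows[k];
            if (zc[i] <= thr) lrows.push_back(i); else rrows.push_back(i);
          }
          if ((int) lrows.size() < a.minsize || (int) rrows.size() < a.minsize)
            continue;
          NodeFit lf = fit_node(a.y, a.off, lrows);
          NodeFit rf = fit_node(a.y, a.off, rrows);
          double gain = pf.dev - lf.dev - rf.dev;
          if (gain > best_gain) {
            best_gain = gain; best_var = v; best_thr = thr; best_subset = 0;
          }
        }
      } else {
        int L = a.nlev[v];
        std::vector<int> masks;
        lex_subsets(L, masks);
        for (size_t mi = 0; mi < masks.size(); ++mi) {
          int mask = masks[mi];
          lrows.clear(); rrows.clear();
          for (size_t k = 0; k < rows.size(); ++k) {
            int i = rows[k];
            int lev = (int) zc[i];
            if (mask & (1 << lev)) lrows.push_back(i); else rrows.push_back(i);
          }
          if ((int) lrows.size() < a.minsize || (int) rrows.size() < a.minsize)
            continue;
          NodeFit lf = fit_node(a.y, a.off, lrows);
          NodeFit rf = fit_node(a.y, a.off, rrows);
          double gain = pf.dev - lf.dev - rf.dev;
          if (gain > best_gain) {
            best_gain = gain; best_var = v; best_mask = mask; best_subset = 1;
          }
        }
      }
    }
  }

  if (best_var < 0) {
    for (size_t k = 0; k < rows.size(); ++k) a.row_leaf[rows[k]] = id;
    return id;
  }

  a.var[id - 1] = best_var + 1;
  a.is_subset[id - 1] = best_subset;
  if (best_subset) a.mask[id - 1] = best_mask; else a.threshold[id - 1] = best_thr;

  std::vector<int> lrows, rrows;
  const double* zc = &(*a.Z)(0, best_var);
  for (size_t k = 0; k < rows.size(); ++k) {
    int i = rows[k];
    bool goleft = best_subset ? ((best_mask >> (int) zc[i]) & 1) : (zc[i] <= best_thr);
    if (goleft) lrows.push_back(i); else rrows.push_back(i);
  }
  rows.clear(); rows.shrink_to_fit();
  int lid = grow(a, lrows, id);
  a.left[id - 1] = lid;
  int rid = grow(a, rrows, id);
  a.right[id - 1] = rid;
  return id;
}

// [[Rcpp::export]]
List cpp_grow_tree(IntegerVector y, NumericMatrix Z, NumericVector offset,
                   IntegerVector types, IntegerVector nlev,
                   int min_node_size, double gain_tol) {
  int n = y.size();
  TreeAcc a;
  a.y = y.begin();
  a.off = offset.begin();
  a.Z = &Z;
  a.types = types.begin();
  a.nlev = nlev.begin();
  a.minsize = min_node_size;
  a.gain_tol = gain_tol;
  a.row_leaf.assign(n, NA_INTEGER);

  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  grow(a, rows, NA_INTEGER);

  return List::create(
    _["parent"] = wrap(a.parent),
    _["left"] = wrap(a.left),
    _["right"] = wrap(a.right),
    _["var"] = wrap(a.var),
    _["is_subset"] = wrap(a.is_subset),
    _["threshold"] = wrap(a.threshold),
    _["mask"] = wrap(a.mask),
    _["n"] = wrap(a.n),
    _["deviance"] = wrap(a.dev),
    _["beta"] = wrap(a.beta),
    _["row_leaf"] = wrap(a.row_leaf));
}

// [[Rcpp::export]]
List cpp_node_fit(IntegerVector y, NumericVector offset, IntegerVector rows1) {
  std::vector<int> rows(rows1.size());
  for (int k = 0; k < rows1.size(); ++k) rows[k] = rows1[k] - 1;
  NodeFit f = fit_node(y.begin(), offset.begin(), rows);
  return List::create(_["beta"] = f.beta, _["deviance"] = f.dev);
}
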