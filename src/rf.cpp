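// Compact random-forest classifier (binary, CART/Gini) with out-of-bag
// permutation importance.  Exists because no tree-ensemble package is
// available in the target library; uses R's RNG so results are fully
// reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> thresh; // go left when x <= thresh
  std::vector<int> left, right, pred;
};

inline int rand_int(int n) {  // uniform on 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

void build_node(Tree &tr, const NumericMatrix &X, const IntegerVector &y,
                std::vector<int> &idx, int lo, int hi, int mtry,
                int min_node, std::vector<int> &feat_pool,
                std::vector<std::pair<double, int> > &buf) {
  int node = (int)tr.feature.size();
  tr.feature.push_back(-1);
  tr.thresh.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  int n = hi - lo, n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  tr.pred.push_back(2 * n1 >= n ? 1 : 0);
  if (n1 == 0 || n1 == n || n <= min_node) return;

  int p = X.ncol();
  double parent = (double)n1 * (n - n1) / n;  // n * gini / 2 form
  double best_gain = 1e-12;
  int best_f = -1;
  double best_t = 0.0;
  // sample mtry features without replacement (partial Fisher-Yates)
  for (int j = 0; j < p; ++j) feat_pool[j] = j;
  for (int m = 0; m < mtry; ++m) {
    int r = m + rand_int(p - m);
    std::swap(feat_pool[m], feat_pool[r]);
    int f = feat_pool[m];
    buf.clear();
    for (int i = lo; i < hi; ++i)
      buf.push_back(std::make_pair(X(idx[i], f), y[idx[i]]));
    std::sort(buf.begin(), buf.end());
    if (buf.front().first == buf.back().first) continue;
    int nl = 0, n1l = 0;
    for (int i = 0; i + 1 < n; ++i) {
      nl++; n1l += buf[i].second;
      if (buf[i].first == buf[i + 1].first) continue;
      int nr = n - nl, n1r = n1 - n1l;
      double child = (double)n1l * (nl - n1l) / nl +
                     (double)n1r * (nr - n1r) / nr;
      double gain = parent - child;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_t = 0.5 * (buf[i].first + buf[i + 1].first);
      }
    }
  }
  if (best_f < 0) return;
  // partition idx[lo..hi) by the chosen split
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_t) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return;  // numeric ties; give up
  tr.feature[node] = best_f;
  tr.thresh[node] = best_t;
  tr.left[node] = (int)tr.feature.size();
  build_node(tr, X, y, idx, lo, mid, mtry, min_node, feat_pool, buf);
  tr.right[node] = (int)tr.feature.size();
  build_node(tr, X, y, idx, mid, hi, mtry, min_node, feat_pool, buf);
}

// Predict one row; when perm_f >= 0, feature perm_f reads from row
// perm_row instead (column-permutation trick for importance).
inline int predict_row(const Tree &tr, const NumericMatrix &X, int row,
                       int perm_f, int perm_row) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    int f = tr.feature[node];
    double v = (f == perm_f) ? X(perm_row, f) : X(row, f);
    node = (v <= tr.thresh[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.pred[node];
}

}  // namespace

// [[Rcpp::export(name = ".rfImportanceCpp")]]
List rf_importance(NumericMatrix X, IntegerVector y, int num_trees,
                   int mtry, int min_node, int n_perm, int balanced) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("label length mismatch");
  int n1 = 0;
  for (int i = 0; i < n; ++i) {
    if (y[i] != 0 && y[i] != 1) stop("labels must be 0/1");
    n1 += y[i];
  }
  if (n1 == 0 || n1 == n) stop("both classes must be present");
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  NumericVector importance(p);
  std::vector<double> imp_n(p, 0.0);
  double oob_acc_sum = 0.0;
  int oob_trees = 0;
  std::vector<int> idx, oob, perm, feat_pool(p), pos, neg;
  for (int i = 0; i < n; ++i) (y[i] ? pos : neg).push_back(i);
  // balanced mode: Balanced Random Forest sampling -- bootstrap (with
  // replacement) the minority-class size from EACH class, so trees see
  // balanced data while ~37% of each class stays out-of-bag
  int nmin = (int)std::min(pos.size(), neg.size());
  std::vector<char> inbag(n);
  std::vector<std::pair<double, int> > buf;
  buf.reserve(n);

  for (int t = 0; t < num_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    if (balanced) {
      idx.clear();
      std::vector<int> *cls[2] = {&neg, &pos};
      for (int c = 0; c < 2; ++c) {
        const std::vector<int> &pool = *cls[c];
        for (int m = 0; m < nmin; ++m) {
          int k = pool[rand_int((int)pool.size())];
          idx.push_back(k);
          inbag[k] = 1;
        }
      }
    } else {
      idx.resize(n);
      for (int i = 0; i < n; ++i) {
        int k = rand_int(n);
        idx[i] = k;
        inbag[k] = 1;
      }
    }
    Tree tr;
    build_node(tr, X, y, idx, 0, (int)idx.size(), mtry, min_node,
               feat_pool, buf);
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    int m = (int)oob.size();
    if (m < 2) continue;
    int np_oob = 0;
    for (int i = 0; i < m; ++i) np_oob += y[oob[i]];
    if (balanced && (np_oob == 0 || np_oob == m)) continue;
    oob_trees++;
    // metric: plain accuracy, or balanced accuracy (mean of per-class
    // accuracies) in balanced mode so the rare class is not drowned out
    double metric_den0 = m - np_oob, metric_den1 = np_oob;
    int c0 = 0, c1 = 0;
    for (int i = 0; i < m; ++i) {
      int pr = predict_row(tr, X, oob[i], -1, -1);
      if (y[oob[i]]) c1 += (pr == 1); else c0 += (pr == 0);
    }
    double acc = balanced ? 0.5 * (c0 / metric_den0 + c1 / metric_den1)
                          : (double)(c0 + c1) / m;
    oob_acc_sum += acc;
    // only features the tree actually uses can change under permutation
    std::vector<char> used(p, 0);
    for (size_t k = 0; k < tr.feature.size(); ++k)
      if (tr.feature[k] >= 0) used[tr.feature[k]] = 1;
    perm.resize(m);
    for (int f = 0; f < p; ++f) {
      imp_n[f] += 1.0;
      if (!used[f]) continue;      // drop is exactly zero
      double drop = 0.0;
      for (int r = 0; r < n_perm; ++r) {
        for (int i = 0; i < m; ++i) perm[i] = i;
        for (int i = m - 1; i > 0; --i)
          std::swap(perm[i], perm[rand_int(i + 1)]);
        int p0 = 0, p1 = 0;
        for (int i = 0; i < m; ++i) {
          int pr = predict_row(tr, X, oob[i], f, oob[perm[i]]);
          if (y[oob[i]]) p1 += (pr == 1); else p0 += (pr == 0);
        }
        double pacc = balanced
          ? 0.5 * (p0 / metric_den0 + p1 / metric_den1)
          : (double)(p0 + p1) / m;
        drop += acc - pacc;
      }
      importance[f] += drop / n_perm;
    }
  }
  if (oob_trees == 0) stop("no trees with out-of-bag samples");
  for (int f = 0; f < p; ++f)
    if (imp_n[f] > 0) importance[f] /= imp_n[f];
  return List::create(_["importance"] = importance,
                      _["oob_accuracy"] = oob_acc_sum / oob_trees,
                      _["trees_used"] = oob_trees);
}
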