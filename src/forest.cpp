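#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bagged CART forests (regression + classification), the ensemble behind
// run_cv()/run_loso() and the pseudo-site classifier. All randomness comes
// from R's RNG stream so results are reproducible under set.seed().

namespace {

struct TreeData {
  std::vector<int> feature;  // split feature (0-based), -1 => leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;  // leaf mean (regression) or class index
};

inline int rand_int(int n) {
  int k = static_cast<int>(std::floor(unif_rand() * n));
  return k >= n ? n - 1 : k;
}

class Builder {
 public:
  const NumericMatrix& X;
  const NumericVector& y;  // class indices stored as doubles when n_classes > 0
  int n, p, mtry, min_split, n_classes;
  std::vector<int> samples;  // bootstrap indices, partitioned in place
  TreeData tree;
  std::vector<int> feat_pool;
  std::vector<std::pair<double, double> > buf;
  std::vector<int> cntL, cntT;

  Builder(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
          int min_split_, int n_classes_)
      : X(X_), y(y_), n(X_.nrow()), p(X_.ncol()), mtry(mtry_),
        min_split(min_split_), n_classes(n_classes_) {
    feat_pool.resize(p);
    buf.reserve(n);
    if (n_classes > 0) {
      cntL.resize(n_classes);
      cntT.resize(n_classes);
    }
  }

  int new_node() {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(0.0);
    return static_cast<int>(tree.feature.size()) - 1;
  }

  double leaf_value(int start, int end) {
    if (n_classes == 0) {
      double s = 0.0;
      for (int i = start; i < end; ++i) s += y[samples[i]];
      return s / (end - start);
    }
    std::fill(cntT.begin(), cntT.end(), 0);
    for (int i = start; i < end; ++i) ++cntT[static_cast<int>(y[samples[i]])];
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (cntT[c] > cntT[best]) best = c;
    return static_cast<double>(best);
  }

  bool find_split(int start, int end, int& best_feat, double& best_thr) {
    const int m = end - start;
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
    double best_score = -1e300;
    best_feat = -1;
    buf.resize(m);
    const int tries = mtry < p ? mtry : p;
    for (int t = 0; t < tries; ++t) {
      const int r = t + rand_int(p - t);
      std::swap(feat_pool[t], feat_pool[r]);
      const int f = feat_pool[t];
      for (int i = 0; i < m; ++i) {
        const int s = samples[start + i];
        buf[i].first = X(s, f);
        buf[i].second = y[s];
      }
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue;  // constant feature
      if (n_classes == 0) {
        double total = 0.0;
        for (int i = 0; i < m; ++i) total += buf[i].second;
        double sL = 0.0;
        for (int i = 0; i < m - 1; ++i) {
          sL += buf[i].second;
          if (buf[i].first == buf[i + 1].first) continue;
          const int nL = i + 1, nR = m - nL;
          const double sR = total - sL;
          const double score = sL * sL / nL + sR * sR / nR;
          if (score > best_score) {
            best_score = score;
            best_feat = f;
            best_thr = buf[i].first + 0.5 * (buf[i + 1].first - buf[i].first);
          }
        }
      } else {
        std::fill(cntT.begin(), cntT.end(), 0);
        for (int i = 0; i < m; ++i) ++cntT[static_cast<int>(buf[i].second)];
        std::fill(cntL.begin(), cntL.end(), 0);
        for (int i = 0; i < m - 1; ++i) {
          ++cntL[static_cast<int>(buf[i].second)];
          if (buf[i].first == buf[i + 1].first) continue;
          const int nL = i + 1, nR = m - nL;
          double score = 0.0;
          for (int c = 0; c < n_classes; ++c) {
            const double l = cntL[c], rr = cntT[c] - cntL[c];
            score += l * l / nL + rr * rr / nR;
          }
          if (score > best_score) {
            best_score = score;
            best_feat = f;
            best_thr = buf[i].first + 0.5 * (buf[i + 1].first - buf[i].first);
          }
        }
      }
    }
    return best_feat >= 0;
  }

  void build(int node, int start, int end) {
    const int m = end - start;
    bool pure = true;
    const double y0 = y[samples[start]];
    for (int i = start + 1; i < end; ++i)
      if (y[samples[i]] != y0) {
        pure = false;
        break;
      }
    if (m < min_split || pure) {
      tree.value[node] = leaf_value(start, end);
      return;
    }
    int f;
    double thr;
    if (!find_split(start, end, f, thr)) {  // all candidate features constant
      tree.value[node] = leaf_value(start, end);
      return;
    }
    int i = start, j = end - 1;
    while (i <= j) {
      if (X(samples[i], f) <= thr)
        ++i;
      else
        std::swap(samples[i], samples[j--]);
    }
    // midpoint of two nearly-equal values can round onto the upper value,
    // emptying one side; treat as unsplittable
    if (i == start || i == end) {
      tree.value[node] = leaf_value(start, end);
      return;
    }
    tree.feature[node] = f;
    tree.threshold[node] = thr;
    const int L = new_node(), R = new_node();
    tree.left[node] = L;
    tree.right[node] = R;
    build(L, start, i);
    build(R, i, end);
  }
};

inline double tree_predict_row(const IntegerVector& feat,
                               const NumericVector& thr,
                               const IntegerVector& lft,
                               const IntegerVector& rgt,
                               const NumericVector& val,
                               const NumericMatrix& X, int row) {
  int node = 0;
  while (feat[node] >= 0)
    node = (X(row, feat[node]) <= thr[node]) ? lft[node] : rgt[node];
  return val[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_grow")]]
List rf_grow(NumericMatrix X, NumericVector y, int num_trees, int mtry,
             int min_split, int n_classes, bool keep_inbag) {
  const int n = X.nrow();
  List trees(num_trees);
  IntegerMatrix inbag =
      keep_inbag ? IntegerMatrix(n, num_trees) : IntegerMatrix(0, 0);
  std::vector<int> counts(n);
  for (int t = 0; t < num_trees; ++t) {
    Builder b(X, y, mtry, min_split, n_classes);
    b.samples.resize(n);
    std::fill(counts.begin(), counts.end(), 0);
    for (int i = 0; i < n; ++i) {
      const int s = rand_int(n);
      b.samples[i] = s;
      ++counts[s];
    }
    const int root = b.new_node();
    b.build(root, 0, n);
    trees[t] = List::create(
        _["feature"] = wrap(b.tree.feature),
        _["threshold"] = wrap(b.tree.threshold),
        _["left"] = wrap(b.tree.left), _["right"] = wrap(b.tree.right),
        _["value"] = wrap(b.tree.value));
    if (keep_inbag)
      for (int i = 0; i < n; ++i) inbag(i, t) = counts[i];
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// [[Rcpp::export(name = ".rf_predict_reg")]]
NumericVector rf_predict_reg(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feature"], lft = tr["left"], rgt = tr["right"];
    NumericVector thr = tr["threshold"], val = tr["value"];
    for (int i = 0; i < n; ++i)
      out[i] += tree_predict_row(feat, thr, lft, rgt, val, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// Out-of-bag prediction for the training matrix: each row is averaged over
// the trees whose bootstrap sample did not contain it.
// [[Rcpp::export(name = ".rf_predict_reg_oob")]]
NumericVector rf_predict_reg_oob(List trees, NumericMatrix X,
                                 IntegerMatrix inbag) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n, 0.0);
  IntegerVector used(n, 0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feature"], lft = tr["left"], rgt = tr["right"];
    NumericVector thr = tr["threshold"], val = tr["value"];
    for (int i = 0; i < n; ++i) {
      if (inbag(i, t) > 0) continue;
      out[i] += tree_predict_row(feat, thr, lft, rgt, val, X, i);
      ++used[i];
    }
  }
  for (int i = 0; i < n; ++i)
    out[i] = used[i] > 0 ? out[i] / used[i] : NA_REAL;
  return out;
}

// [[Rcpp::export(name = ".rf_predict_class")]]
IntegerVector rf_predict_class(List trees, NumericMatrix X, int n_classes) {
  const int n = X.nrow(), T = trees.size();
  IntegerMatrix votes(n, n_classes);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feature"], lft = tr["left"], rgt = tr["right"];
    NumericVector thr = tr["threshold"], val = tr["value"];
    for (int i = 0; i < n; ++i) {
      const int c = static_cast<int>(
          tree_predict_row(feat, thr, lft, rgt, val, X, i));
      ++votes(i, c);
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (votes(i, c) > votes(i, best)) best = c;  // ties -> lowest index
    out[i] = best + 1;                             // 1-based for R
  }
  return out;
}
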