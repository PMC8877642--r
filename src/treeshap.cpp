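// Exact TreeSHAP attributions for binary regression trees, computed in
// double precision from a flattened forest (all trees concatenated into
// node arrays; children/roots are absolute 0-based indices, -1 for leaf
// children / non-split features). Implements the polynomial-time path
// algorithm of Lundberg et al. for the cover-weighted conditional
// expectation v(S) used by tree SHAP.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct PathElement {
  int feature_index;
  double zero_fraction;  // share of training cover flowing down this branch
  double one_fraction;   // 1 if the instance follows this branch, else 0
  double pweight;
};

void extend_path(PathElement *path, int depth, double zero_fraction,
                 double one_fraction, int feature_index) {
  path[depth].feature_index = feature_index;
  path[depth].zero_fraction = zero_fraction;
  path[depth].one_fraction = one_fraction;
  path[depth].pweight = (depth == 0 ? 1.0 : 0.0);
  for (int i = depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1.0) /
                           (depth + 1.0);
    path[i].pweight = zero_fraction * path[i].pweight * (depth - i) /
                      (depth + 1.0);
  }
}

void unwind_path(PathElement *path, int depth, int index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one_portion = path[depth].pweight;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (depth + 1.0) /
                        ((i + 1.0) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
                               (depth - i) / (depth + 1.0);
    } else {
      path[i].pweight = (path[i].pweight * (depth + 1.0)) /
                        (zero_fraction * (depth - i));
    }
  }
  for (int i = index; i < depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

double unwound_path_sum(const PathElement *path, int depth, int index) {
  const double one_fraction = path[index].one_fraction;
  const double zero_fraction = path[index].zero_fraction;
  double next_one_portion = path[depth].pweight;
  double total = 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (depth + 1.0) /
                         ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight - tmp * zero_fraction *
                                           (depth - i) / (depth + 1.0);
    } else {
      total += (path[i].pweight / zero_fraction) /
               ((depth - i) / (depth + 1.0));
    }
  }
  return total;
}

struct Forest {
  const int *left, *right, *feat;
  const double *thr, *val, *cover;
};

void shap_recursive(const Forest &f, const double *x, double *phi, int node,
                    int depth, PathElement *parent_path,
                    double parent_zero_fraction, double parent_one_fraction,
                    int parent_feature_index) {
  PathElement *path = parent_path + depth + 1;
  std::copy(parent_path, parent_path + depth, path);
  extend_path(path, depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);

  if (f.feat[node] < 0) {  // leaf
    for (int i = 1; i <= depth; ++i) {
      const double w = unwound_path_sum(path, depth, i);
      phi[path[i].feature_index] +=
          w * (path[i].one_fraction - path[i].zero_fraction) * f.val[node];
    }
    return;
  }

  const int split_feat = f.feat[node];
  const int hot = (x[split_feat] < f.thr[node]) ? f.left[node] : f.right[node];
  const int cold = (hot == f.left[node]) ? f.right[node] : f.left[node];
  const double hot_zero_fraction = f.cover[hot] / f.cover[node];
  const double cold_zero_fraction = f.cover[cold] / f.cover[node];
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  // a prior split on the same feature is merged into this one
  int index = 0;
  for (; index <= depth; ++index) {
    if (path[index].feature_index == split_feat) break;
  }
  if (index != depth + 1) {
    incoming_zero_fraction = path[index].zero_fraction;
    incoming_one_fraction = path[index].one_fraction;
    unwind_path(path, depth, index);
    depth -= 1;
  }

  shap_recursive(f, x, phi, hot, depth + 1, path,
                 hot_zero_fraction * incoming_zero_fraction,
                 incoming_one_fraction, split_feat);
  shap_recursive(f, x, phi, cold, depth + 1, path,
                 cold_zero_fraction * incoming_zero_fraction, 0.0, split_feat);
}

int max_depth_from(const Forest &f, int node) {
  if (f.feat[node] < 0) return 0;
  return 1 + std::max(max_depth_from(f, f.left[node]),
                      max_depth_from(f, f.right[node]));
}

double leaf_mean(const Forest &f, int node) {
  if (f.feat[node] < 0) return f.val[node];
  const double wl = f.cover[f.left[node]], wr = f.cover[f.right[node]];
  return (wl * leaf_mean(f, f.left[node]) + wr * leaf_mean(f, f.right[node])) /
         (wl + wr);
}

double traverse(const Forest &f, int node, const double *x) {
  while (f.feat[node] >= 0) {
    node = (x[f.feat[node]] < f.thr[node]) ? f.left[node] : f.right[node];
  }
  return f.val[node];
}

Forest make_forest(const IntegerVector &left, const IntegerVector &right,
                   const IntegerVector &feat, const NumericVector &thr,
                   const NumericVector &val, const NumericVector &cover) {
  Forest f;
  f.left = INTEGER(left);
  f.right = INTEGER(right);
  f.feat = INTEGER(feat);
  f.thr = REAL(thr);
  f.val = REAL(val);
  f.cover = REAL(cover);
  return f;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_tree_shap(IntegerVector roots, IntegerVector left,
                            IntegerVector right, IntegerVector feat,
                            NumericVector thr, NumericVector val,
                            NumericVector cover, NumericMatrix X) {
  const Forest f = make_forest(left, right, feat, thr, val, cover);
  const int n = X.nrow(), m = X.ncol(), ntree = roots.size();
  NumericMatrix phi(n, m);
  int maxd = 0;
  for (int t = 0; t < ntree; ++t) {
    maxd = std::max(maxd, max_depth_from(f, roots[t]));
  }
  const int arena = (maxd + 2) * (maxd + 3) / 2 + maxd + 2;
  std::vector<PathElement> path(arena);
  std::vector<double> x(m), prow(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      x[j] = X(i, j);
      prow[j] = 0.0;
    }
    for (int t = 0; t < ntree; ++t) {
      shap_recursive(f, x.data(), prow.data(), roots[t], 0, path.data(), 1.0,
                     1.0, -1);
    }
    for (int j = 0; j < m; ++j) phi(i, j) = prow[j];
  }
  return phi;
}

// [[Rcpp::export]]
double cpp_tree_expected(IntegerVector roots, IntegerVector left,
                         IntegerVector right, IntegerVector feat,
                         NumericVector thr, NumericVector val,
                         NumericVector cover) {
  const Forest f = make_forest(left, right, feat, thr, val, cover);
  double total = 0.0;
  for (int t = 0; t < roots.size(); ++t) total += leaf_mean(f, roots[t]);
  return total;
}

// [[Rcpp::export]]
NumericVector cpp_tree_predict(IntegerVector roots, IntegerVector left,
                               IntegerVector right, IntegerVector feat,
                               NumericVector thr, NumericVector val,
                               NumericVector cover, NumericMatrix X) {
  const Forest f = make_forest(left, right, feat, thr, val, cover);
  const int n = X.nrow(), m = X.ncol();
  NumericVector out(n);
  std::vector<double> x(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) x[j] = X(i, j);
    double s = 0.0;
    for (int t = 0; t < roots.size(); ++t) s += traverse(f, roots[t], x.data());
    out[i] = s;
  }
  return out;
}
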