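#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Separable convolution with reflect padding.
// Kernels are applied along rows (ky, vertical) and columns (kx, horizontal);
// both kernels must have odd length.  Reflection is edge-inclusive
// (index -1 maps to 0), matching scipy's "nearest-free" mirror used by the
// classic multiscale feature banks.
// ---------------------------------------------------------------------------
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv_sep(const NumericMatrix& img, const NumericVector& ky,
                           const NumericVector& kx) {
  const int nr = img.nrow(), nc = img.ncol();
  const int hy = (ky.size() - 1) / 2, hx = (kx.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int k = -hy; k <= hy; ++k)
        s += ky[k + hy] * img(reflect_idx(r + k, nr), c);
      tmp(r, c) = s;
    }
  // horizontal pass
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int k = -hx; k <= hx; ++k)
        s += kx[k + hx] * tmp(r, reflect_idx(c + k, nc));
      out(r, c) = s;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Bilinear interpolation at continuous 0-based pixel-centred coordinates.
// Out-of-range coordinates clamp to the border value.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_bilinear(const NumericMatrix& img, const NumericVector& x,
                           const NumericVector& y) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double xi = std::min(std::max(x[i], 0.0), nc - 1.0);
    double yi = std::min(std::max(y[i], 0.0), nr - 1.0);
    int c0 = (int)std::floor(xi), r0 = (int)std::floor(yi);
    int c1 = std::min(c0 + 1, nc - 1), r1 = std::min(r0 + 1, nr - 1);
    double fx = xi - c0, fy = yi - r0;
    out[i] = (1 - fy) * ((1 - fx) * img(r0, c0) + fx * img(r0, c1)) +
             fy * ((1 - fx) * img(r1, c0) + fx * img(r1, c1));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Bilinear splatting: deposit weights w at continuous coordinates (x, y)
// into an image, conserving the total deposited mass (samples falling
// outside the grid are clipped to the border pixel).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_splat(int nrow, int ncol, const NumericVector& x,
                        const NumericVector& y, const NumericVector& w) {
  NumericMatrix out(nrow, ncol);
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    double xi = std::min(std::max(x[i], 0.0), ncol - 1.0);
    double yi = std::min(std::max(y[i], 0.0), nrow - 1.0);
    int c0 = (int)std::floor(xi), r0 = (int)std::floor(yi);
    int c1 = std::min(c0 + 1, ncol - 1), r1 = std::min(r0 + 1, nrow - 1);
    double fx = xi - c0, fy = yi - r0;
    out(r0, c0) += w[i] * (1 - fy) * (1 - fx);
    out(r0, c1) += w[i] * (1 - fy) * fx;
    out(r1, c0) += w[i] * fy * (1 - fx);
    out(r1, c1) += w[i] * fy * fx;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a binary mask (8- or 4-connectivity),
// iterative flood fill.  Labels are 1..K in scan order of first pixel.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, bool eight) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int nn = eight ? 8 : 4;
  const int* dr = eight ? dr8 : dr4;
  const int* dc = eight ? dc8 : dc4;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  return lab;
}

// ---------------------------------------------------------------------------
// Zhang-Suen thinning of a binary mask down to a 1-px skeleton.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(clone(mask));
  for (int i = 0; i < nr * nc; ++i) img[i] = img[i] ? 1 : 0;
  auto P = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c);
  };
  bool changed = true;
  std::vector<std::pair<int, int> > del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          int p2 = P(r - 1, c), p3 = P(r - 1, c + 1), p4 = P(r, c + 1),
              p5 = P(r + 1, c + 1), p6 = P(r + 1, c), p7 = P(r + 1, c - 1),
              p8 = P(r, c - 1), p9 = P(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i)
        img(del[i].first, del[i].second) = 0;
    }
  }
  return img;
}

// ===========================================================================
// Random forest (CART, gini impurity, bootstrap + mtry feature subsampling).
// Uses R's RNG so that set.seed() in R makes training reproducible.
// Each tree is stored as a 5-column matrix:
//   [feature (0-based, -1 for leaf), threshold, left, right, class]
// ===========================================================================
struct TreeNode {
  int feature;
  double thr;
  int left, right, cls;
};

static void grow_node(const NumericMatrix& X, const IntegerVector& y,
                      std::vector<int>& idx, int lo, int hi, int depth,
                      int max_depth, int min_node, int mtry, int nclass,
                      std::vector<TreeNode>& nodes, int me) {
  // class counts
  std::vector<int> cnt(nclass, 0);
  for (int i = lo; i < hi; ++i) cnt[y[idx[i]]]++;
  int best_c = 0;
  for (int k = 1; k < nclass; ++k)
    if (cnt[k] > cnt[best_c]) best_c = k;
  nodes[me].cls = best_c;
  int n = hi - lo;
  bool pure = (cnt[best_c] == n);
  if (pure || depth >= max_depth || n < min_node) {
    nodes[me].feature = -1;
    return;
  }
  const int p = X.ncol();
  // sample mtry features without replacement
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry; ++j) {
    int pick = j + (int)(unif_rand() * (p - j));
    if (pick >= p) pick = p - 1;
    std::swap(feats[j], feats[pick]);
  }
  double best_gain = -1.0, best_thr = 0.0;
  int best_f = -1;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  std::vector<int> lcnt(nclass), rcnt(nclass);
  double tot = 0.0;
  {
    double imp = 0.0;
    for (int k = 0; k < nclass; ++k) imp += (double)cnt[k] * cnt[k];
    tot = 1.0 - imp / ((double)n * n);
  }
  for (int jj = 0; jj < mtry; ++jj) {
    int f = feats[jj];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    std::fill(lcnt.begin(), lcnt.end(), 0);
    for (int k = 0; k < nclass; ++k) rcnt[k] = cnt[k];
    for (int i = 0; i < n - 1; ++i) {
      int c = y[ord[i]];
      lcnt[c]++;
      rcnt[c]--;
      double v0 = X(ord[i], f), v1 = X(ord[i + 1], f);
      if (v1 <= v0) continue;
      int nl = i + 1, nrr = n - nl;
      double gl = 0.0, gr = 0.0;
      for (int k = 0; k < nclass; ++k) {
        gl += (double)lcnt[k] * lcnt[k];
        gr += (double)rcnt[k] * rcnt[k];
      }
      double gini = ((double)nl - gl / nl + (double)nrr - gr / nrr) / n;
      double gain = tot - gini;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (v0 + v1);
      }
    }
  }
  if (best_f < 0 || best_gain <= 1e-12) {
    nodes[me].feature = -1;
    return;
  }
  // partition idx[lo:hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) {
    nodes[me].feature = -1;
    return;
  }
  nodes[me].feature = best_f;
  nodes[me].thr = best_thr;
  int li = (int)nodes.size();
  nodes.push_back(TreeNode());
  int ri = (int)nodes.size();
  nodes.push_back(TreeNode());
  nodes[me].left = li;
  nodes[me].right = ri;
  grow_node(X, y, idx, lo, mid, depth + 1, max_depth, min_node, mtry, nclass,
            nodes, li);
  grow_node(X, y, idx, mid, hi, depth + 1, max_depth, min_node, mtry, nclass,
            nodes, ri);
}

// [[Rcpp::export]]
List cpp_rf_train(const NumericMatrix& X, const IntegerVector& y, int ntree,
                  int mtry, int max_depth, int min_node, int nclass) {
  RNGScope scope;
  const int n = X.nrow();
  List forest(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int pick = (int)(unif_rand() * n);
      if (pick >= n) pick = n - 1;
      idx[i] = pick;
    }
    std::vector<TreeNode> nodes;
    nodes.push_back(TreeNode());
    grow_node(X, y, idx, 0, n, 0, max_depth, min_node, mtry, nclass, nodes, 0);
    NumericMatrix tm(nodes.size(), 5);
    for (size_t i = 0; i < nodes.size(); ++i) {
      tm(i, 0) = nodes[i].feature;
      tm(i, 1) = nodes[i].feature < 0 ? 0.0 : nodes[i].thr;
      tm(i, 2) = nodes[i].feature < 0 ? -1 : nodes[i].left;
      tm(i, 3) = nodes[i].feature < 0 ? -1 : nodes[i].right;
      tm(i, 4) = nodes[i].cls;
    }
    forest[t] = tm;
  }
  return forest;
}

// [[Rcpp::export]]
IntegerVector cpp_rf_predict(const List& forest, const NumericMatrix& X,
                             int nclass) {
  const int n = X.nrow(), ntree = forest.size();
  std::vector<int> votes((size_t)n * nclass, 0);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tm = forest[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while ((int)tm(node, 0) >= 0) {
        int f = (int)tm(node, 0);
        node = X(i, f) <= tm(node, 1) ? (int)tm(node, 2) : (int)tm(node, 3);
      }
      votes[(size_t)i * nclass + (int)tm(node, 4)]++;
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    for (int k = 1; k < nclass; ++k)
      if (votes[(size_t)i * nclass + k] > votes[(size_t)i * nclass + best])
        best = k;
    out[i] = best;
  }
  return out;
}
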