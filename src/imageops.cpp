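// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>

using namespace Rcpp;

static inline int reflect(int i, int n) {
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - i - 1;
  return i;
}

// Separable Gaussian blur with reflective boundary handling.
// [[Rcpp::export]]
arma::mat cpp_gaussian_blur(const arma::mat& img, double sigma) {
  if (sigma <= 0) return img;
  int r = (int)std::ceil(3.0 * sigma);
  arma::vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k(i + r) = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
  k /= arma::accu(k);

  int H = img.n_rows, W = img.n_cols;
  arma::mat tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)       // vertical pass
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t) s += k(t + r) * img(reflect(i + t, H), j);
      tmp(i, j) = s;
    }
  for (int i = 0; i < H; ++i)       // horizontal pass
    for (int j = 0; j < W; ++j) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t) s += k(t + r) * tmp(i, reflect(j + t, W));
      out(i, j) = s;
    }
  return out;
}

// 8-connected component labeling of a logical mask (BFS flood fill).
// Returns an integer matrix of labels, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int j0 = 0; j0 < W; ++j0)
    for (int i0 = 0; i0 < H; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      ++next;
      stack.push_back(i0 + j0 * H);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int i = p % H, j = p / H;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * H);
            }
          }
      }
    }
  return lab;
}
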