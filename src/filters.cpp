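#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// symmetric (reflective) boundary index: -1 -> 0, -2 -> 1, n -> n-1, n+1 -> n-2
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel must be a positive odd integer");
  const int H = x.nrow(), W = x.ncol(), b = k / 2;
  NumericMatrix out(H, W);
  std::vector<double> buf((size_t)k * k);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int m = 0;
      for (int dj = -b; dj <= b; ++dj) {
        const int jj = reflect_idx(j + dj, W);
        for (int di = -b; di <= b; ++di) {
          buf[m++] = x(reflect_idx(i + di, H), jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      out(i, j) = buf[m / 2];
    }
  }
  return out;
}

// mean over a block x block neighbourhood with symmetric padding, via an
// integral image over the padded frame
// [[Rcpp::export]]
NumericMatrix cpp_local_mean(NumericMatrix x, int block) {
  if (block < 1 || block % 2 == 0) stop("block must be a positive odd integer");
  const int H = x.nrow(), W = x.ncol(), b = block / 2;
  const int PH = H + 2 * b, PW = W + 2 * b;
  std::vector<double> S((size_t)(PH + 1) * (PW + 1), 0.0);
  for (int i = 0; i < PH; ++i) {
    const int ii = reflect_idx(i - b, H);
    double rowsum = 0.0;
    for (int j = 0; j < PW; ++j) {
      rowsum += x(ii, reflect_idx(j - b, W));
      S[(size_t)(i + 1) * (PW + 1) + (j + 1)] =
        S[(size_t)i * (PW + 1) + (j + 1)] + rowsum;
    }
  }
  NumericMatrix out(H, W);
  const double area = (double)block * block;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      const double s =
        S[(size_t)(i + block) * (PW + 1) + (j + block)]
        - S[(size_t)i * (PW + 1) + (j + block)]
        - S[(size_t)(i + block) * (PW + 1) + j]
        + S[(size_t)i * (PW + 1) + j];
      out(i, j) = s / area;
    }
  }
  return out;
}
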