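#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fold an arbitrary integer index into [0, n) by symmetric (mirror)
// reflection with edge repetition: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
// The folding has period 2n, so kernels wider than the image are handled
// by repeated reflection rather than being rejected.
static inline int mirror_index(int i, int n) {
  if (n == 1) return 0;
  int p = 2 * n;
  i %= p;
  if (i < 0) i += p;
  return (i < n) ? i : (p - 1 - i);
}

// Separable convolution of a matrix with a 1-D kernel (applied along rows,
// then along columns), symmetric boundary padding.  The kernel must have
// odd length; its centre is at (len-1)/2.  Mirror indices are tabulated
// once per axis: this routine is the hot path of the level-set transform.
// [[Rcpp::export]]
NumericMatrix sep_conv2_symm(const NumericMatrix& img, const NumericVector& k) {
  const int nr = img.nrow(), nc = img.ncol(), len = k.size();
  if (len % 2 == 0) stop("kernel length must be odd");
  const int r = (len - 1) / 2;

  // index tables: mc[t*nc + j] = mirrored column for offset t-r at column j
  std::vector<int> mc(static_cast<size_t>(len) * nc), mr(static_cast<size_t>(len) * nr);
  for (int t = 0; t < len; ++t) {
    for (int j = 0; j < nc; ++j) mc[static_cast<size_t>(t) * nc + j] = mirror_index(j + t - r, nc);
    for (int i = 0; i < nr; ++i) mr[static_cast<size_t>(t) * nr + i] = mirror_index(i + t - r, nr);
  }

  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* src = img.begin();
  double* tdat = tmp.begin();
  // horizontal pass (across columns); columns are contiguous in R layout
  for (int t = 0; t < len; ++t) {
    const double kw = k[t];
    const int* cols = &mc[static_cast<size_t>(t) * nc];
    for (int j = 0; j < nc; ++j) {
      const double* in = src + static_cast<size_t>(cols[j]) * nr;
      double* o = tdat + static_cast<size_t>(j) * nr;
      for (int i = 0; i < nr; ++i) o[i] += kw * in[i];
    }
  }
  // vertical pass (within each column)
  double* odat = out.begin();
  for (int j = 0; j < nc; ++j) {
    const double* in = tdat + static_cast<size_t>(j) * nr;
    double* o = odat + static_cast<size_t>(j) * nr;
    for (int t = 0; t < len; ++t) {
      const double kw = k[t];
      const int* rows = &mr[static_cast<size_t>(t) * nr];
      for (int i = 0; i < nr; ++i) o[i] += kw * in[rows[i]];
    }
  }
  return out;
}

// Full 2-D convolution with an arbitrary odd-sized kernel, symmetric padding.
// [[Rcpp::export]]
NumericMatrix conv2_symm(const NumericMatrix& img, const NumericMatrix& K) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = K.nrow(), kc = K.ncol();
  if (kr % 2 == 0 || kc % 2 == 0) stop("kernel dimensions must be odd");
  const int ri = (kr - 1) / 2, rj = (kc - 1) / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int tj = -rj; tj <= rj; ++tj) {
        const int jj = mirror_index(j + tj, nc);
        for (int ti = -ri; ti <= ri; ++ti) {
          acc += K(ti + ri, tj + rj) * img(mirror_index(i + ti, nr), jj);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Direct per-pixel evaluation of the nonlinear summation term
//   N(x) = sum_i w_i * atan(I(y_i) - c(x))
// where the sum runs over the support of the 2-D kernel W centred at x,
// neighbours taken with symmetric padding, and c = g * I precomputed by the
// caller.  No approximation: this is the ground-truth path.
// [[Rcpp::export]]
NumericMatrix inrf_nonlinear_naive(const NumericMatrix& img,
                                   const NumericMatrix& cimg,
                                   const NumericMatrix& W) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = W.nrow(), kc = W.ncol();
  if (kr % 2 == 0 || kc % 2 == 0) stop("kernel dimensions must be odd");
  const int ri = (kr - 1) / 2, rj = (kc - 1) / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double c = cimg(i, j);
      double acc = 0.0;
      for (int tj = -rj; tj <= rj; ++tj) {
        const int jj = mirror_index(j + tj, nc);
        for (int ti = -ri; ti <= ri; ++ti) {
          acc += W(ti + ri, tj + rj) * std::atan(img(mirror_index(i + ti, nr), jj) - c);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Level-set evaluation of the shifting-nonlinearity term.  For each level
// c_k in `levels` that brackets at least one pixel, computes
// (w * atan(I - c_k)) by separable convolution and scatters the linear
// interpolation weights; `lo` holds the 0-based lower-bracket level per
// pixel and `frac` the interpolation fraction.  Doing the loop here avoids
// allocating the full level stack.
// [[Rcpp::export]]
NumericMatrix levelset_nonlinear(const NumericMatrix& img,
                                 const NumericVector& levels,
                                 const IntegerVector& lo,
                                 const NumericVector& frac,
                                 const NumericVector& kw) {
  const int nr = img.nrow(), nc = img.ncol(), npx = nr * nc;
  const int nl = levels.size();
  NumericMatrix acc(nr, nc);
  NumericMatrix shifted(nr, nc);
  // which levels are referenced at all
  std::vector<bool> used(nl, false);
  for (int p = 0; p < npx; ++p) {
    used[lo[p]] = true;
    if (lo[p] + 1 < nl) used[lo[p] + 1] = true;
  }
  for (int k = 0; k < nl; ++k) {
    if (!used[k]) continue;
    const double ck = levels[k];
    for (int p = 0; p < npx; ++p) shifted[p] = std::atan(img[p] - ck);
    NumericMatrix Lk = sep_conv2_symm(shifted, kw);
    for (int p = 0; p < npx; ++p) {
      if (lo[p] == k) acc[p] += (1.0 - frac[p]) * Lk[p];
      else if (lo[p] + 1 == k) acc[p] += frac[p] * Lk[p];
    }
  }
  return acc;
}
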