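// Numeric kernels for the slice encoder.
//
// Layout convention ("pixel matrix"): a stack of N single- or multi-channel
// images of size H x W is a numeric matrix with H*W*N rows and C columns;
// row index = h + H*w + H*W*n (0-based), i.e. column-major within a slice,
// slices stacked. Convolutions are 3x3, stride 1, zero ("same") padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int K = 3; // kernel side

// im2col for 3x3 same-padded convolution.
// Column ordering: col = c*9 + j with j = (ky+1) + 3*(kx+1), offsets in {-1,0,1}.
//
// Each im2col column is the whole stack shifted by a constant flat offset
// (kx*H + ky): one bulk copy, after which the positions that wrapped
// across a row/column/slice boundary -- exactly the out-of-image positions
// of the shift -- are zeroed in place. A persistent workspace avoids
// re-mapping tens of MB on every call.

// Zero the out-of-image positions of a shifted stack column.
static void zero_invalid(double* dst, int H, int W, int N, int ky, int kx) {
  const arma::uword HW = (arma::uword)H * W;
  if (ky == 1)
    for (arma::uword p = H - 1; p < HW * N; p += H) dst[p] = 0.0;
  else if (ky == -1)
    for (arma::uword p = 0; p < HW * N; p += H) dst[p] = 0.0;
  if (kx == 1)
    for (int n = 0; n < N; ++n)
      std::fill(dst + (arma::uword)n * HW + (arma::uword)(W - 1) * H,
                dst + (arma::uword)(n + 1) * HW, 0.0);
  else if (kx == -1)
    for (int n = 0; n < N; ++n)
      std::fill(dst + (arma::uword)n * HW, dst + (arma::uword)n * HW + H, 0.0);
}

static arma::mat& im2col3(const arma::mat& X, int H, int W, int N) {
  static arma::mat Xcol;
  const int C = X.n_cols;
  const arma::uword R = X.n_rows;
  Xcol.set_size(R, (arma::uword)9 * C);
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        int j = (ky + 1) + 3 * (kx + 1);
        double* dst = Xcol.colptr((arma::uword)c * 9 + j);
        long off = (long)kx * H + ky;
        if (off >= 0) {
          std::copy(src + off, src + R, dst);
          std::fill(dst + (R - off), dst + R, 0.0);
        } else {
          std::copy(src, src + R + off, dst - off);
          std::fill(dst, dst - off, 0.0);
        }
        zero_invalid(dst, H, W, N, ky, kx);
      }
    }
  }
  return Xcol;
}

// Convolution with optional fused ReLU.
// [[Rcpp::export]]
arma::mat conv3_fwd(const arma::mat& X, int H, int W, int N,
                    const arma::mat& Wt, const arma::rowvec& bias,
                    bool relu = false) {
  arma::mat Y = im2col3(X, H, W, N) * Wt;
  Y.each_row() += bias;
  if (relu) Y.elem(arma::find(Y < 0)).zeros();
  return Y;
}

// Backward through conv (+ fused ReLU when the post-activation output
// `Yrelu` is supplied: incoming gradients are masked where Yrelu == 0).
// [[Rcpp::export]]
List conv3_bwd(const arma::mat& X, int H, int W, int N,
               const arma::mat& Wt, const arma::mat& dY,
               Rcpp::Nullable<Rcpp::NumericMatrix> Yrelu = R_NilValue) {
  static arma::mat dYm;
  const arma::mat* dYp = &dY;
  if (Yrelu.isNotNull()) {
    Rcpp::NumericMatrix Ym(Yrelu);
    const arma::mat Y(Ym.begin(), Ym.nrow(), Ym.ncol(), false, true);
    dYm = dY;
    dYm.elem(arma::find(Y == 0)).zeros();
    dYp = &dYm;
  }
  arma::mat& Xcol = im2col3(X, H, W, N);
  arma::mat dW = Xcol.t() * (*dYp);
  arma::rowvec db = arma::sum(*dYp, 0);
  static arma::mat dXcol;
  dXcol = (*dYp) * Wt.t();
  const int C = X.n_cols;
  const arma::uword R = X.n_rows;
  arma::mat dX(X.n_rows, C, arma::fill::zeros);
  // col2im scatter-add: zero each column's out-of-image positions, then
  // accumulate the column shifted by the inverse flat offset.
  for (int c = 0; c < C; ++c) {
    double* dst = dX.colptr(c);
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        int j = (ky + 1) + 3 * (kx + 1);
        double* src = dXcol.colptr((arma::uword)c * 9 + j);
        zero_invalid(src, H, W, N, ky, kx);
        long off = (long)kx * H + ky;
        if (off >= 0)
          for (arma::uword p = 0; p < R - off; ++p) dst[p + off] += src[p];
        else
          for (arma::uword p = 0; p < R + off; ++p) dst[p] += src[p - off];
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 2x2 mean pooling, stride 2 (H and W must be even).
// [[Rcpp::export]]
arma::mat pool2_fwd(const arma::mat& X, int H, int W, int N) {
  const int C = X.n_cols, Ho = H / 2, Wo = W / 2;
  const arma::uword HW = (arma::uword)H * W, HWo = (arma::uword)Ho * Wo;
  arma::mat Y((arma::uword)N * HWo, C);
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    double* dst = Y.colptr(c);
    for (int n = 0; n < N; ++n)
      for (int x = 0; x < Wo; ++x) {
        const double* s0 = src + (arma::uword)n * HW + (arma::uword)(2 * x) * H;
        const double* s1 = s0 + H;
        double* d = dst + (arma::uword)n * HWo + (arma::uword)x * Ho;
        for (int y = 0; y < Ho; ++y)
          d[y] = 0.25 * (s0[2 * y] + s0[2 * y + 1] + s1[2 * y] + s1[2 * y + 1]);
      }
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat pool2_bwd(const arma::mat& dY, int H, int W, int N) {
  const int C = dY.n_cols, Ho = H / 2, Wo = W / 2;
  const arma::uword HW = (arma::uword)H * W, HWo = (arma::uword)Ho * Wo;
  arma::mat dX((arma::uword)N * HW, C);
  for (int c = 0; c < C; ++c) {
    const double* src = dY.colptr(c);
    double* dst = dX.colptr(c);
    for (int n = 0; n < N; ++n)
      for (int x = 0; x < Wo; ++x) {
        const double* s = src + (arma::uword)n * HWo + (arma::uword)x * Ho;
        double* d0 = dst + (arma::uword)n * HW + (arma::uword)(2 * x) * H;
        double* d1 = d0 + H;
        for (int y = 0; y < Ho; ++y) {
          double g = 0.25 * s[y];
          d0[2 * y] = g; d0[2 * y + 1] = g; d1[2 * y] = g; d1[2 * y + 1] = g;
        }
      }
  }
  return dX;
}

// Per-slice zoom + shift with bilinear resampling, zero fill outside.
// zoom > 1 magnifies about the slice centre; dx/dy shift in pixels.
// [[Rcpp::export]]
NumericVector warp_stack(const NumericVector& X, int H, int W, int N,
                         const NumericVector& zoom,
                         const NumericVector& dx, const NumericVector& dy) {
  const arma::uword HW = (arma::uword)H * W;
  NumericVector out((arma::uword)N * HW);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int n = 0; n < N; ++n) {
    const double z = zoom[n], sx0 = dx[n], sy0 = dy[n];
    const double* src = &X[(arma::uword)n * HW];
    double* dst = &out[(arma::uword)n * HW];
    for (int x = 0; x < W; ++x) {
      double sx = cx + (x - cx) / z - sx0;
      for (int y = 0; y < H; ++y) {
        double sy = cy + (y - cy) / z - sy0;
        double v = 0.0;
        if (sx >= 0 && sx <= W - 1 && sy >= 0 && sy <= H - 1) {
          int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
          int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
          double fx = sx - x0, fy = sy - y0;
          double v00 = src[(arma::uword)x0 * H + y0], v01 = src[(arma::uword)x1 * H + y0];
          double v10 = src[(arma::uword)x0 * H + y1], v11 = src[(arma::uword)x1 * H + y1];
          v = (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
        }
        dst[(arma::uword)x * H + y] = v;
      }
    }
  }
  out.attr("dim") = X.attr("dim");
  return out;
}
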