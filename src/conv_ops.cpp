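// Convolution and pooling kernels for the patch classifiers.
//
// Layout conventions (match R's column-major arrays):
//   images:  4-d array (H, W, C, N), one contiguous H*W*C block per image
//   kernels: matrix (k*k*C_in, F), row index r = kh + k*kw + k*k*c, i.e. the
//            natural flattening of an R array of dim (k, k, C_in, F)
//   conv output (H*W, F) reshapes directly to (H, W, F)
// All convolutions are 3x3-style "same" padding (zero pad), stride 1.
// Max pooling is 2x2 stride 2 with either ceil- or floor-mode output size.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc4d(int a, int b, int c, int d) {
  NumericVector v(static_cast<R_xlen_t>(a) * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v(static_cast<R_xlen_t>(a) * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Gather the k*k neighbourhood of every output pixel into a row of `cols`.
static void im2col_same(const arma::cube &x, int k, arma::mat &cols) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col_idx = kh + k * kw + k * k * c;
        double *dstcol = cols.colptr(col_idx);
        for (int w = 0; w < W; ++w) {
          const int iw = w + kw - pad;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, pad - kh);
          const int h1 = std::min(H - 1, H - 1 + pad - kh);
          if (h1 < h0) continue;
          const double *src = &x(h0 + kh - pad, iw, c);
          std::memcpy(dstcol + h0 + static_cast<size_t>(H) * w, src,
                      sizeof(double) * (h1 - h0 + 1));
        }
      }
    }
  }
}

// Transpose of im2col: scatter-add column gradients back onto the image.
static void col2im_same(const arma::mat &cols, int k, arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col_idx = kh + k * kw + k * k * c;
        const double *srccol = cols.colptr(col_idx);
        for (int w = 0; w < W; ++w) {
          const int iw = w + kw - pad;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, pad - kh);
          const int h1 = std::min(H - 1, H - 1 + pad - kh);
          if (h1 < h0) continue;
          const double *src = srccol + h0 + static_cast<size_t>(H) * w;
          double *dst = &x(h0 + kh - pad, iw, c);
          for (int i = 0; i <= h1 - h0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericMatrix Wm, NumericVector b,
                        bool relu) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int k2C = Wm.nrow(), F = Wm.ncol();
  const int k = static_cast<int>(std::lround(std::sqrt(double(k2C / C))));
  if (k * k * C != k2C) stop("kernel rows inconsistent with input channels");
  arma::mat Wa(Wm.begin(), k2C, F, false);
  arma::rowvec bv(b.begin(), F);
  NumericVector out = alloc4d(H, W, F, N);
  arma::mat cols(static_cast<size_t>(H) * W, k2C);
  const size_t inplane = static_cast<size_t>(H) * W * C;
  const size_t outplane = static_cast<size_t>(H) * W * F;
  for (int n = 0; n < N; ++n) {
    arma::cube xn(x.begin() + n * inplane, H, W, C, false, true);
    im2col_same(xn, k, cols);
    arma::mat Z = cols * Wa;
    Z.each_row() += bv;
    if (relu) Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    std::memcpy(out.begin() + n * outplane, Z.memptr(),
                sizeof(double) * outplane);
  }
  return out;
}

// Gradient of the same-padded convolution. `out` is the forward output
// (post-ReLU when relu = true) and is used only for the ReLU mask.
// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericMatrix Wm, NumericVector out,
               NumericVector dout, bool relu, bool need_dx) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int k2C = Wm.nrow(), F = Wm.ncol();
  const int k = static_cast<int>(std::lround(std::sqrt(double(k2C / C))));
  arma::mat Wa(Wm.begin(), k2C, F, false);
  arma::mat dW(k2C, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) dx = alloc4d(H, W, C, N);
  arma::mat cols(static_cast<size_t>(H) * W, k2C);
  const size_t inplane = static_cast<size_t>(H) * W * C;
  const size_t outplane = static_cast<size_t>(H) * W * F;
  for (int n = 0; n < N; ++n) {
    arma::cube xn(x.begin() + n * inplane, H, W, C, false, true);
    arma::mat dZ(dout.begin() + n * outplane, static_cast<size_t>(H) * W, F);
    if (relu) {
      const arma::mat On(out.begin() + n * outplane,
                         static_cast<size_t>(H) * W, F, false, true);
      dZ.elem(arma::find(On <= 0.0)).zeros();
    }
    im2col_same(xn, k, cols);
    dW += cols.t() * dZ;
    db += arma::sum(dZ, 0);
    if (need_dx) {
      arma::mat dcols = dZ * Wa.t();
      arma::cube dxn(dx.begin() + n * inplane, H, W, C, false, true);
      col2im_same(dcols, k, dxn);
    }
  }
  return List::create(_["dx"] = need_dx ? (SEXP)dx : R_NilValue,
                      _["dW"] = wrap(dW), _["db"] = wrap(arma::vec(db.t())));
}

// 2x2 stride-2 max pooling; ceil_mode keeps a trailing 1-wide window when
// the input size is odd, floor mode drops the trailing row/column.
// [[Rcpp::export]]
List maxpool2_fw(NumericVector x, bool ceil_mode) {
  IntegerVector dm = x.attr("dim");
  const int H = dm[0], W = dm[1], C = dm[2], N = dm[3];
  const int OH = ceil_mode ? (H + 1) / 2 : H / 2;
  const int OW = ceil_mode ? (W + 1) / 2 : W / 2;
  NumericVector out = alloc4d(OH, OW, C, N);
  IntegerVector idx = alloc4i(OH, OW, C, N);  // argmax as h + H*w, 0-based
  const size_t inplane = static_cast<size_t>(H) * W;
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *plane =
          x.begin() + (static_cast<size_t>(n) * C + c) * inplane;
      for (int ow = 0; ow < OW; ++ow) {
        const int w0 = 2 * ow, w1 = std::min(2 * ow + 1, W - 1);
        for (int oh = 0; oh < OH; ++oh, ++o) {
          const int h0 = 2 * oh, h1 = std::min(2 * oh + 1, H - 1);
          double best = -std::numeric_limits<double>::infinity();
          int besti = h0 + H * w0;
          for (int w = w0; w <= w1; ++w)
            for (int h = h0; h <= h1; ++h) {
              const double v = plane[h + static_cast<size_t>(H) * w];
              if (v > best) {
                best = v;
                besti = h + H * w;
              }
            }
          out[o] = best;
          idx[o] = besti;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(NumericVector dout, IntegerVector idx, int H, int W) {
  IntegerVector dm = dout.attr("dim");
  const int OH = dm[0], OW = dm[1], C = dm[2], N = dm[3];
  NumericVector dx = alloc4d(H, W, C, N);
  const size_t inplane = static_cast<size_t>(H) * W;
  const size_t outplane = static_cast<size_t>(OH) * OW;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *dplane = dx.begin() + (static_cast<size_t>(n) * C + c) * inplane;
      const size_t off = (static_cast<size_t>(n) * C + c) * outplane;
      for (size_t o = 0; o < outplane; ++o)
        dplane[idx[off + o]] += dout[off + o];
    }
  return dx;
}
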