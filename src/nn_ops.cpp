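// Convolutional primitives for the encoder-decoder networks.
// Feature maps are arma::cube (H, W, C), matching R arrays dim = c(H, W, C).
// Pixel linear index is h + w*H (column-major), so mat<->cube reshapes are free.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// im2col for a 3x3 kernel with same (zero) padding.
// Output: (H*W) x (9*C); column c*9 + (dw+1)*3 + (dh+1) holds x(h+dh, w+dw, c).
static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * W, 9 * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        const int col = c * 9 + (dw + 1) * 3 + (dh + 1);
        double* o = out.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          const double* xs = x.slice_colptr(c, ws);
          const int h0 = (dh < 0) ? 1 : 0, h1 = (dh > 0) ? H - 1 : H;
          for (int h = h0; h < h1; ++h) o[h + w * H] = xs[h + dh];
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add (H*W) x (9*C) columns back to an (H,W,C) cube.
static cube col2im3(const mat& dxcol, int H, int W, int C) {
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        const int col = c * 9 + (dw + 1) * 3 + (dh + 1);
        const double* o = dxcol.colptr(col);
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          double* xs = dx.slice_colptr(c, ws);
          const int h0 = (dh < 0) ? 1 : 0, h1 = (dh > 0) ? H - 1 : H;
          for (int h = h0; h < h1; ++h) xs[h + dh] += o[h + w * H];
        }
      }
    }
  }
  return dx;
}

// Double 3x3 convolution block with fused ReLUs. The forward pass keeps its
// im2col matrices and ReLU masks in a C++-side cache (external pointer), so
// the backward pass reuses them instead of recomputing.
struct BlockCache {
  mat xc;      // im2col of the block input
  mat zc;      // im2col of the first activation
  umat mask1;  // ReLU mask after conv1 (pre-activation > 0)
  umat mask2;  // ReLU mask after conv2
  int H, W, Cin;
};

// [[Rcpp::export]]
Rcpp::List nn_block_forward(const arma::cube& x, const arma::mat& W1,
                            const arma::vec& b1, const arma::mat& W2,
                            const arma::vec& b2) {
  const int H = x.n_rows, W = x.n_cols;
  Rcpp::XPtr<BlockCache> cache(new BlockCache, true);
  cache->H = H; cache->W = W; cache->Cin = x.n_slices;
  cache->xc = im2col3(x);
  mat y1 = cache->xc * W1;
  y1.each_row() += b1.t();
  cache->mask1 = y1 > 0;
  y1 %= conv_to<mat>::from(cache->mask1);
  cache->zc = im2col3(cube(y1.memptr(), H, W, W1.n_cols));
  mat y2 = cache->zc * W2;
  y2.each_row() += b2.t();
  cache->mask2 = y2 > 0;
  y2 %= conv_to<mat>::from(cache->mask2);
  return Rcpp::List::create(
      Rcpp::Named("out") = cube(y2.memptr(), H, W, W2.n_cols),
      Rcpp::Named("cache") = cache);
}

// [[Rcpp::export]]
Rcpp::List nn_block_backward(SEXP cache_xp, const arma::mat& W1,
                             const arma::mat& W2, const arma::cube& d_out) {
  Rcpp::XPtr<BlockCache> cache(cache_xp);
  const int H = cache->H, W = cache->W;
  mat dy2(const_cast<double*>(d_out.memptr()), H * W, d_out.n_slices, false);
  mat dy2m = dy2 % conv_to<mat>::from(cache->mask2);
  mat dW2 = cache->zc.t() * dy2m;
  vec db2 = sum(dy2m, 0).t();
  cube dz1 = col2im3(dy2m * W2.t(), H, W, W2.n_rows / 9);
  mat dy1(dz1.memptr(), H * W, dz1.n_slices, false);
  mat dy1m = dy1 % conv_to<mat>::from(cache->mask1);
  mat dW1 = cache->xc.t() * dy1m;
  vec db1 = sum(dy1m, 0).t();
  cube dx = col2im3(dy1m * W1.t(), H, W, cache->Cin);
  return Rcpp::List::create(
      Rcpp::Named("dx") = dx, Rcpp::Named("dW1") = dW1,
      Rcpp::Named("db1") = db1, Rcpp::Named("dW2") = dW2,
      Rcpp::Named("db2") = db2);
}

// Inference-only double-conv block: no cache is built.
// [[Rcpp::export]]
arma::cube nn_block_infer(const arma::cube& x, const arma::mat& W1,
                          const arma::vec& b1, const arma::mat& W2,
                          const arma::vec& b2) {
  const int H = x.n_rows, W = x.n_cols;
  mat y1 = im2col3(x) * W1;
  y1.each_row() += b1.t();
  y1.transform([](double v) { return v > 0 ? v : 0.0; });
  mat y2 = im2col3(cube(y1.memptr(), H, W, W1.n_cols)) * W2;
  y2.each_row() += b2.t();
  y2.transform([](double v) { return v > 0 ? v : 0.0; });
  return cube(y2.memptr(), H, W, W2.n_cols);
}

// 3x3 convolution, stride 1, same padding. Wm: (9*Cin) x Cout.
// [[Rcpp::export]]
arma::cube nn_conv3_forward(const arma::cube& x, const arma::mat& Wm,
                            const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  mat y = im2col3(x) * Wm;
  y.each_row() += b.t();
  return cube(y.memptr(), H, W, Wm.n_cols);
}

// [[Rcpp::export]]
Rcpp::List nn_conv3_backward(const arma::cube& x, const arma::mat& Wm,
                             const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const mat dym(const_cast<double*>(dy.memptr()), H * W, dy.n_slices, false);
  mat xc = im2col3(x);
  mat dW = xc.t() * dym;
  vec db = sum(dym, 0).t();
  cube dx = col2im3(dym * Wm.t(), H, W, Cin);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 1x1 convolution (pointwise projection). Wm: Cin x Cout.
// [[Rcpp::export]]
arma::cube nn_conv1_forward(const arma::cube& x, const arma::mat& Wm,
                            const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const mat xm(const_cast<double*>(x.memptr()), H * W, x.n_slices, false);
  mat y = xm * Wm;
  y.each_row() += b.t();
  return cube(y.memptr(), H, W, Wm.n_cols);
}

// [[Rcpp::export]]
Rcpp::List nn_conv1_backward(const arma::cube& x, const arma::mat& Wm,
                             const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols;
  const mat xm(const_cast<double*>(x.memptr()), H * W, x.n_slices, false);
  const mat dym(const_cast<double*>(dy.memptr()), H * W, dy.n_slices, false);
  mat dW = xm.t() * dym;
  vec db = sum(dym, 0).t();
  mat dxm = dym * Wm.t();
  cube dx(dxm.memptr(), H, W, x.n_slices);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2 (H, W even). Returns pooled cube and the argmax
// position (0..3, encoded dh + 2*dw) needed by the backward pass.
// [[Rcpp::export]]
Rcpp::List nn_maxpool2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  icube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double best = x(2 * h, 2 * w, c);
        int arg = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            const double v = x(2 * h + dh, 2 * w + dw, c);
            if (v > best) { best = v; arg = dh + 2 * dw; }
          }
        y(h, w, c) = best;
        idx(h, w, c) = arg;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube nn_maxpool2_backward(const arma::icube& idx, const arma::cube& dy) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(2 * Ho, 2 * Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const int a = idx(h, w, c);
        dx(2 * h + a % 2, 2 * w + a / 2, c) = dy(h, w, c);
      }
  return dx;
}

// 2x2 transpose convolution, stride 2 (non-overlapping upsampling).
// Wm: Cin x (4*Cout); column co*4 + dh + 2*dw maps x(h,w,.) to y(2h+dh, 2w+dw, co).
// [[Rcpp::export]]
arma::cube nn_upconv2_forward(const arma::cube& x, const arma::mat& Wm,
                              const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = Wm.n_cols / 4;
  const mat xm(const_cast<double*>(x.memptr()), H * W, x.n_slices, false);
  mat ym = xm * Wm;  // (H*W) x (4*Cout)
  cube y(2 * H, 2 * W, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int dw = 0; dw < 2; ++dw)
      for (int dh = 0; dh < 2; ++dh) {
        const double* src = ym.colptr(co * 4 + dh + 2 * dw);
        for (int w = 0; w < W; ++w) {
          double* dst = y.slice_colptr(co, 2 * w + dw);
          for (int h = 0; h < H; ++h) dst[2 * h + dh] = src[h + w * H] + b(co);
        }
      }
  return y;
}

// [[Rcpp::export]]
Rcpp::List nn_upconv2_backward(const arma::cube& x, const arma::mat& Wm,
                               const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  const mat xm(const_cast<double*>(x.memptr()), H * W, Cin, false);
  mat dyg(H * W, 4 * Cout);  // gather dy into im2col-like layout
  vec db(Cout);
  for (int co = 0; co < Cout; ++co) {
    db(co) = accu(dy.slice(co));
    for (int dw = 0; dw < 2; ++dw)
      for (int dh = 0; dh < 2; ++dh) {
        double* dst = dyg.colptr(co * 4 + dh + 2 * dw);
        for (int w = 0; w < W; ++w) {
          const double* src = dy.slice_colptr(co, 2 * w + dw);
          for (int h = 0; h < H; ++h) dst[h + w * H] = src[2 * h + dh];
        }
      }
  }
  mat dW = xm.t() * dyg;
  mat dxm = dyg * Wm.t();
  cube dx(dxm.memptr(), H, W, Cin);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
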