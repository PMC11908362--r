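// Low-level tensor kernels for the interpolation network.
//
// Layout conventions (match R arrays, column-major):
//   feature maps: cube (H, W, C) — row index = image row, fastest-varying
//   conv weights: array (kh, kw, cin, cout), viewed as a (kh*kw*cin) x cout matrix
//   flow fields:  cube (H, W, 2), channel 1 = dx (columns), channel 2 = dy (rows)
//
// Convolutions are im2col + GEMM. Transposed convolutions are expressed in R as
// the adjoint of a forward convolution, so only the three conv kernels below are
// needed for all forward/backward passes (including double backprop for the
// critic's gradient penalty, which composes the same primitives).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Build the im2col matrix: (kh*kw*cin) x (Ho*Wo), zero-padded borders.
static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  arma::mat col(kh * kw * C, Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int j = ho + wo * Ho;
      double* cj = col.colptr(j);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = ho * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            cj[ki + kj * kh + c * kh * kw] = x(h, w, c);
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add a column matrix back onto an image (adjoint of im2col).
static arma::cube col2im(const arma::mat& col, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int j = ho + wo * Ho;
      const double* cj = col.colptr(j);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = ho * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            x(h, w, c) += cj[ki + kj * kh + c * kh * kw];
          }
        }
      }
    }
  }
  return x;
}

static arma::mat weight_view(const NumericVector& Wv, int& kh, int& kw, int& cin, int& cout) {
  IntegerVector d = Wv.attr("dim");
  if (d.size() != 4) stop("conv weights must be a 4-d array (kh, kw, cin, cout)");
  kh = d[0]; kw = d[1]; cin = d[2]; cout = d[3];
  return arma::mat(const_cast<double*>(Wv.begin()), kh * kw * cin, cout, false, true);
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const NumericVector& Wv,
                      const arma::vec& bias, int stride, int pad) {
  int kh, kw, cin, cout;
  arma::mat Wm = weight_view(Wv, kh, kw, cin, cout);
  if ((int)x.n_slices != cin) stop("conv2d: input has %d channels, weights expect %d",
                                   (int)x.n_slices, cin);
  const int Ho = out_size(x.n_rows, kh, stride, pad), Wo = out_size(x.n_cols, kw, stride, pad);
  arma::mat col = im2col(x, kh, kw, stride, pad);
  arma::mat out = col.t() * Wm;                      // (Ho*Wo) x cout
  out.each_row() += bias.t();
  return arma::cube(out.memptr(), Ho, Wo, cout);     // copies
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_bwd_input(const arma::cube& gout, const NumericVector& Wv,
                                int stride, int pad, int H, int W) {
  int kh, kw, cin, cout;
  arma::mat Wm = weight_view(Wv, kh, kw, cin, cout);
  if ((int)gout.n_slices != cout) stop("conv2d_bwd_input: channel mismatch");
  arma::mat gm(const_cast<double*>(gout.memptr()), gout.n_rows * gout.n_cols, cout, false, true);
  arma::mat colg = Wm * gm.t();                      // K x (Ho*Wo)
  return col2im(colg, H, W, cin, kh, kw, stride, pad);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd_weight(const arma::cube& x, const arma::cube& gout,
                           int kh, int kw, int stride, int pad) {
  const int cin = x.n_slices, cout = gout.n_slices;
  arma::mat col = im2col(x, kh, kw, stride, pad);
  arma::mat gm(const_cast<double*>(gout.memptr()), gout.n_rows * gout.n_cols, cout, false, true);
  arma::mat Wg = col * gm;                           // K x cout
  NumericVector Wgv(Wg.begin(), Wg.end());
  Wgv.attr("dim") = IntegerVector::create(kh, kw, cin, cout);
  arma::vec bg = arma::sum(gm, 0).t();
  return List::create(_["W"] = Wgv, _["b"] = bg);
}

// Backward warp: out(h, w) = bilinear sample of img at (w + dx, h + dy),
// coordinates clamped to the image border.
// [[Rcpp::export]]
arma::mat cpp_warp(const arma::mat& img, const arma::cube& flow) {
  const int H = img.n_rows, W = img.n_cols;
  if ((int)flow.n_rows != H || (int)flow.n_cols != W || flow.n_slices != 2)
    stop("warp: flow must be (H, W, 2)");
  arma::mat out(H, W);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      double sx = w + flow(h, w, 0), sy = h + flow(h, w, 1);
      sx = std::min(std::max(sx, 0.0), (double)(W - 1));
      sy = std::min(std::max(sy, 0.0), (double)(H - 1));
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
      const double fx = sx - x0, fy = sy - y0;
      out(h, w) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy       * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  }
  return out;
}

// Gradient of the warped image w.r.t. the flow field (the source image is a
// constant input plane in this network, so no image gradient is needed).
// [[Rcpp::export]]
arma::cube cpp_warp_bwd_flow(const arma::mat& img, const arma::cube& flow,
                             const arma::mat& gout) {
  const int H = img.n_rows, W = img.n_cols;
  arma::cube g(H, W, 2, arma::fill::zeros);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      double sx = w + flow(h, w, 0), sy = h + flow(h, w, 1);
      const bool cx = (sx <= 0.0 || sx >= (double)(W - 1));
      const bool cy = (sy <= 0.0 || sy >= (double)(H - 1));
      sx = std::min(std::max(sx, 0.0), (double)(W - 1));
      sy = std::min(std::max(sy, 0.0), (double)(H - 1));
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
      const double fx = sx - x0, fy = sy - y0;
      const double dvdx = (1 - fy) * (img(y0, x1) - img(y0, x0)) +
                          fy       * (img(y1, x1) - img(y1, x0));
      const double dvdy = (1 - fx) * (img(y1, x0) - img(y0, x0)) +
                          fx       * (img(y1, x1) - img(y0, x1));
      g(h, w, 0) = cx ? 0.0 : gout(h, w) * dvdx;
      g(h, w, 1) = cy ? 0.0 : gout(h, w) * dvdy;
    }
  }
  return g;
}

struct lerp_idx { int i0, i1; double f; };

static std::vector<lerp_idx> axis_map(int n_src, int n_dst) {
  std::vector<lerp_idx> m(n_dst);
  const double scale = (double)n_src / n_dst;
  for (int i = 0; i < n_dst; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    s = std::min(std::max(s, 0.0), (double)(n_src - 1));
    const int i0 = (int)std::floor(s);
    m[i].i0 = i0;
    m[i].i1 = std::min(i0 + 1, n_src - 1);
    m[i].f = s - i0;
  }
  return m;
}

// Bilinear resize (half-pixel centre alignment), channel-wise.
// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube& x, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  std::vector<lerp_idx> mh = axis_map(H, Ho), mw = axis_map(W, Wo);
  arma::cube out(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const lerp_idx& ah = mh[h]; const lerp_idx& aw = mw[w];
        out(h, w, c) =
          (1 - ah.f) * ((1 - aw.f) * x(ah.i0, aw.i0, c) + aw.f * x(ah.i0, aw.i1, c)) +
          ah.f       * ((1 - aw.f) * x(ah.i1, aw.i0, c) + aw.f * x(ah.i1, aw.i1, c));
      }
  return out;
}

// Exact adjoint of cpp_resize_bilinear (scatter with the same weights).
// [[Rcpp::export]]
arma::cube cpp_resize_bilinear_adj(const arma::cube& g, int H, int W) {
  const int Ho = g.n_rows, Wo = g.n_cols, C = g.n_slices;
  std::vector<lerp_idx> mh = axis_map(H, Ho), mw = axis_map(W, Wo);
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const lerp_idx& ah = mh[h]; const lerp_idx& aw = mw[w];
        const double v = g(h, w, c);
        out(ah.i0, aw.i0, c) += (1 - ah.f) * (1 - aw.f) * v;
        out(ah.i0, aw.i1, c) += (1 - ah.f) * aw.f * v;
        out(ah.i1, aw.i0, c) += ah.f * (1 - aw.f) * v;
        out(ah.i1, aw.i1, c) += ah.f * aw.f * v;
      }
  return out;
}
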