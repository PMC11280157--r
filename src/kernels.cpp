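// Numerical kernels for the Attention U-Net and mask post-processing.
//
// Layout convention: a mini-batch of feature maps is an arma::cube of
// dimension H x W x (N*C), slice index = n*C + c (0-based), i.e. the
// channels of sample n are contiguous. This matches an R array of
// dim c(H, W, C, N) flattened over its last two dimensions.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// im2col / col2im for same-padded k x k convolution (k odd)

// patches-by-rows layout: colsT is (N*H*W) x (cin*k*k), so every copy in
// both directions is a contiguous run over the row index h
static arma::mat im2col_batch(const arma::cube& x, int k, int n, int cin) {
  const int H = x.n_rows, W = x.n_cols, p = k / 2;
  const int K = cin * k * k;
  const size_t HW = (size_t)H * W, NHW = (size_t)n * HW;
  arma::mat colsT(NHW, K, arma::fill::zeros);
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < cin; ++c) {
      const double* sm = x.slice_memptr((size_t)s * cin + c);
      for (int dw = 0; dw < k; ++dw) {
        for (int dh = 0; dh < k; ++dh) {
          const int col = c * k * k + dw * k + dh;
          double* cp = colsT.colptr(col) + s * HW;
          // output position (h, w) reads input (h + dh - p, w + dw - p)
          for (int w = 0; w < W; ++w) {
            const int iw = w + dw - p;
            if (iw < 0 || iw >= W) continue;
            const int h0 = std::max(0, p - dh), h1 = std::min(H, H + p - dh);
            std::memcpy(cp + (size_t)w * H + h0,
                        sm + (size_t)iw * H + (h0 + dh - p),
                        (h1 - h0) * sizeof(double));
          }
        }
      }
    }
  }
  return colsT;
}

static arma::cube col2im_batch(const arma::mat& gcolsT, int k, int n, int cin,
                               int H, int W) {
  const int p = k / 2;
  const size_t HW = (size_t)H * W;
  arma::cube gx(H, W, (size_t)n * cin, arma::fill::zeros);
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < cin; ++c) {
      double* sm = gx.slice_memptr((size_t)s * cin + c);
      for (int dw = 0; dw < k; ++dw) {
        for (int dh = 0; dh < k; ++dh) {
          const int col = c * k * k + dw * k + dh;
          const double* cp = gcolsT.colptr(col) + s * HW;
          for (int w = 0; w < W; ++w) {
            const int iw = w + dw - p;
            if (iw < 0 || iw >= W) continue;
            const int h0 = std::max(0, p - dh), h1 = std::min(H, H + p - dh);
            double* dst = sm + (size_t)iw * H + (h0 + dh - p);
            const double* src = cp + (size_t)w * H + h0;
            for (int h = h0; h < h1; ++h) *dst++ += *src++;
          }
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
List cpp_conv2d_fwd(const arma::cube& x, const arma::mat& Wm,
                    const arma::vec& b, int k, int n, bool keep_cols) {
  const int H = x.n_rows, W = x.n_cols;
  const int cin = Wm.n_cols / (k * k), cout = Wm.n_rows;
  const size_t HW = (size_t)H * W;
  arma::mat colsT = im2col_batch(x, k, n, cin);
  arma::mat outT = colsT * Wm.t();          // (N*H*W) x cout
  outT.each_row() += b.t();
  arma::cube y(H, W, (size_t)n * cout);
  for (int s = 0; s < n; ++s)
    for (int c = 0; c < cout; ++c)
      std::memcpy(y.slice_memptr((size_t)s * cout + c),
                  outT.colptr(c) + s * HW, HW * sizeof(double));
  if (keep_cols) return List::create(_["out"] = y, _["cols"] = colsT);
  return List::create(_["out"] = y);
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(const arma::cube& gout, const arma::mat& colsT,
                    const arma::mat& Wm, int k, int n) {
  const int H = gout.n_rows, W = gout.n_cols;
  const int cin = Wm.n_cols / (k * k), cout = Wm.n_rows;
  const size_t HW = (size_t)H * W, NHW = (size_t)n * HW;
  arma::mat gmT(NHW, cout);
  for (int s = 0; s < n; ++s)
    for (int c = 0; c < cout; ++c)
      std::memcpy(gmT.colptr(c) + s * HW,
                  gout.slice_memptr((size_t)s * cout + c),
                  HW * sizeof(double));
  arma::mat gW = (colsT.t() * gmT).t();     // cout x (cin*k*k)
  arma::vec gb = arma::sum(gmT, 0).t();
  arma::mat gcolsT = gmT * Wm;              // (N*H*W) x (cin*k*k)
  arma::cube gx = col2im_batch(gcolsT, k, n, cin, H, W);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// 2x2 max pooling, stride 2

// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, S = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, S);
  arma::ucube idx(Ho, Wo, S);  // linear index within the input slice
  for (int s = 0; s < S; ++s) {
    const arma::mat& sl = x.slice(s);
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        int bh = 2 * h, bw = 2 * w;
        double best = sl(bh, bw);
        int bi = bh, bj = bw;
        if (sl(bh + 1, bw) > best) { best = sl(bh + 1, bw); bi = bh + 1; }
        if (sl(bh, bw + 1) > best) { best = sl(bh, bw + 1); bi = bh; bj = bw + 1; }
        if (sl(bh + 1, bw + 1) > best) { best = sl(bh + 1, bw + 1); bi = bh + 1; bj = bw + 1; }
        y(h, w, s) = best;
        idx(h, w, s) = (size_t)bj * H + bi;
      }
    }
  }
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
arma::cube cpp_maxpool2_bwd(const arma::cube& gout, const arma::ucube& idx,
                            int H, int W) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, S = gout.n_slices;
  arma::cube gx(H, W, S, arma::fill::zeros);
  for (int s = 0; s < S; ++s)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        gx.slice(s)(idx(h, w, s)) += gout(h, w, s);
  return gx;
}

// ---------------------------------------------------------------------------
// bilinear x2 upsampling (half-pixel centres) and its exact adjoint

static void up2_weights(int Ho, int H, arma::ivec& i0, arma::ivec& i1,
                        arma::vec& w1) {
  i0.set_size(Ho); i1.set_size(Ho); w1.set_size(Ho);
  for (int o = 0; o < Ho; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;
    int lo = (int)std::floor(src);
    double f = src - lo;
    int a = std::min(std::max(lo, 0), H - 1);
    int b = std::min(std::max(lo + 1, 0), H - 1);
    i0(o) = a; i1(o) = b; w1(o) = f;
  }
}

// [[Rcpp::export(name = ".cpp_upsample2_fwd")]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, S = x.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  arma::ivec ri0, ri1, ci0, ci1; arma::vec rw, cw;
  up2_weights(Ho, H, ri0, ri1, rw);
  up2_weights(Wo, W, ci0, ci1, cw);
  arma::cube y(Ho, Wo, S);
  for (int s = 0; s < S; ++s) {
    const arma::mat& sl = x.slice(s);
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double top = (1 - cw(w)) * sl(ri0(h), ci0(w)) + cw(w) * sl(ri0(h), ci1(w));
        double bot = (1 - cw(w)) * sl(ri1(h), ci0(w)) + cw(w) * sl(ri1(h), ci1(w));
        y(h, w, s) = (1 - rw(h)) * top + rw(h) * bot;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample2_bwd")]]
arma::cube cpp_upsample2_bwd(const arma::cube& gout, int H, int W) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, S = gout.n_slices;
  arma::ivec ri0, ri1, ci0, ci1; arma::vec rw, cw;
  up2_weights(Ho, H, ri0, ri1, rw);
  up2_weights(Wo, W, ci0, ci1, cw);
  arma::cube gx(H, W, S, arma::fill::zeros);
  for (int s = 0; s < S; ++s) {
    arma::mat& g = gx.slice(s);
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double v = gout(h, w, s);
        g(ri0(h), ci0(w)) += (1 - rw(h)) * (1 - cw(w)) * v;
        g(ri0(h), ci1(w)) += (1 - rw(h)) * cw(w) * v;
        g(ri1(h), ci0(w)) += rw(h) * (1 - cw(w)) * v;
        g(ri1(h), ci1(w)) += rw(h) * cw(w) * v;
      }
    }
  }
  return gx;
}

// ---------------------------------------------------------------------------
// 2-D connected component labelling (4- or 8-connectivity), BFS

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int>> nb;
  nb.push_back({-1, 0}); nb.push_back({1, 0});
  nb.push_back({0, -1}); nb.push_back({0, 1});
  if (connectivity == 8) {
    nb.push_back({-1, -1}); nb.push_back({-1, 1});
    nb.push_back({1, -1}); nb.push_back({1, 1});
  }
  int cur = 0;
  std::vector<std::pair<int,int>> stack;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      ++cur;
      stack.clear();
      stack.push_back({h, w});
      lab(h, w) = cur;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (size_t q = 0; q < nb.size(); ++q) {
          int nh = p.first + nb[q].first, nw = p.second + nb[q].second;
          if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
          if (mask(nh, nw) != 0 && lab(nh, nw) == 0) {
            lab(nh, nw) = cur;
            stack.push_back({nh, nw});
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// in-place rotation about the image centre; bilinear for images,
// nearest-neighbour for label maps; out-of-support samples take `fill`

// [[Rcpp::export(name = ".cpp_rotate2d")]]
NumericMatrix cpp_rotate2d(const NumericMatrix& img, double angle_deg,
                           bool bilinear, double fill) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      // inverse map: rotate output coords by -angle to find the source
      double dy = h - cy, dx = w - cx;
      double sy = ct * dy + st * dx + cy;
      double sx = -st * dy + ct * dx + cx;
      if (bilinear) {
        int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
        double fy = sy - y0, fx = sx - x0;
        double acc = 0.0;
        for (int dyy = 0; dyy <= 1; ++dyy) {
          for (int dxx = 0; dxx <= 1; ++dxx) {
            int yy = y0 + dyy, xx = x0 + dxx;
            double wgt = (dyy ? fy : 1 - fy) * (dxx ? fx : 1 - fx);
            double v = (yy < 0 || yy >= H || xx < 0 || xx >= W) ? fill : img(yy, xx);
            acc += wgt * v;
          }
        }
        out(h, w) = acc;
      } else {
        int yy = (int)std::lround(sy), xx = (int)std::lround(sx);
        out(h, w) = (yy < 0 || yy >= H || xx < 0 || xx >= W) ? fill : img(yy, xx);
      }
    }
  }
  return out;
}
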