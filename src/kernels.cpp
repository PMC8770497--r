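// Low-level numerical kernels for the FC-DenseNet engine and the
// preprocessing convolution. Activations are H x W x C cubes (R arrays,
// column-major); convolution weights are flat (k*k*Cin) x Cout matrices with
// row index r = c*k*k + dj*k + di for kernel offset (di, dj), channel c.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for stride-1 "same" convolution: rows index output pixels in
// column-major (h + w*H) order, columns index (channel, dj, di). The h-run
// for fixed (c, dj, di, w) is contiguous in both source and destination.
static arma::mat im2col_same(const arma::cube& x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        double* cr = col.colptr(r);
        const int h0 = std::max(0, pad - di);           // first valid out row
        const int h1 = std::min(H, H + pad - di);       // one past last
        if (h1 <= h0) continue;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dj - pad;
          if (sw < 0 || sw >= W) continue;
          std::memcpy(cr + (h0 + w * H),
                      xs + ((h0 + di - pad) + sw * H),
                      (h1 - h0) * sizeof(double));
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& W, const arma::vec& b,
                      int k, int pad) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_cols;
  arma::mat y = im2col_same(x, k, pad) * W;
  y.each_row() += b.t();
  return arma::cube(y.memptr(), H, Wd, Cout);
}

// [[Rcpp::export]]
List conv2d_bwd(const arma::cube& x, const arma::mat& W, const arma::cube& dy,
                int k, int pad) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Cout = dy.n_slices;
  arma::mat dyM(const_cast<double*>(dy.memptr()), H * Wd, Cout, false, true);
  arma::mat col = im2col_same(x, k, pad);
  arma::mat dW = col.t() * dyM;
  arma::vec db = arma::sum(dyM, 0).t();
  arma::mat dcol = dyM * W.t();
  arma::cube dx(H, Wd, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xs = dx.slice_memptr(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        const double* cr = dcol.colptr(r);
        const int h0 = std::max(0, pad - di);
        const int h1 = std::min(H, H + pad - di);
        if (h1 <= h0) continue;
        for (int w = 0; w < Wd; ++w) {
          const int sw = w + dj - pad;
          if (sw < 0 || sw >= Wd) continue;
          double* dst = xs + ((h0 + di - pad) + sw * H);
          const double* src = cr + (h0 + w * H);
          for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 3x3 transposed convolution, stride 2, pad 1, output 2H x 2W
// (output pixel o = 2*i + d - 1 for kernel offset d in {0,1,2}).
// [[Rcpp::export]]
arma::cube convt2d_fwd(const arma::cube& x, const arma::mat& W, const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols, k = 3;
  arma::cube y(2 * H, 2 * Wd, Cout);
  for (int co = 0; co < Cout; ++co) y.slice(co).fill(b(co));
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xs = x.slice_memptr(ci);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = ci * k * k + dj * k + di;
        const int hlo = (di == 0) ? 1 : 0;              // oh = 2h+di-1 >= 0
        const int hhi = H;                              // oh = 2h+di-1 <= 2H-1 always
        for (int co = 0; co < Cout; ++co) {
          const double wv = W(r, co);
          if (wv == 0.0) continue;
          double* ys = y.slice_memptr(co);
          for (int w = 0; w < Wd; ++w) {
            const int ow = 2 * w + dj - 1;
            if (ow < 0 || ow >= 2 * Wd) continue;
            double* yc = ys + ow * 2 * H + di - 1;
            const double* xc = xs + w * H;
            for (int h = hlo; h < hhi; ++h) yc[2 * h] += wv * xc[h];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List convt2d_bwd(const arma::cube& x, const arma::mat& W, const arma::cube& dy) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices, k = 3;
  arma::cube dx(H, Wd, Cin, arma::fill::zeros);
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) db(co) = arma::accu(dy.slice(co));
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xs = x.slice_memptr(ci);
    double* dxs = dx.slice_memptr(ci);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = ci * k * k + dj * k + di;
        const int hlo = (di == 0) ? 1 : 0;
        const int hhi = H;                              // oh = 2h+di-1 <= 2H-1 always
        for (int co = 0; co < Cout; ++co) {
          const double wv = W(r, co);
          const double* gs = dy.slice_memptr(co);
          double acc = 0.0;
          for (int w = 0; w < Wd; ++w) {
            const int ow = 2 * w + dj - 1;
            if (ow < 0 || ow >= 2 * Wd) continue;
            const double* gc = gs + ow * 2 * H + di - 1;
            const double* xc = xs + w * H;
            double* dxc = dxs + w * H;
            for (int h = hlo; h < hhi; ++h) {
              const double g = gc[2 * h];
              acc += g * xc[h];
              dxc[h] += g * wv;
            }
          }
          dW(r, co) += acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2; idx records the winning offset 0..3
// (dh + 2*dw) per output cell for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  int p = 0;
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double best = x(2 * h, 2 * w, c);
        int bi = 0;
        for (int dw = 0; dw < 2; ++dw) {
          for (int dh = 0; dh < 2; ++dh) {
            const double v = x(2 * h + dh, 2 * w + dw, c);
            if (v > best) { best = v; bi = dh + 2 * dw; }
          }
        }
        y(h, w, c) = best;
        idx[p++] = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& dy, const IntegerVector& idx,
                        int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  int p = 0;
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const int bi = idx[p++];
        dx(2 * h + bi % 2, 2 * w + bi / 2, c) = dy(h, w, c);
      }
    }
  }
  return dx;
}

// Mirror index (reflect without repeating the edge pixel), valid for any
// out-of-range distance; n == 1 collapses to 0.
static int reflect_idx(int s, int n) {
  if (n == 1) return 0;
  const int period = 2 * (n - 1);
  s = s % period;
  if (s < 0) s += period;
  return (s >= n) ? period - s : s;
}

// 2-D correlation with mirror padding for the Gaussian preprocessing filter;
// kernel is odd-sized.
// [[Rcpp::export]]
arma::mat conv2d_reflect(const arma::mat& img, const arma::mat& kernel) {
  const int H = img.n_rows, W = img.n_cols;
  const int kh = kernel.n_rows, kw = kernel.n_cols;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::mat out(H, W, arma::fill::zeros);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      double acc = 0.0;
      for (int b = 0; b < kw; ++b) {
        const int sw = reflect_idx(w + b - pw, W);
        for (int a = 0; a < kh; ++a) {
          const int sh = reflect_idx(h + a - ph, H);
          acc += kernel(a, b) * img(sh, sw);
        }
      }
      out(h, w) = acc;
    }
  }
  return out;
}
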