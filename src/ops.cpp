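// Numerical kernels for CPU training/inference of the segmentation networks.
// Tensors are R arrays with dim (H, W, C, N), column-major:
//   index = h + H*(w + W*(c + C*n)).
// Convolutions use zero ("same") padding and stride 1; im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C,
                             int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for one sample: out (H*W) x (k*k*Cin), zero padding, dilation.
static void im2col(const double* x, int H, int W, int Cin, int k, int dil,
                   arma::mat& M) {
  const int r = (k - 1) / 2;
  const int HW = H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)HW * ci;
    for (int kw = 0; kw < k; ++kw) {
      const int dw = (kw - r) * dil;
      for (int kh = 0; kh < k; ++kh) {
        const int dh = (kh - r) * dil;
        const int j = kh + k * (kw + k * ci);
        double* col = M.colptr(j);
        for (int w = 0; w < W; ++w) {
          const int ww = w + dw;
          if (ww < 0 || ww >= W) {
            std::fill(col + (size_t)H * w, col + (size_t)H * (w + 1), 0.0);
            continue;
          }
          const double* src = xc + (size_t)H * ww;
          double* dst = col + (size_t)H * w;
          for (int h = 0; h < H; ++h) {
            const int hh = h + dh;
            dst[h] = (hh < 0 || hh >= H) ? 0.0 : src[hh];
          }
        }
      }
    }
  }
}

// scatter-add of a column matrix back to the input grid (adjoint of im2col)
static void col2im_add(const arma::mat& M, int H, int W, int Cin, int k,
                       int dil, double* gx) {
  const int r = (k - 1) / 2;
  const int HW = H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    double* gc = gx + (size_t)HW * ci;
    for (int kw = 0; kw < k; ++kw) {
      const int dw = (kw - r) * dil;
      for (int kh = 0; kh < k; ++kh) {
        const int dh = (kh - r) * dil;
        const int j = kh + k * (kw + k * ci);
        const double* col = M.colptr(j);
        for (int w = 0; w < W; ++w) {
          const int ww = w + dw;
          if (ww < 0 || ww >= W) continue;
          double* dst = gc + (size_t)H * ww;
          const double* src = col + (size_t)H * w;
          for (int h = 0; h < H; ++h) {
            const int hh = h + dh;
            if (hh >= 0 && hh < H) dst[hh] += src[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int dilation) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("weight/input channel mismatch");
  const int HW = H * W, kkC = k * k * Cin;
  arma::mat Wm(const_cast<double*>(w.begin()), kkC, Cout, false, true);
  NumericVector y((size_t)HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat M(HW, kkC);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)HW * Cin * n, H, W, Cin, k, dilation, M);
    arma::mat Y(y.begin() + (size_t)HW * Cout * n, HW, Cout, false, true);
    Y = M * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int dilation) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cout = wd[3];
  const int HW = H * W, kkC = k * k * Cin;
  arma::mat Wm(const_cast<double*>(w.begin()), kkC, Cout, false, true);
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  arma::mat Gw(gw.begin(), kkC, Cout, false, true);
  arma::mat M(HW, kkC), Gcol(HW, kkC);
  for (int n = 0; n < N; ++n) {
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)HW * Cout * n, HW,
                 Cout, false, true);
    im2col(x.begin() + (size_t)HW * Cin * n, H, W, Cin, k, dilation, M);
    Gw += M.t() * Gy;
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(Gy.col(co));
    Gcol = Gy * Wm.t();
    col2im_add(Gcol, H, W, Cin, k, dilation,
               gx.begin() + (size_t)HW * Cin * n);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, kernel 2x2 stride 2 (the U-Net up-sampling step).
// w dims (2, 2, Cin, Cout); output (2H, 2W, Cout, N).
// [[Rcpp::export]]
NumericVector cpp_convt2_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  if (wd[2] != Cin) stop("weight/input channel mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    double* yn = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (size_t)Ho * Wo * co;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] = b[co];
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = xn + (size_t)H * W * ci;
        const double* wk = w.begin() + 4 * (ci + Cin * co);  // (a,b) block
        for (int ww = 0; ww < W; ++ww)
          for (int h = 0; h < H; ++h) {
            const double v = xc[h + (size_t)H * ww];
            double* base = yc + (size_t)Ho * (2 * ww) + 2 * h;
            base[0] += v * wk[0];
            base[1] += v * wk[1];
            base[Ho] += v * wk[2];
            base[Ho + 1] += v * wk[3];
          }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Cout);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * Cin * n;
    const double* gyn = gy.begin() + (size_t)Ho * Wo * Cout * n;
    double* gxn = gx.begin() + (size_t)H * W * Cin * n;
    for (int co = 0; co < Cout; ++co) {
      const double* gc = gyn + (size_t)Ho * Wo * co;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) gb[co] += gc[i];
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = xn + (size_t)H * W * ci;
        double* gxc = gxn + (size_t)H * W * ci;
        double* gwk = gw.begin() + 4 * (ci + Cin * co);
        const double* wk = w.begin() + 4 * (ci + Cin * co);
        for (int ww = 0; ww < W; ++ww)
          for (int h = 0; h < H; ++h) {
            const double* base = gc + (size_t)Ho * (2 * ww) + 2 * h;
            const double v = xc[h + (size_t)H * ww];
            gwk[0] += v * base[0];
            gwk[1] += v * base[1];
            gwk[2] += v * base[Ho];
            gwk[3] += v * base[Ho + 1];
            gxc[h + (size_t)H * ww] += wk[0] * base[0] + wk[1] * base[1] +
                                       wk[2] * base[Ho] +
                                       wk[3] * base[Ho + 1];
          }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and the in-window argmax
// offset (0..3, column-major within the window) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("max pooling requires even height and width");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  size_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = x.begin() + (size_t)H * W * cn;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h, ++o) {
        const double* base = xc + (size_t)H * (2 * w) + 2 * h;
        double best = base[0];
        int bi = 0;
        if (base[1] > best) { best = base[1]; bi = 1; }
        if (base[H] > best) { best = base[H]; bi = 2; }
        if (base[H + 1] > best) { best = base[H + 1]; bi = 3; }
        y[o] = best;
        idx[o] = bi;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx, int H,
                               int W) {
  IntegerVector d = gy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    double* gc = gx.begin() + (size_t)H * W * cn;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h, ++o) {
        const int bi = idx[o];
        gc[2 * h + (bi & 1) + (size_t)H * (2 * w + (bi >> 1))] += gy[o];
      }
  }
  return gx;
}

// Bilinear resize with the half-pixel (area-aligned) convention:
//   src = (dst + 0.5) * in/out - 0.5, clamped.
static void bilin_coeffs(int in, int out, std::vector<int>& i0,
                         std::vector<int>& i1, std::vector<double>& a) {
  i0.resize(out); i1.resize(out); a.resize(out);
  const double s = (double)in / out;
  for (int o = 0; o < out; ++o) {
    double src = (o + 0.5) * s - 0.5;
    if (src < 0) src = 0;
    if (src > in - 1) src = in - 1;
    int lo = (int)std::floor(src);
    int hi = lo + 1 < in ? lo + 1 : lo;
    i0[o] = lo; i1[o] = hi; a[o] = src - lo;
  }
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> ah, aw;
  bilin_coeffs(H, Ho, h0, h1, ah);
  bilin_coeffs(W, Wo, w0, w1, aw);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = x.begin() + (size_t)H * W * cn;
    for (int w = 0; w < Wo; ++w) {
      const double* cl = xc + (size_t)H * w0[w];
      const double* ch = xc + (size_t)H * w1[w];
      for (int h = 0; h < Ho; ++h, ++o) {
        const double t = ah[h], u = aw[w];
        y[o] = (1 - u) * ((1 - t) * cl[h0[h]] + t * cl[h1[h]]) +
               u * ((1 - t) * ch[h0[h]] + t * ch[h1[h]]);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector gy, int H, int W) {
  IntegerVector d = gy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> ah, aw;
  bilin_coeffs(H, Ho, h0, h1, ah);
  bilin_coeffs(W, Wo, w0, w1, aw);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    double* gc = gx.begin() + (size_t)H * W * cn;
    for (int w = 0; w < Wo; ++w) {
      double* cl = gc + (size_t)H * w0[w];
      double* ch = gc + (size_t)H * w1[w];
      for (int h = 0; h < Ho; ++h, ++o) {
        const double t = ah[h], u = aw[w], g = gy[o];
        cl[h0[h]] += (1 - u) * (1 - t) * g;
        cl[h1[h]] += (1 - u) * t * g;
        ch[h0[h]] += u * (1 - t) * g;
        ch[h1[h]] += u * t * g;
      }
    }
  }
  return gx;
}

// 8-connected component labelling of a binary matrix (flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!m(h, w) || lab(h, w)) continue;
      ++next;
      stack.push_back(std::make_pair(h, w));
      lab(h, w) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh) {
            const int hh = p.first + dh, ww = p.second + dw;
            if (hh < 0 || hh >= H || ww < 0 || ww >= W) continue;
            if (m(hh, ww) && !lab(hh, ww)) {
              lab(hh, ww) = next;
              stack.push_back(std::make_pair(hh, ww));
            }
          }
      }
    }
  return lab;
}
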