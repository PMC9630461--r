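// Low-level numerical kernels for the UNet: same-padding convolution
// (im2col + GEMM), depthwise convolution, 2x2 max pooling, 2x2 stride-2
// transposed convolution, separable Gaussian blur, and a brute-force
// multiply-accumulate counter used as an independent oracle for the
// analytic convolution-cost formulas.
//
// Array layout matches R: cube (H, W, C) column-major, i.e. element
// (r, c, s) sits at r + c*H + s*H*W.  Convolution weights arrive as a
// 4-d R array (k, k, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col for same-padding k x k convolution, transposed layout:
// Kt is (H*W) x (Cin*k*k) with column r = i + k*j + k*k*c (i = kernel row
// offset, j = col offset, c = input channel) -- the same ordering as the
// (k,k,Cin,Cout) weight array, so the weight matrix is a zero-copy reshape
// and the GEMM result lands directly in the output cube's memory layout.
// Runs over output rows are contiguous in both x and Kt.
static arma::mat im2col_same_t(const arma::cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  arma::mat Kt(H * W, C * k * k, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice(c).memptr();
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        double* kc = Kt.colptr(i + k * j + k * k * c);
        const int r0 = std::max(0, pad - i);            // valid output rows
        const int r1 = std::min(H, H + pad - i);
        for (int oc = 0; oc < W; ++oc) {
          const int sc = oc + j - pad;
          if (sc < 0 || sc >= W) continue;
          std::memcpy(kc + oc * H + r0, xs + sc * H + (r0 + i - pad),
                      sizeof(double) * (r1 - r0));
        }
      }
    }
  }
  return Kt;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const NumericVector& w,
                      const arma::vec& bias, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = bias.n_elem;
  const arma::mat Wt(const_cast<double*>(&w[0]), k * k * Cin, Cout,
                     false, true);
  arma::cube y(H, W, Cout);
  arma::mat Ym(y.memptr(), H * W, Cout, false, true);
  if (k == 1) {
    const arma::mat Xm(const_cast<double*>(x.memptr()), H * W, Cin,
                       false, true);
    Ym = Xm * Wt;
  } else {
    Ym = im2col_same_t(x, k) * Wt;
  }
  Ym.each_row() += bias.t();
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(const arma::cube& x, const NumericVector& w,
                const arma::cube& dy, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  const int pad = (k - 1) / 2;
  const arma::mat Wt(const_cast<double*>(&w[0]), k * k * Cin, Cout,
                     false, true);
  const arma::mat dY(const_cast<double*>(dy.memptr()), H * W, Cout,
                     false, true);
  NumericVector dw(k * k * Cin * Cout);
  arma::mat dWt(&dw[0], k * k * Cin, Cout, false, true);
  arma::vec db = arma::sum(dY, 0).t();
  arma::cube dx(H, W, Cin, arma::fill::zeros);

  if (k == 1) {
    const arma::mat Xm(const_cast<double*>(x.memptr()), H * W, Cin,
                       false, true);
    dWt = Xm.t() * dY;
    arma::mat dXm(dx.memptr(), H * W, Cin, false, true);
    dXm = dY * Wt.t();
    dw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  }

  arma::mat Kt = im2col_same_t(x, k);
  dWt = Kt.t() * dY;
  arma::mat dKt = dY * Wt.t();                  // (H*W) x (Cin*k*k)
  // col2im: scatter-add dKt back onto input pixels (contiguous row runs)
  for (int c = 0; c < Cin; ++c) {
    double* dxs = dx.slice(c).memptr();
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const double* kc = dKt.colptr(i + k * j + k * k * c);
        const int r0 = std::max(0, pad - i);
        const int r1 = std::min(H, H + pad - i);
        for (int oc = 0; oc < W; ++oc) {
          const int sc = oc + j - pad;
          if (sc < 0 || sc >= W) continue;
          double* dst = dxs + sc * H + (r0 + i - pad);
          const double* src = kc + oc * H + r0;
          for (int r = 0; r < r1 - r0; ++r) dst[r] += src[r];
        }
      }
    }
  }
  dw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// depthwise same-padding k x k convolution, weights (k,k,C), no bias
// [[Rcpp::export]]
arma::cube dwconv2d_fwd(const arma::cube& x, const NumericVector& w, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  arma::cube y(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int oc = 0; oc < W; ++oc)
      for (int orr = 0; orr < H; ++orr) {
        double acc = 0.0;
        for (int j = 0; j < k; ++j) {
          const int sc = oc + j - pad;
          if (sc < 0 || sc >= W) continue;
          for (int i = 0; i < k; ++i) {
            const int sr = orr + i - pad;
            if (sr < 0 || sr >= H) continue;
            acc += x(sr, sc, c) * w[i + k * (j + k * c)];
          }
        }
        y(orr, oc, c) = acc;
      }
  return y;
}

// [[Rcpp::export]]
List dwconv2d_bwd(const arma::cube& x, const NumericVector& w,
                  const arma::cube& dy, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  arma::cube dx(H, W, C, arma::fill::zeros);
  NumericVector dw(k * k * C);
  for (int c = 0; c < C; ++c)
    for (int oc = 0; oc < W; ++oc)
      for (int orr = 0; orr < H; ++orr) {
        const double g = dy(orr, oc, c);
        if (g == 0.0) continue;
        for (int j = 0; j < k; ++j) {
          const int sc = oc + j - pad;
          if (sc < 0 || sc >= W) continue;
          for (int i = 0; i < k; ++i) {
            const int sr = orr + i - pad;
            if (sr < 0 || sr >= H) continue;
            dx(sr, sc, c) += g * w[i + k * (j + k * c)];
            dw[i + k * (j + k * c)] += g * x(sr, sc, c);
          }
        }
      }
  dw.attr("dim") = IntegerVector::create(k, k, C);
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// 2x2 max pooling, stride 2; H and W must be even.
// Returns pooled cube and 0-based linear argmax indices into the input cube.
// [[Rcpp::export]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  int q = 0;
  for (int c = 0; c < C; ++c)
    for (int oc = 0; oc < Wo; ++oc)
      for (int orr = 0; orr < Ho; ++orr) {
        double best = -1e300; int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int sr = 2 * orr + di, sc = 2 * oc + dj;
            const double v = x(sr, sc, c);
            if (v > best) { best = v; bi = sr + sc * H + c * H * W; }
          }
        y(orr, oc, c) = best;
        idx[q++] = bi;
      }
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& dy, const IntegerVector& idx,
                        const int H, const int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  const int n = dy.n_elem;
  const double* g = dy.memptr();
  double* out = dx.memptr();
  for (int q = 0; q < n; ++q) out[idx[q]] += g[q];
  return dx;
}

// 2x2 stride-2 transposed convolution ("up-convolution"):
// out(2i+a, 2j+b, o) = sum_c x(i,j,c) * w(a,b,c,o) + bias(o)
// [[Rcpp::export]]
arma::cube upconv2_fwd(const arma::cube& x, const NumericVector& w,
                       const arma::vec& bias) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = bias.n_elem;
  arma::mat Xm(const_cast<double*>(x.memptr()), H * W, Cin, false, true);
  arma::cube y(2 * H, 2 * W, Cout);
  for (int b = 0; b < 2; ++b)
    for (int a = 0; a < 2; ++a) {
      arma::mat Wab(Cin, Cout);
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c)
          Wab(c, o) = w[a + 2 * (b + 2 * (c + Cin * o))];
      arma::mat O = Xm * Wab;               // HW x Cout
      for (int o = 0; o < Cout; ++o)
        for (int p = 0; p < H * W; ++p)
          y(2 * (p % H) + a, 2 * (p / H) + b, o) = O(p, o) + bias(o);
    }
  return y;
}

// [[Rcpp::export]]
List upconv2_bwd(const arma::cube& x, const NumericVector& w,
                 const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  arma::mat Xm(const_cast<double*>(x.memptr()), H * W, Cin, false, true);
  arma::mat dXm(H * W, Cin, arma::fill::zeros);
  NumericVector dw(2 * 2 * Cin * Cout);
  arma::vec db(Cout, arma::fill::zeros);
  for (int b = 0; b < 2; ++b)
    for (int a = 0; a < 2; ++a) {
      arma::mat dO(H * W, Cout);
      for (int o = 0; o < Cout; ++o)
        for (int p = 0; p < H * W; ++p)
          dO(p, o) = dy(2 * (p % H) + a, 2 * (p / H) + b, o);
      arma::mat Wab(Cin, Cout);
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c)
          Wab(c, o) = w[a + 2 * (b + 2 * (c + Cin * o))];
      arma::mat dWab = Xm.t() * dO;         // Cin x Cout
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c)
          dw[a + 2 * (b + 2 * (c + Cin * o))] = dWab(c, o);
      dXm += dO * Wab.t();
      db += arma::sum(dO, 0).t();
    }
  arma::cube dx(H, W, Cin);
  std::memcpy(dx.memptr(), dXm.memptr(), sizeof(double) * dXm.n_elem);
  dw.attr("dim") = IntegerVector::create(2, 2, Cin, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// separable Gaussian blur with reflected edges
// [[Rcpp::export]]
arma::mat gaussian_blur_mat(const arma::mat& m, const double sigma) {
  if (sigma <= 0) return m;
  const int H = m.n_rows, W = m.n_cols;
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  arma::vec kern(2 * rad + 1);
  for (int i = -rad; i <= rad; ++i)
    kern(i + rad) = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
  kern /= arma::accu(kern);
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  arma::mat tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) acc += kern(i + rad) * m(reflect(r + i, H), c);
      tmp(r, c) = acc;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) acc += kern(i + rad) * tmp(r, reflect(c + i, W));
      out(r, c) = acc;
    }
  return out;
}

// Brute-force multiply-accumulate counter: walks the literal loop nest of a
// naive convolution (and of depthwise-then-pointwise for the separable kind)
// incrementing a counter once per multiply-accumulate.  Independent oracle
// for the closed-form cost expressions — never used by conv_cost() itself.
// [[Rcpp::export]]
double mac_count_loopnest(const int Df, const int M, const int N,
                          const int Dk, const std::string kind) {
  long long cnt = 0;
  if (kind == "conventional") {
    for (int x = 0; x < Df; ++x)
      for (int y = 0; y < Df; ++y)
        for (int n = 0; n < N; ++n)
          for (int m = 0; m < M; ++m)
            for (int i = 0; i < Dk; ++i)
              for (int j = 0; j < Dk; ++j)
                ++cnt;
  } else if (kind == "separable") {
    for (int x = 0; x < Df; ++x)          // depthwise pass
      for (int y = 0; y < Df; ++y)
        for (int m = 0; m < M; ++m)
          for (int i = 0; i < Dk; ++i)
            for (int j = 0; j < Dk; ++j)
              ++cnt;
    for (int x = 0; x < Df; ++x)          // pointwise pass
      for (int y = 0; y < Df; ++y)
        for (int m = 0; m < M; ++m)
          for (int n = 0; n < N; ++n)
            ++cnt;
  } else {
    stop("unknown convolution kind '%s'", kind.c_str());
  }
  return (double)cnt;
}
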