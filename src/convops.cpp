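// im2col + GEMM kernels for 3D convolution, its data/weight gradients, and
// 3D max pooling. Tensors are column-major R arrays with layout
// (D, H, W, C, B): depth fastest, then height, width, channel, batch.
// Weights are (kd, kh, kw, Cin, Cout). These are the hot loops of the
// encoder-decoder network; everything else lives in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Fill the im2col buffer (K x N) for one sample. K = kd*kh*kw*Ci ordered
// (kd fastest, then kh, kw, ci) to match the weight layout; N = Do*Ho*Wo
// ordered (Do fastest) to match the output layout.
static void im2col(const double* x, int D, int H, int W, int Ci,
                   int kd, int kh, int kw, int sd, int sh, int sw,
                   int pd, int ph, int pw, int Do, int Ho, int Wo,
                   arma::mat& col) {
  const int DH = D * H;
  const int DHW = DH * W;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int od = 0; od < Do; ++od) {
        const int n = od + Do * (ho + Ho * wo);
        double* cptr = col.colptr(n);
        int row = 0;
        for (int ci = 0; ci < Ci; ++ci) {
          const double* xc = x + (size_t)ci * DHW;
          for (int dx = 0; dx < kw; ++dx) {
            const int wi = wo * sw - pw + dx;
            const bool w_ok = (wi >= 0 && wi < W);
            for (int dy = 0; dy < kh; ++dy) {
              const int hi = ho * sh - ph + dy;
              const bool h_ok = w_ok && (hi >= 0 && hi < H);
              const double* base = xc + (size_t)wi * DH + (size_t)hi * D;
              for (int dz = 0; dz < kd; ++dz, ++row) {
                const int di = od * sd - pd + dz;
                cptr[row] = (h_ok && di >= 0 && di < D) ? base[di] : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add the columns of a (K x N) buffer back into one sample
// (col2im), the adjoint of im2col.
static void col2im(const arma::mat& col, double* x, int D, int H, int W,
                   int Ci, int kd, int kh, int kw, int sd, int sh, int sw,
                   int pd, int ph, int pw, int Do, int Ho, int Wo) {
  const int DH = D * H;
  const int DHW = DH * W;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int od = 0; od < Do; ++od) {
        const int n = od + Do * (ho + Ho * wo);
        const double* cptr = col.colptr(n);
        int row = 0;
        for (int ci = 0; ci < Ci; ++ci) {
          double* xc = x + (size_t)ci * DHW;
          for (int dx = 0; dx < kw; ++dx) {
            const int wi = wo * sw - pw + dx;
            const bool w_ok = (wi >= 0 && wi < W);
            for (int dy = 0; dy < kh; ++dy) {
              const int hi = ho * sh - ph + dy;
              const bool h_ok = w_ok && (hi >= 0 && hi < H);
              double* base = xc + (size_t)wi * DH + (size_t)hi * D;
              for (int dz = 0; dz < kd; ++dz, ++row) {
                const int di = od * sd - pd + dz;
                if (h_ok && di >= 0 && di < D) base[di] += cptr[row];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias,
                             IntegerVector stride, IntegerVector pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Ci = xdim[3], B = xdim[4];
  const int kd = wdim[0], kh = wdim[1], kw = wdim[2], Co = wdim[4];
  if (wdim[3] != Ci) stop("conv3d: channel mismatch");
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = out_size(D, kd, sd, pd), Ho = out_size(H, kh, sh, ph),
            Wo = out_size(W, kw, sw, pw);
  const int K = kd * kh * kw * Ci, N = Do * Ho * Wo;
  const size_t in_block = (size_t)D * H * W * Ci;
  const size_t out_block = (size_t)N * Co;

  NumericVector y(out_block * B);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);
  arma::mat col(K, N);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)b * in_block, D, H, W, Ci, kd, kh, kw,
           sd, sh, sw, pd, ph, pw, Do, Ho, Wo, col);
    arma::mat Y(y.begin() + (size_t)b * out_block, N, Co, false, true);
    Y = col.t() * Wm;
    for (int co = 0; co < Co; ++co) Y.col(co) += bias[co];
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, Co, B);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_data(NumericVector dy, NumericVector w,
                                  IntegerVector wdim, IntegerVector xdim,
                                  IntegerVector stride, IntegerVector pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Ci = xdim[3], B = xdim[4];
  const int kd = wdim[0], kh = wdim[1], kw = wdim[2], Co = wdim[4];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = out_size(D, kd, sd, pd), Ho = out_size(H, kh, sh, ph),
            Wo = out_size(W, kw, sw, pw);
  const int K = kd * kh * kw * Ci, N = Do * Ho * Wo;
  const size_t in_block = (size_t)D * H * W * Ci;
  const size_t out_block = (size_t)N * Co;

  NumericVector dx(in_block * B);  // zero-initialized
  arma::mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);
  arma::mat col(K, N);
  for (int b = 0; b < B; ++b) {
    arma::mat DY(const_cast<double*>(dy.begin()) + (size_t)b * out_block,
                 N, Co, false, true);
    col = Wm * DY.t();
    col2im(col, dx.begin() + (size_t)b * in_block, D, H, W, Ci,
           kd, kh, kw, sd, sh, sw, pd, ph, pw, Do, Ho, Wo);
  }
  dx.attr("dim") = IntegerVector::create(D, H, W, Ci, B);
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_w(NumericVector x, IntegerVector xdim,
                               NumericVector dy, IntegerVector wdim,
                               IntegerVector stride, IntegerVector pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Ci = xdim[3], B = xdim[4];
  const int kd = wdim[0], kh = wdim[1], kw = wdim[2], Co = wdim[4];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = out_size(D, kd, sd, pd), Ho = out_size(H, kh, sh, ph),
            Wo = out_size(W, kw, sw, pw);
  const int K = kd * kh * kw * Ci, N = Do * Ho * Wo;
  const size_t in_block = (size_t)D * H * W * Ci;
  const size_t out_block = (size_t)N * Co;

  NumericVector dw((size_t)K * Co);
  arma::mat DW(dw.begin(), K, Co, false, true);
  arma::mat col(K, N);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)b * in_block, D, H, W, Ci, kd, kh, kw,
           sd, sh, sw, pd, ph, pw, Do, Ho, Wo, col);
    arma::mat DY(const_cast<double*>(dy.begin()) + (size_t)b * out_block,
                 N, Co, false, true);
    DW += col * DY;
  }
  dw.attr("dim") = IntegerVector::create(kd, kh, kw, Ci, Co);
  return dw;
}

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector xdim,
                       IntegerVector pool) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], B = xdim[4];
  const int pd = pool[0], ph = pool[1], pw = pool[2];
  if (D % pd || H % ph || W % pw) stop("maxpool: shape not divisible by pool");
  const int Do = D / pd, Ho = H / ph, Wo = W / pw;
  const size_t in_block = (size_t)D * H * W;     // per channel
  const size_t out_len = (size_t)Do * Ho * Wo * C * B;

  NumericVector y(out_len);
  IntegerVector arg(out_len);  // 0-based index within the (D,H,W,C) block
  size_t o = 0;
  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (size_t)b * in_block * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xb + (size_t)c * in_block;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          for (int od = 0; od < Do; ++od) {
            double best = -arma::datum::inf;
            size_t best_i = 0;
            for (int dx = 0; dx < pw; ++dx)
              for (int dy = 0; dy < ph; ++dy)
                for (int dz = 0; dz < pd; ++dz) {
                  const size_t i = (size_t)(wo * pw + dx) * D * H +
                                   (size_t)(ho * ph + dy) * D +
                                   (od * pd + dz);
                  if (xc[i] > best) { best = xc[i]; best_i = i; }
                }
            // output position (Do,Ho,Wo,C,B) order, but we must write in
            // column-major order of the output: compute index explicitly
            const size_t oi = (size_t)b * (size_t)Do * Ho * Wo * C +
                              (size_t)c * Do * Ho * Wo +
                              (size_t)wo * Do * Ho + (size_t)ho * Do + od;
            y[oi] = best;
            arg[oi] = (int)((size_t)c * in_block + best_i);
            ++o;
          }
    }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, B);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector dy, IntegerVector arg,
                                IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], B = xdim[4];
  const size_t block = (size_t)D * H * W * C;
  NumericVector dx(block * B);
  const size_t out_block = dy.size() / B;
  for (int b = 0; b < B; ++b) {
    double* dxb = dx.begin() + (size_t)b * block;
    const size_t off = (size_t)b * out_block;
    for (size_t i = 0; i < out_block; ++i)
      dxb[arg[off + i]] += dy[off + i];
  }
  dx.attr("dim") = xdim;
  return dx;
}

// ---- small fused elementwise kernels (batch-norm scaling, activations) ----

// y = x * scale[col] + shift[col] for a (v x ncol) column-major matrix.
// [[Rcpp::export]]
NumericVector cpp_colscale_add(NumericVector x, int v, NumericVector scale,
                               NumericVector shift) {
  const R_xlen_t n = x.size();
  const int ncol = n / v;
  NumericVector y(n);
  for (int c = 0; c < ncol; ++c) {
    const double a = scale[c], b = shift[c];
    const double* xi = x.begin() + (size_t)c * v;
    double* yi = y.begin() + (size_t)c * v;
    for (int i = 0; i < v; ++i) yi[i] = xi[i] * a + b;
  }
  return y;
}

// dx = (dxhat - m1[col] - xhat * m2[col]) * istd[col]
// [[Rcpp::export]]
NumericVector cpp_bn_bwd_fuse(NumericVector dxhat, NumericVector xhat, int v,
                              NumericVector m1, NumericVector m2,
                              NumericVector istd) {
  const R_xlen_t n = dxhat.size();
  const int ncol = n / v;
  NumericVector dx(n);
  for (int c = 0; c < ncol; ++c) {
    const double a1 = m1[c], a2 = m2[c], s = istd[c];
    const double* dh = dxhat.begin() + (size_t)c * v;
    const double* xh = xhat.begin() + (size_t)c * v;
    double* o = dx.begin() + (size_t)c * v;
    for (int i = 0; i < v; ++i) o[i] = (dh[i] - a1 - xh[i] * a2) * s;
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_leaky_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : slope * x[i];
  y.attr("dim") = x.attr("dim");
  return y;
}

// Gradient through LeakyReLU using its own output (sign(y) == sign(x)).
// [[Rcpp::export]]
NumericVector cpp_leaky_bwd(NumericVector dy, NumericVector y, double slope) {
  NumericVector dx(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[i] = y[i] > 0 ? dy[i] : slope * dy[i];
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0.0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
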