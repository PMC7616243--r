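#include <Rcpp.h>
using namespace Rcpp;

// Tensors use an (H, W, N, C) column-major layout throughout the network
// code: spatial dims fastest, batch third, channels last so that channel
// concatenation (U-Net skips) is contiguous.

// Unfold 3x3 (or kxk) patches into a matrix of shape (oH*oW*N) x (k*k*C) so
// that a convolution becomes a single BLAS matmul against the weight matrix.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(oH * oW * N, k * k * C);
  const double *px = x.begin();
  double *po = out.begin();
  R_xlen_t nrow = (R_xlen_t)oH * oW * N;
  for (int ch = 0; ch < C; ++ch) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        R_xlen_t col = ki + (R_xlen_t)k * kj + (R_xlen_t)k * k * ch;
        double *pcol = po + col * nrow;
        for (int n = 0; n < N; ++n) {
          const double *pslab = px + ((R_xlen_t)ch * N + n) * H * W;
          for (int ow = 0; ow < oW; ++ow) {
            int w = ow * stride - pad + kj;
            R_xlen_t rbase = (R_xlen_t)oH * (ow + (R_xlen_t)oW * n);
            if (w < 0 || w >= W) {
              for (int oh = 0; oh < oH; ++oh) pcol[rbase + oh] = 0.0;
            } else {
              const double *pc = pslab + (R_xlen_t)w * H;
              for (int oh = 0; oh < oH; ++oh) {
                int h = oh * stride - pad + ki;
                pcol[rbase + oh] = (h < 0 || h >= H) ? 0.0 : pc[h];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Fold patch-gradients back onto the input grid (adjoint of cpp_im2col).
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int N, int C,
                         int k, int stride, int pad) {
  int oH = (H + 2 * pad - k) / stride + 1;
  int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)H * W * N * C);
  const double *pc = cols.begin();
  double *po = out.begin();
  R_xlen_t nrow = (R_xlen_t)oH * oW * N;
  for (int ch = 0; ch < C; ++ch) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        R_xlen_t col = ki + (R_xlen_t)k * kj + (R_xlen_t)k * k * ch;
        const double *pcol = pc + col * nrow;
        for (int n = 0; n < N; ++n) {
          double *pslab = po + ((R_xlen_t)ch * N + n) * H * W;
          for (int ow = 0; ow < oW; ++ow) {
            int w = ow * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            R_xlen_t rbase = (R_xlen_t)oH * (ow + (R_xlen_t)oW * n);
            double *pcw = pslab + (R_xlen_t)w * H;
            for (int oh = 0; oh < oH; ++oh) {
              int h = oh * stride - pad + ki;
              if (h >= 0 && h < H) pcw[h] += pcol[rbase + oh];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, N, C);
  return out;
}

// Nearest-neighbour 2x upsampling of an (H, W, N, C) tensor.
// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x, int H, int W, int N, int C) {
  int H2 = 2 * H, W2 = 2 * W;
  NumericVector out((R_xlen_t)H2 * W2 * N * C);
  const double *px = x.begin();
  double *po = out.begin();
  R_xlen_t nslab = (R_xlen_t)N * C;
  for (R_xlen_t s = 0; s < nslab; ++s) {
    const double *pi = px + s * H * W;
    double *pu = po + s * H2 * W2;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double v = pi[h + (R_xlen_t)w * H];
        R_xlen_t b = 2 * h + (R_xlen_t)2 * w * H2;
        pu[b] = v; pu[b + 1] = v; pu[b + H2] = v; pu[b + H2 + 1] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H2, W2, N, C);
  return out;
}

// Adjoint of cpp_upsample2: sum gradients over each 2x2 block.
// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector dy, int H2, int W2,
                                     int N, int C) {
  int H = H2 / 2, W = W2 / 2;
  NumericVector out((R_xlen_t)H * W * N * C);
  const double *pd = dy.begin();
  double *po = out.begin();
  R_xlen_t nslab = (R_xlen_t)N * C;
  for (R_xlen_t s = 0; s < nslab; ++s) {
    const double *pu = pd + s * H2 * W2;
    double *pi = po + s * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        R_xlen_t b = 2 * h + (R_xlen_t)2 * w * H2;
        pi[h + (R_xlen_t)w * H] = pu[b] + pu[b + 1] + pu[b + H2] + pu[b + H2 + 1];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, N, C);
  return out;
}

// y = x * scale[s] + shift[s], where s indexes slabs of `slab` consecutive
// elements (the (n, c) broadcast used by group norm).
// [[Rcpp::export]]
NumericVector cpp_scale_shift(NumericVector x, NumericVector scale,
                              NumericVector shift, int slab) {
  NumericVector out(x.size());
  const double *px = x.begin(), *ps = scale.begin(), *pt = shift.begin();
  double *po = out.begin();
  R_xlen_t n = x.size();
  R_xlen_t ns = scale.size();
  R_xlen_t i = 0;
  for (R_xlen_t s = 0; s < ns; ++s) {
    double a = ps[s], b = pt[s];
    for (int k = 0; k < slab; ++k, ++i) po[i] = px[i] * a + b;
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// fused group-norm input gradient:
// dx = istd[s] * (dxhat - S1[s]/m - xhat * S2[s]/m)
// [[Rcpp::export]]
NumericVector cpp_gn_backward(NumericVector dxhat, NumericVector xhat,
                              NumericVector istd, NumericVector S1,
                              NumericVector S2, double m, int slab) {
  NumericVector out(dxhat.size());
  const double *pd = dxhat.begin(), *ph = xhat.begin();
  const double *pi = istd.begin(), *p1 = S1.begin(), *p2 = S2.begin();
  double *po = out.begin();
  R_xlen_t ns = istd.size();
  R_xlen_t i = 0;
  for (R_xlen_t s = 0; s < ns; ++s) {
    double is = pi[s], a = p1[s] / m, b = p2[s] / m;
    for (int k = 0; k < slab; ++k, ++i)
      po[i] = is * (pd[i] - a - ph[i] * b);
  }
  out.attr("dim") = dxhat.attr("dim");
  return out;
}

// PReLU forward with per-slab negative slope a[s]
// [[Rcpp::export]]
NumericVector cpp_prelu_forward(NumericVector x, NumericVector a, int slab) {
  NumericVector out(x.size());
  const double *px = x.begin(), *pa = a.begin();
  double *po = out.begin();
  R_xlen_t ns = a.size();
  R_xlen_t i = 0;
  for (R_xlen_t s = 0; s < ns; ++s) {
    double av = pa[s];
    for (int k = 0; k < slab; ++k, ++i)
      po[i] = px[i] > 0 ? px[i] : av * px[i];
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// PReLU backward: returns dx, writes per-slab slope gradient into da
// [[Rcpp::export]]
NumericVector cpp_prelu_backward(NumericVector dy, NumericVector x,
                                 NumericVector a, NumericVector da,
                                 int slab) {
  NumericVector out(dy.size());
  const double *pd = dy.begin(), *px = x.begin(), *pa = a.begin();
  double *po = out.begin(), *pg = da.begin();
  R_xlen_t ns = a.size();
  R_xlen_t i = 0;
  for (R_xlen_t s = 0; s < ns; ++s) {
    double av = pa[s], g = 0;
    for (int k = 0; k < slab; ++k, ++i) {
      if (px[i] > 0) po[i] = pd[i];
      else { po[i] = pd[i] * av; g += pd[i] * px[i]; }
    }
    pg[s] += g;
  }
  out.attr("dim") = dy.attr("dim");
  return out;
}
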