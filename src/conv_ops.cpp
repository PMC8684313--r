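// Convolution / pooling primitives for small-canvas recurrent CNNs.
// Arrays are column-major R arrays with dim (H, W, C, N); kernels (k, k, Cin, Cout).
// Convolutions are stride-1 with explicit (possibly asymmetric) zero padding;
// strided and transposed variants are composed on the R side.
//
// The im2col buffer is laid out (Ho*Wo*N) x (k*k*Cin) so that the innermost
// loops (over the output row index i0) are stride-1 on both the buffer and
// the image, and the GEMMs are tall-and-skinny, which OpenBLAS handles well.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// cols(q, r) with q = i0 + Ho*(j0 + Wo*n), r = ki + k*(kj + k*c)
static arma::mat im2col_t(const double* x, int H, int W, int C, int N, int k,
                          int pt, int pl, int Ho, int Wo) {
  arma::mat cols((size_t)Ho * Wo * N, (size_t)k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* col = cols.colptr(ki + (size_t)k * (kj + (size_t)k * c));
        for (int n = 0; n < N; ++n) {
          const double* xc = x + (size_t)(c + (size_t)C * n) * H * W;
          for (int j0 = 0; j0 < Wo; ++j0) {
            int jj = j0 + kj - pl;
            double* dst = col + (size_t)Ho * (j0 + (size_t)Wo * n);
            if (jj < 0 || jj >= W) {
              std::memset(dst, 0, sizeof(double) * Ho);
              continue;
            }
            const double* src = xc + (size_t)jj * H;
            int i0 = 0;
            for (; i0 < Ho; ++i0) {
              int ii = i0 + ki - pt;
              dst[i0] = (ii < 0 || ii >= H) ? 0.0 : src[ii];
            }
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_add_t(const arma::mat& dcols, double* dx, int H, int W,
                         int C, int N, int k, int pt, int pl, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* col = dcols.colptr(ki + (size_t)k * (kj + (size_t)k * c));
        for (int n = 0; n < N; ++n) {
          double* xc = dx + (size_t)(c + (size_t)C * n) * H * W;
          for (int j0 = 0; j0 < Wo; ++j0) {
            int jj = j0 + kj - pl;
            if (jj < 0 || jj >= W) continue;
            const double* src = col + (size_t)Ho * (j0 + (size_t)Wo * n);
            double* dst = xc + (size_t)jj * H;
            for (int i0 = 0; i0 < Ho; ++i0) {
              int ii = i0 + ki - pt;
              if (ii >= 0 && ii < H) dst[ii] += src[i0];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias, IntegerVector pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int k = wdim[0], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  int pt = pad[0], pb = pad[1], pl = pad[2], pr = pad[3];
  int Ho = H + pt + pb - k + 1, Wo = W + pl + pr - k + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: non-positive output size");

  arma::mat cols = im2col_t(REAL(x), H, W, C, N, k, pt, pl, Ho, Wo);
  arma::mat wmat(const_cast<double*>(REAL(w)), (size_t)k * k * Cin, Cout,
                 false, true);
  arma::mat z = cols * wmat;  // (Ho*Wo*N, Cout)

  NumericVector out((size_t)Ho * Wo * Cout * N);
  double* o = REAL(out);
  const double* b = REAL(bias);
  size_t plane = (size_t)Ho * Wo;
  for (int c = 0; c < Cout; ++c) {
    const double* zc = z.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double* src = zc + plane * n;
      double* dst = o + plane * (c + (size_t)Cout * n);
      double bc = b[c];
      for (size_t q = 0; q < plane; ++q) dst[q] = src[q] + bc;
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector dz, IntegerVector pad,
                    bool need_dx) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int k = wdim[0], Cin = wdim[2], Cout = wdim[3];
  int pt = pad[0], pb = pad[1], pl = pad[2], pr = pad[3];
  int Ho = H + pt + pb - k + 1, Wo = W + pl + pr - k + 1;

  // repack dz (Ho,Wo,Cout,N) into (Ho*Wo*N, Cout)
  arma::mat dzmat((size_t)Ho * Wo * N, Cout);
  const double* dzp = REAL(dz);
  size_t plane = (size_t)Ho * Wo;
  for (int c = 0; c < Cout; ++c) {
    double* dst0 = dzmat.colptr(c);
    for (int n = 0; n < N; ++n)
      std::memcpy(dst0 + plane * n, dzp + plane * (c + (size_t)Cout * n),
                  sizeof(double) * plane);
  }

  arma::mat cols = im2col_t(REAL(x), H, W, C, N, k, pt, pl, Ho, Wo);
  arma::mat dwmat = cols.t() * dzmat;  // (k*k*Cin, Cout)
  arma::rowvec db = arma::sum(dzmat, 0);

  NumericVector dw(dwmat.begin(), dwmat.end());
  dw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector dbv(db.begin(), db.end());

  if (!need_dx)
    return List::create(_["dw"] = dw, _["db"] = dbv, _["dx"] = R_NilValue);

  arma::mat wmat(const_cast<double*>(REAL(w)), (size_t)k * k * Cin, Cout,
                 false, true);
  arma::mat dcols = dzmat * wmat.t();  // (Ho*Wo*N, k*k*Cin)
  NumericVector dx((size_t)H * W * C * N);  // zero-initialized
  col2im_add_t(dcols, REAL(dx), H, W, C, N, k, pt, pl, Ho, Wo);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dw"] = dw, _["db"] = dbv, _["dx"] = dx);
}

// 2x2 max pooling with 2x2 stride; ties resolved to the first element in
// column-major scan order. Returns pooled values and 0-based argmax indices
// into the input array for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (H % 2 || W % 2) stop("maxpool: spatial dims must be even, got %dx%d", H, W);
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)(c + (size_t)C * n) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          size_t p00 = base + (size_t)(2 * j) * H + 2 * i;
          size_t cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
          size_t best = cand[0];
          double bv = xp[best];
          for (int t = 1; t < 4; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          yp[q] = bv;
          ip[q] = (int)best;
          ++q;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  size_t len = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(len);
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  const int* ip = INTEGER(idx);
  R_xlen_t m = dy.size();
  for (R_xlen_t q = 0; q < m; ++q) dxp[ip[q]] += dyp[q];
  dx.attr("dim") = xdim;
  return dx;
}

// batch-norm helpers operating per channel over (H, W, N): per-channel mean
// and biased SD, and the normalization itself, avoiding R-side aperm copies.
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t plane = (size_t)H * W;
  const double* xp = REAL(x);
  NumericVector mu(C), sd(C);
  double m = (double)plane * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = xp + plane * (c + (size_t)C * n);
      for (size_t q = 0; q < plane; ++q) { s += p[q]; s2 += p[q] * p[q]; }
    }
    double mean = s / m;
    double var = s2 / m - mean * mean;
    if (var < 0) var = 0;
    mu[c] = mean;
    sd[c] = std::sqrt(var);
  }
  return List::create(_["mu"] = mu, _["sd"] = sd);
}

// h = x * scale[c] + shift[c]
// [[Rcpp::export]]
NumericVector cpp_channel_affine(NumericVector x, IntegerVector xdim,
                                 NumericVector scale, NumericVector shift) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t plane = (size_t)H * W;
  NumericVector out((size_t)plane * C * N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = xp + plane * (c + (size_t)C * n);
      double* dst = op + plane * (c + (size_t)C * n);
      double a = scale[c], b = shift[c];
      for (size_t q = 0; q < plane; ++q) dst[q] = src[q] * a + b;
    }
  out.attr("dim") = xdim;
  return out;
}

// per-channel sums needed by the batch-norm backward pass:
// sum(g), sum(g * x) over (H, W, N) for each channel
// [[Rcpp::export]]
List cpp_bn_bwd_sums(NumericVector x, NumericVector g, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t plane = (size_t)H * W;
  const double* xp = REAL(x);
  const double* gp = REAL(g);
  NumericVector sg(C), sgx(C);
  for (int c = 0; c < C; ++c) {
    double a = 0, b = 0;
    for (int n = 0; n < N; ++n) {
      size_t off = plane * (c + (size_t)C * n);
      const double* px = xp + off;
      const double* pg = gp + off;
      for (size_t q = 0; q < plane; ++q) { a += pg[q]; b += pg[q] * px[q]; }
    }
    sg[c] = a; sgx[c] = b;
  }
  return List::create(_["sg"] = sg, _["sgx"] = sgx);
}

// da = A[c] * g + B[c] * x + D[c]  (channel-wise affine combination used by
// the batch-norm backward pass)
// [[Rcpp::export]]
NumericVector cpp_bn_bwd_combine(NumericVector x, NumericVector g,
                                 IntegerVector xdim, NumericVector A,
                                 NumericVector B, NumericVector D) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t plane = (size_t)H * W;
  NumericVector out((size_t)plane * C * N);
  const double* xp = REAL(x);
  const double* gp = REAL(g);
  double* op = REAL(out);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = plane * (c + (size_t)C * n);
      const double* px = xp + off;
      const double* pg = gp + off;
      double* dst = op + off;
      double a = A[c], b = B[c], d = D[c];
      for (size_t q = 0; q < plane; ++q) dst[q] = a * pg[q] + b * px[q] + d;
    }
  out.attr("dim") = xdim;
  return out;
}
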