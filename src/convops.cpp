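// Minimal conv-net kernels for 2D encoder-decoder networks.
// Tensor layout everywhere: [H, W, C, N] column-major doubles (R arrays).
// Convolution weights: [k, k, Cin, Cout]; transposed-conv weights: [2, 2, Cin, Cout].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword idx4(arma::uword h, arma::uword w, arma::uword c,
                               arma::uword n, arma::uword H, arma::uword W,
                               arma::uword C) {
  return h + H * (w + W * (c + C * n));
}

// im2col with zero "same" padding, odd kernel k.
// Output: [H*W, k*k*C] where column q = ki + k*(kj + k*c).
static arma::mat im2col_same(const double* x, arma::uword H, arma::uword W,
                             arma::uword C, arma::uword n, arma::uword k) {
  const int r = (int)(k - 1) / 2;
  arma::mat cols(H * W, k * k * C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    for (int kj = 0; kj < (int)k; ++kj) {
      for (int ki = 0; ki < (int)k; ++ki) {
        const arma::uword q = ki + k * (kj + k * c);
        for (int w = 0; w < (int)W; ++w) {
          const int ws = w + kj - r;
          if (ws < 0 || ws >= (int)W) continue;
          for (int h = 0; h < (int)H; ++h) {
            const int hs = h + ki - r;
            if (hs < 0 || hs >= (int)H) continue;
            cols(h + H * w, q) = x[idx4(hs, ws, c, n, H, W, C)];
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col_same: scatter-add columns back into an image.
static void col2im_same(const arma::mat& cols, double* x, arma::uword H,
                        arma::uword W, arma::uword C, arma::uword n,
                        arma::uword k) {
  const int r = (int)(k - 1) / 2;
  for (arma::uword c = 0; c < C; ++c) {
    for (int kj = 0; kj < (int)k; ++kj) {
      for (int ki = 0; ki < (int)k; ++ki) {
        const arma::uword q = ki + k * (kj + k * c);
        for (int w = 0; w < (int)W; ++w) {
          const int ws = w + kj - r;
          if (ws < 0 || ws >= (int)W) continue;
          for (int h = 0; h < (int)H; ++h) {
            const int hs = h + ki - r;
            if (hs < 0 || hs >= (int)H) continue;
            x[idx4(hs, ws, c, n, H, W, C)] += cols(h + H * w, q);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const arma::uword k = wd[0], Cout = wd[3];
  if ((arma::uword)wd[2] != C) stop("channel mismatch in conv2d_fw");
  arma::mat Wm(w.begin(), k * k * C, Cout, false);
  arma::rowvec bv(b.begin(), Cout);
  NumericVector y(H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (arma::uword n = 0; n < N; ++n) {
    arma::mat cols = im2col_same(x.begin(), H, W, C, n, k);
    arma::mat yn = cols * Wm;
    yn.each_row() += bv;
    std::copy(yn.begin(), yn.end(), y.begin() + H * W * Cout * n);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const arma::uword k = wd[0], Cout = wd[3];
  arma::mat Wm(w.begin(), k * k * C, Cout, false);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat dW(k * k * C, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  for (arma::uword n = 0; n < N; ++n) {
    arma::mat dyn(const_cast<double*>(dy.begin()) + H * W * Cout * n, H * W,
                  Cout, false);
    arma::mat cols = im2col_same(x.begin(), H, W, C, n, k);
    dW += cols.t() * dyn;
    db += arma::sum(dyn, 0);
    arma::mat dcols = dyn * Wm.t();
    col2im_same(dcols, dx.begin(), H, W, C, n, k);
  }
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax
// positions into the input tensor (first maximum wins on ties).
// [[Rcpp::export]]
List maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const arma::uword Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C * N);
  IntegerVector am(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  arma::uword o = 0;
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c)
      for (arma::uword w = 0; w < Wo; ++w)
        for (arma::uword h = 0; h < Ho; ++h) {
          double best = -1e300;
          arma::uword bi = 0;
          for (arma::uword dj = 0; dj < 2; ++dj)
            for (arma::uword di = 0; di < 2; ++di) {
              arma::uword i = idx4(2 * h + di, 2 * w + dj, c, n, H, W, C);
              if (x[i] > best) { best = x[i]; bi = i; }
            }
          y[o] = best;
          am[o] = (int)(bi + 1);
          ++o;
        }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(NumericVector dy, IntegerVector argmax,
                          IntegerVector xdim) {
  NumericVector dx((arma::uword)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i] - 1] += dy[i];
  return dx;
}

// Transposed convolution, kernel 2x2, stride 2 (non-overlapping upsampling):
// every output 2x2 block is a linear map of one input pixel, so the whole
// operation is one GEMM plus a gather/scatter. Weight element (di, dj, c, co)
// maps input channel c to offset (di, dj) of output channel co.
// Reordered weight matrix: [C, 4*Cout] with column q = di + 2*dj + 4*co.
static arma::mat upw_matrix(const NumericVector& w, arma::uword C,
                            arma::uword Cout) {
  arma::mat Wm(C, 4 * Cout);
  for (arma::uword co = 0; co < Cout; ++co)
    for (arma::uword dj = 0; dj < 2; ++dj)
      for (arma::uword di = 0; di < 2; ++di)
        for (arma::uword c = 0; c < C; ++c)
          Wm(c, di + 2 * dj + 4 * co) = w[di + 2 * (dj + 2 * (c + C * co))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector upconv2_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const arma::uword Cout = wd[3];
  arma::mat Wm = upw_matrix(w, C, Cout);
  NumericVector y(4 * H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, Cout, N);
  for (arma::uword n = 0; n < N; ++n) {
    arma::mat xn(const_cast<double*>(x.begin()) + H * W * C * n, H * W, C,
                 false);
    arma::mat yn = xn * Wm;  // [H*W, 4*Cout]
    double* yp = y.begin() + 4 * H * W * Cout * n;
    for (arma::uword co = 0; co < Cout; ++co)
      for (arma::uword dj = 0; dj < 2; ++dj)
        for (arma::uword di = 0; di < 2; ++di) {
          const double* col = yn.colptr(di + 2 * dj + 4 * co);
          const double bc = b[co];
          for (arma::uword ww = 0; ww < W; ++ww)
            for (arma::uword h = 0; h < H; ++h)
              yp[(2 * h + di) +
                 2 * H * ((2 * ww + dj) + 2 * W * co)] = col[h + H * ww] + bc;
        }
  }
  return y;
}

// [[Rcpp::export]]
List upconv2_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const arma::uword H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const arma::uword Cout = wd[3];
  arma::mat Wm = upw_matrix(w, C, Cout);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dwv(w.size());
  dwv.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(C, 4 * Cout, arma::fill::zeros);
  arma::mat dyn(H * W, 4 * Cout);
  for (arma::uword n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + 4 * H * W * Cout * n;
    for (arma::uword co = 0; co < Cout; ++co)
      for (arma::uword dj = 0; dj < 2; ++dj)
        for (arma::uword di = 0; di < 2; ++di) {
          double* col = dyn.colptr(di + 2 * dj + 4 * co);
          double acc = 0.0;
          for (arma::uword ww = 0; ww < W; ++ww)
            for (arma::uword h = 0; h < H; ++h) {
              const double g =
                  dyp[(2 * h + di) + 2 * H * ((2 * ww + dj) + 2 * W * co)];
              col[h + H * ww] = g;
              acc += g;
            }
          db[co] += acc;
        }
    arma::mat xn(const_cast<double*>(x.begin()) + H * W * C * n, H * W, C,
                 false);
    arma::mat dxn(dx.begin() + H * W * C * n, H * W, C, false, true);
    dxn = dyn * Wm.t();
    dWm += xn.t() * dyn;
  }
  for (arma::uword co = 0; co < Cout; ++co)
    for (arma::uword dj = 0; dj < 2; ++dj)
      for (arma::uword di = 0; di < 2; ++di)
        for (arma::uword c = 0; c < C; ++c)
          dwv[di + 2 * (dj + 2 * (c + C * co))] =
              dWm(c, di + 2 * dj + 4 * co);
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// Per-channel affine map y = a[c] * x + s[c] for [H, W, C, N] tensors.
// [[Rcpp::export]]
NumericVector channel_affine(NumericVector x, NumericVector a,
                             NumericVector s) {
  IntegerVector xd = x.attr("dim");
  const arma::uword HW = (arma::uword)xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  arma::uword o = 0;
  for (arma::uword n = 0; n < N; ++n)
    for (arma::uword c = 0; c < C; ++c) {
      const double ac = a[c], sc = s[c];
      for (arma::uword i = 0; i < HW; ++i, ++o) y[o] = ac * x[o] + sc;
    }
  return y;
}

// Per-channel sums of x and of x*y (y optional) for [H, W, C, N] tensors.
// [[Rcpp::export]]
NumericVector channel_dot(NumericVector x, Nullable<NumericVector> y) {
  IntegerVector xd = x.attr("dim");
  const arma::uword HW = (arma::uword)xd[0] * xd[1], C = xd[2], N = xd[3];
  NumericVector out(C);
  arma::uword o = 0;
  if (y.isNotNull()) {
    NumericVector yy(y);
    for (arma::uword n = 0; n < N; ++n)
      for (arma::uword c = 0; c < C; ++c) {
        double acc = 0.0;
        for (arma::uword i = 0; i < HW; ++i, ++o) acc += x[o] * yy[o];
        out[c] += acc;
      }
  } else {
    for (arma::uword n = 0; n < N; ++n)
      for (arma::uword c = 0; c < C; ++c) {
        double acc = 0.0;
        for (arma::uword i = 0; i < HW; ++i, ++o) acc += x[o];
        out[c] += acc;
      }
  }
  return out;
}
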