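// 3x3 same-padding 2D convolution, forward and backward, for slice batches.
// Arrays follow R's column-major (H, W, C, N) layout. Weights are stored as a
// (9*Cin) x Cout matrix whose row index is q = k*Cin + ci, where k = 0..8
// enumerates the kernel offset (di, dj) = (k %% 3 - 1, k %/% 3 - 1).
//
// GEMMs run in single precision: parameters and activations live in double
// on the R side, but conv arithmetic at these network sizes is insensitive
// to float32 rounding and the sgemm path roughly halves training time.
// The im2col buffer is zeroed once per call; out-of-image positions stay
// zero (zero padding) because only in-range segments are rewritten.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void im2col_sample(const float* xn, arma::fmat& col,
                                 int H, int W, int C) {
  const int HW = H * W;
  for (int k = 0; k < 9; ++k) {
    const int di = k % 3 - 1, dj = k / 3 - 1;
    const int h0 = std::max(0, -di), h1 = std::min(H, H - di); // valid dest rows
    if (h1 <= h0) continue;
    for (int ci = 0; ci < C; ++ci) {
      float* dst = col.colptr(k * C + ci);
      const float* srcc = xn + ci * HW;
      for (int wc = 0; wc < W; ++wc) {
        const int sj = wc + dj;
        if (sj < 0 || sj >= W) continue;
        std::memcpy(dst + wc * H + h0, srcc + sj * H + h0 + di,
                    (h1 - h0) * sizeof(float));
      }
    }
  }
}

static arma::fvec to_float(const double* p, R_xlen_t n) {
  arma::fvec out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = static_cast<float>(p[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector dims,
                            NumericMatrix w, NumericVector b) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int HW = H * W, Cout = w.ncol();
  if (w.nrow() != 9 * C) stop("weight/channel mismatch");
  arma::fvec xf = to_float(x.begin(), x.size());
  arma::fmat Wf(w.nrow(), Cout);
  std::copy(w.begin(), w.end(), Wf.begin());
  arma::frowvec bt(Cout);
  std::copy(b.begin(), b.end(), bt.begin());
  NumericVector y(static_cast<R_xlen_t>(HW) * Cout * N);
  arma::fmat col(HW, 9 * C, arma::fill::zeros);
  arma::fmat yn(HW, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_sample(xf.memptr() + static_cast<R_xlen_t>(n) * HW * C, col, H, W, C);
    yn = col * Wf;
    yn.each_row() += bt;
    double* yp = y.begin() + static_cast<R_xlen_t>(n) * HW * Cout;
    for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(HW) * Cout; ++i)
      yp[i] = yn[i];
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector dims,
                   NumericMatrix w, NumericVector dy) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int HW = H * W, Cout = w.ncol();
  arma::fvec xf = to_float(x.begin(), x.size());
  arma::fvec dyf = to_float(dy.begin(), dy.size());
  arma::fmat Wf(w.nrow(), Cout);
  std::copy(w.begin(), w.end(), Wf.begin());

  NumericVector dx(x.size());
  NumericMatrix dw(9 * C, Cout);
  NumericVector db(Cout);
  arma::fmat dWf(9 * C, Cout, arma::fill::zeros);
  arma::fmat col(HW, 9 * C, arma::fill::zeros);
  arma::fmat dcol(HW, 9 * C);
  arma::frowvec dbv(Cout, arma::fill::zeros);
  arma::fvec dxf(x.size(), arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const float* xn = xf.memptr() + static_cast<R_xlen_t>(n) * HW * C;
    arma::fmat dyn(dyf.memptr() + static_cast<R_xlen_t>(n) * HW * Cout,
                   HW, Cout, false, true);
    im2col_sample(xn, col, H, W, C);
    dWf += col.t() * dyn;
    dbv += arma::sum(dyn, 0);
    dcol = dyn * Wf.t();
    // col2im: scatter-add valid segments back into dx
    float* dxn = dxf.memptr() + static_cast<R_xlen_t>(n) * HW * C;
    for (int k = 0; k < 9; ++k) {
      const int di = k % 3 - 1, dj = k / 3 - 1;
      const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
      if (h1 <= h0) continue;
      for (int ci = 0; ci < C; ++ci) {
        const float* src = dcol.colptr(k * C + ci);
        float* dstc = dxn + ci * HW;
        for (int wc = 0; wc < W; ++wc) {
          const int sj = wc + dj;
          if (sj < 0 || sj >= W) continue;
          float* dst = dstc + sj * H + h0 + di;
          const float* s = src + wc * H + h0;
          for (int h = 0; h < h1 - h0; ++h) dst[h] += s[h];
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < dx.size(); ++i) dx[i] = dxf[i];
  std::copy(dWf.begin(), dWf.end(), dw.begin());
  std::copy(dbv.begin(), dbv.end(), db.begin());
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
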