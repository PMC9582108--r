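// Low-level tensor kernels for the network engine.
//
// Layout conventions (match R's column-major arrays):
//   feature map  x : dim (H, W, C)            -> arma::cube H x W x C
//   conv weight  w : dim (k, k, Cin, Cout)    -> matrix (k*k*Cin) x Cout
//   tconv weight w : dim (k, k, Cout, Cin)    -> matrix (k*k*Cout) x Cin
//                    (the weight of the "virtual" convolution whose transpose
//                     the transposed convolution computes)
//
// im2col column ordering: patch row index = dr + k*dc + k*k*ci (dr fastest),
// which matches the flattening of the R weight array, so conv is a single
// BLAS matmul. Padding follows the TensorFlow "same" rule: for output size
// Ho = ceil(Hi/stride), total pad = max((Ho-1)*stride + k - Hi, 0), with the
// extra pixel (if odd) on the bottom/right.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int same_out(int in, int stride) { return (in + stride - 1) / stride; }

static inline int same_pad_before(int in, int k, int stride) {
  int out = same_out(in, stride);
  int total = std::max((out - 1) * stride + k - in, 0);
  return total / 2;
}

// Gather patches of x (H x W x C) into a (k*k*C) x (Ho*Wo) matrix.
static arma::mat im2col(const arma::cube& x, int k, int stride,
                        int Ho, int Wo, int pad_h, int pad_w) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(k * k * C, Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const int r0 = ho * stride - pad_h;
      const int c0 = wo * stride - pad_w;
      double* dst = cols.colptr(col);
      for (int ci = 0; ci < C; ++ci) {
        for (int dc = 0; dc < k; ++dc) {
          const int cc = c0 + dc;
          if (cc < 0 || cc >= W) continue;
          const double* src = x.slice_colptr(ci, cc);
          const int base = ci * k * k + dc * k;
          for (int dr = 0; dr < k; ++dr) {
            const int rr = r0 + dr;
            if (rr < 0 || rr >= H) continue;
            dst[base + dr] = src[rr];
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add patch columns back into an H x W x C cube (adjoint of im2col).
static arma::cube col2im(const arma::mat& cols, int H, int W, int C, int k,
                         int stride, int Ho, int Wo, int pad_h, int pad_w) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const int r0 = ho * stride - pad_h;
      const int c0 = wo * stride - pad_w;
      const double* src = cols.colptr(col);
      for (int ci = 0; ci < C; ++ci) {
        for (int dc = 0; dc < k; ++dc) {
          const int cc = c0 + dc;
          if (cc < 0 || cc >= W) continue;
          double* dst = x.slice_colptr(ci, cc);
          const int base = ci * k * k + dc * k;
          for (int dr = 0; dr < k; ++dr) {
            const int rr = r0 + dr;
            if (rr < 0 || rr >= H) continue;
            dst[rr] += src[base + dr];
          }
        }
      }
    }
  }
  return x;
}

static arma::cube as_cube(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  return arma::cube(const_cast<double*>(a.begin()), d[0], d[1], d[2], false, true);
}

static NumericVector wrap_cube(const arma::cube& c) {
  NumericVector out(c.begin(), c.end());
  out.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

// ---- convolution -----------------------------------------------------------

// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
NumericVector cpp_conv2d_fw(NumericVector x_, NumericVector w_, NumericVector b_,
                            int k, int stride) {
  arma::cube x = as_cube(x_);
  const int Ci = x.n_slices;
  const int Co = b_.size();
  const int Ho = same_out(x.n_rows, stride), Wo = same_out(x.n_cols, stride);
  const int ph = same_pad_before(x.n_rows, k, stride);
  const int pw = same_pad_before(x.n_cols, k, stride);
  arma::mat Wm(const_cast<double*>(w_.begin()), k * k * Ci, Co, false, true);
  arma::mat cols = im2col(x, k, stride, Ho, Wo, ph, pw);
  arma::mat y = cols.t() * Wm;           // (Ho*Wo) x Co
  arma::rowvec b(const_cast<double*>(b_.begin()), Co, false, true);
  y.each_row() += b;
  arma::cube out(y.memptr(), Ho, Wo, Co);
  return wrap_cube(out);
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(NumericVector x_, NumericVector w_, NumericVector dy_,
                   int k, int stride) {
  arma::cube x = as_cube(x_);
  arma::cube dy = as_cube(dy_);
  const int Ci = x.n_slices, Co = dy.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  const int ph = same_pad_before(x.n_rows, k, stride);
  const int pw = same_pad_before(x.n_cols, k, stride);
  arma::mat Wm(const_cast<double*>(w_.begin()), k * k * Ci, Co, false, true);
  arma::mat dY(dy.memptr(), Ho * Wo, Co, false, true);
  arma::mat cols = im2col(x, k, stride, Ho, Wo, ph, pw);
  arma::mat dW = cols * dY;              // (k*k*Ci) x Co
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dcols = Wm * dY.t();         // (k*k*Ci) x (Ho*Wo)
  arma::cube dx = col2im(dcols, x.n_rows, x.n_cols, Ci, k, stride, Ho, Wo, ph, pw);
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = IntegerVector::create(k, k, Ci, Co);
  return List::create(_["dx"] = wrap_cube(dx), _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// ---- transposed convolution ------------------------------------------------
// y (sH x sW x Co) = transpose of a stride-s "same" conv (sH,sW,Co)->(H,W,Ci)

// [[Rcpp::export(name = ".cpp_tconv2d_fw")]]
NumericVector cpp_tconv2d_fw(NumericVector x_, NumericVector w_, NumericVector b_,
                             int k, int stride) {
  arma::cube x = as_cube(x_);
  const int H = x.n_rows, W = x.n_cols, Ci = x.n_slices;
  const int Co = b_.size();
  const int sH = H * stride, sW = W * stride;
  const int ph = same_pad_before(sH, k, stride);
  const int pw = same_pad_before(sW, k, stride);
  arma::mat Wm(const_cast<double*>(w_.begin()), k * k * Co, Ci, false, true);
  arma::mat Xm(x.memptr(), H * W, Ci, false, true);
  arma::mat dcols = Wm * Xm.t();         // (k*k*Co) x (H*W)
  arma::cube y = col2im(dcols, sH, sW, Co, k, stride, H, W, ph, pw);
  for (int c = 0; c < Co; ++c) y.slice(c) += b_[c];
  return wrap_cube(y);
}

// [[Rcpp::export(name = ".cpp_tconv2d_bw")]]
List cpp_tconv2d_bw(NumericVector x_, NumericVector w_, NumericVector dy_,
                    int k, int stride) {
  arma::cube x = as_cube(x_);
  arma::cube dy = as_cube(dy_);
  const int H = x.n_rows, W = x.n_cols, Ci = x.n_slices;
  const int Co = dy.n_slices;
  const int ph = same_pad_before(dy.n_rows, k, stride);
  const int pw = same_pad_before(dy.n_cols, k, stride);
  arma::mat Wm(const_cast<double*>(w_.begin()), k * k * Co, Ci, false, true);
  arma::mat Xm(x.memptr(), H * W, Ci, false, true);
  arma::mat cols = im2col(dy, k, stride, H, W, ph, pw);  // (k*k*Co) x (H*W)
  arma::mat dXm = cols.t() * Wm;                          // (H*W) x Ci
  arma::mat dW = cols * Xm;                               // (k*k*Co) x Ci
  arma::vec db(Co);
  for (int c = 0; c < Co; ++c) db[c] = arma::accu(dy.slice(c));
  arma::cube dx(dXm.memptr(), H, W, Ci);
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = IntegerVector::create(k, k, Co, Ci);
  return List::create(_["dx"] = wrap_cube(dx), _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// ---- 2x2 max pooling -------------------------------------------------------

// [[Rcpp::export(name = ".cpp_maxpool2_fw")]]
List cpp_maxpool2_fw(NumericVector x_) {
  arma::cube x = as_cube(x_);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector arg(Ho * Wo * C);   // linear index into x, 0-based
  int p = 0;
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int best = -1; double bv = -std::numeric_limits<double>::infinity();
        for (int dc = 0; dc < 2; ++dc) {
          for (int dr = 0; dr < 2; ++dr) {
            const int rr = 2 * ho + dr, cc = 2 * wo + dc;
            const double v = x(rr, cc, c);
            if (v > bv) { bv = v; best = rr + H * cc + H * W * c; }
          }
        }
        y(ho, wo, c) = bv;
        arg[p++] = best;
      }
    }
  }
  List out = List::create(_["y"] = wrap_cube(y), _["argmax"] = arg);
  return out;
}

// [[Rcpp::export(name = ".cpp_maxpool2_bw")]]
NumericVector cpp_maxpool2_bw(NumericVector dy_, IntegerVector argmax,
                              int H, int W) {
  arma::cube dy = as_cube(dy_);
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  const double* g = dy.memptr();
  double* d = dx.memptr();
  const int n = dy.n_elem;
  for (int i = 0; i < n; ++i) d[argmax[i]] += g[i];
  return wrap_cube(dx);
}

// ---- nearest-neighbour x2 upsampling --------------------------------------

// [[Rcpp::export(name = ".cpp_nnup2_fw")]]
NumericVector cpp_nnup2_fw(NumericVector x_) {
  arma::cube x = as_cube(x_);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = x(h, w, c);
        y(2 * h, 2 * w, c) = v; y(2 * h + 1, 2 * w, c) = v;
        y(2 * h, 2 * w + 1, c) = v; y(2 * h + 1, 2 * w + 1, c) = v;
      }
  return wrap_cube(y);
}

// [[Rcpp::export(name = ".cpp_nnup2_bw")]]
NumericVector cpp_nnup2_bw(NumericVector dy_) {
  arma::cube dy = as_cube(dy_);
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        dx(h, w, c) = dy(2 * h, 2 * w, c) + dy(2 * h + 1, 2 * w, c) +
                      dy(2 * h, 2 * w + 1, c) + dy(2 * h + 1, 2 * w + 1, c);
  return wrap_cube(dx);
}
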