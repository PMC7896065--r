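// Compact convolutional-network primitives: im2col convolution with BLAS
// gemm, max/average pooling, and their backward passes. Tensors are
// (height, width, channels) cubes; convolution weights are
// (k*k*in_ch) x out_ch matrices whose rows run over (dy, dx, channel) in
// column-major order (dy fastest), matching im2col below.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& x, int k, int stride, int pad, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(k * k * C, oh * ow);
  for (int oj = 0; oj < ow; ++oj) {
    for (int oi = 0; oi < oh; ++oi) {
      const int col_idx = oj * oh + oi;
      double* dst = cols.colptr(col_idx);
      const int i0 = oi * stride - pad, j0 = oj * stride - pad;
      int r = 0;
      for (int c = 0; c < C; ++c) {
        for (int dj = 0; dj < k; ++dj) {
          const int j = j0 + dj;
          if (j < 0 || j >= W) {
            for (int di = 0; di < k; ++di) dst[r++] = 0.0;
          } else {
            const double* src = x.slice_colptr(c, j);
            for (int di = 0; di < k; ++di) {
              const int i = i0 + di;
              dst[r++] = (i < 0 || i >= H) ? 0.0 : src[i];
            }
          }
        }
      }
    }
  }
  return cols;
}

static void col2im(const mat& cols, cube& dx, int k, int stride, int pad,
                   int oh, int ow) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int oj = 0; oj < ow; ++oj) {
    for (int oi = 0; oi < oh; ++oi) {
      const int col_idx = oj * oh + oi;
      const double* src = cols.colptr(col_idx);
      const int i0 = oi * stride - pad, j0 = oj * stride - pad;
      int r = 0;
      for (int c = 0; c < C; ++c) {
        for (int dj = 0; dj < k; ++dj) {
          const int j = j0 + dj;
          if (j < 0 || j >= W) { r += k; continue; }
          double* dst = dx.slice_colptr(c, j);
          for (int di = 0; di < k; ++di) {
            const int i = i0 + di;
            if (i >= 0 && i < H) dst[i] += src[r];
            ++r;
          }
        }
      }
    }
  }
}

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".conv_forward")]]
arma::cube conv_forward_cpp(const arma::cube& x, const arma::mat& W,
                            const arma::vec& b, int k, int stride, int pad) {
  const int oh = out_dim(x.n_rows, k, stride, pad);
  const int ow = out_dim(x.n_cols, k, stride, pad);
  mat cols = im2col(x, k, stride, pad, oh, ow);
  mat out = W.t() * cols;           // (out_ch) x (oh*ow)
  out.each_col() += b;
  cube y(oh, ow, W.n_cols);
  for (unsigned int c = 0; c < W.n_cols; ++c) {
    y.slice(c) = reshape(out.row(c), oh, ow);
  }
  return y;
}

// [[Rcpp::export(name = ".conv_backward")]]
Rcpp::List conv_backward_cpp(const arma::cube& x, const arma::mat& W,
                             const arma::cube& dout, int k, int stride,
                             int pad) {
  const int oh = dout.n_rows, ow = dout.n_cols;
  const int oc = dout.n_slices;
  mat dmat(oc, oh * ow);
  for (int c = 0; c < oc; ++c) {
    dmat.row(c) = vectorise(dout.slice(c)).t();
  }
  mat cols = im2col(x, k, stride, pad, oh, ow);
  mat dW = cols * dmat.t();
  vec db = sum(dmat, 1);
  mat dcols = W * dmat;
  cube dx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im(dcols, dx, k, stride, pad, oh, ow);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".maxpool_forward")]]
Rcpp::List maxpool_forward_cpp(const arma::cube& x, int k, int stride) {
  const int oh = out_dim(x.n_rows, k, stride, 0);
  const int ow = out_dim(x.n_cols, k, stride, 0);
  const int C = x.n_slices;
  cube y(oh, ow, C);
  ucube amax(oh, ow, C);  // linear index into the input slice
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int oj = 0; oj < ow; ++oj) {
      for (int oi = 0; oi < oh; ++oi) {
        double best = -datum::inf; uword bidx = 0;
        for (int dj = 0; dj < k; ++dj) {
          const int j = oj * stride + dj;
          if (j >= (int)x.n_cols) break;
          for (int di = 0; di < k; ++di) {
            const int i = oi * stride + di;
            if (i >= (int)x.n_rows) break;
            const double v = xs(i, j);
            if (v > best) { best = v; bidx = j * x.n_rows + i; }
          }
        }
        y(oi, oj, c) = best;
        amax(oi, oj, c) = bidx;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = y,
                            Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
arma::cube maxpool_backward_cpp(const arma::ucube& amax,
                                const arma::cube& dout, int in_h, int in_w) {
  const int C = dout.n_slices;
  cube dx(in_h, in_w, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& dxs = dx.slice(c);
    for (unsigned int j = 0; j < dout.n_cols; ++j) {
      for (unsigned int i = 0; i < dout.n_rows; ++i) {
        dxs(amax(i, j, c)) += dout(i, j, c);
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".avgpool_forward")]]
arma::cube avgpool_forward_cpp(const arma::cube& x, int k, int stride) {
  const int oh = out_dim(x.n_rows, k, stride, 0);
  const int ow = out_dim(x.n_cols, k, stride, 0);
  const int C = x.n_slices;
  cube y(oh, ow, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int oj = 0; oj < ow; ++oj) {
      for (int oi = 0; oi < oh; ++oi) {
        double s = 0.0; int n = 0;
        for (int dj = 0; dj < k; ++dj) {
          const int j = oj * stride + dj;
          if (j >= (int)x.n_cols) break;
          for (int di = 0; di < k; ++di) {
            const int i = oi * stride + di;
            if (i >= (int)x.n_rows) break;
            s += xs(i, j); ++n;
          }
        }
        y(oi, oj, c) = s / n;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".avgpool_backward")]]
arma::cube avgpool_backward_cpp(const arma::cube& dout, int k, int stride,
                                int in_h, int in_w) {
  const int C = dout.n_slices;
  cube dx(in_h, in_w, C, fill::zeros);
  const double inv = 1.0 / (k * k);
  for (int c = 0; c < C; ++c) {
    mat& dxs = dx.slice(c);
    for (unsigned int oj = 0; oj < dout.n_cols; ++oj) {
      for (unsigned int oi = 0; oi < dout.n_rows; ++oi) {
        const double g = dout(oi, oj, c) * inv;
        for (int dj = 0; dj < k; ++dj) {
          const int j = oj * stride + dj;
          if (j >= in_w) break;
          for (int di = 0; di < k; ++di) {
            const int i = oi * stride + di;
            if (i >= in_h) break;
            dxs(i, j) += g;
          }
        }
      }
    }
  }
  return dx;
}
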