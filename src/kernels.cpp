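// Hot loops of the 1D CNN: valid-padding convolution (im2col + GEMM),
// max pooling with argmax bookkeeping, per-channel batch normalization
// and ReLU. Batches are held as (length, channels, n) cubes so each R
// array of dim (L, C, N) maps directly onto an arma::cube; inner loops
// walk raw column pointers because the channel axis is the middle one.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Column layout of the patch matrix (and of the weight matrix W):
// row index c * k + j  <->  kernel offset j of input channel c.
static void im2col_into(const arma::mat& x, int k, arma::mat& cols) {
  const int L = x.n_rows, C = x.n_cols, Lout = L - k + 1;
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    for (int j = 0; j < k; ++j)
      std::copy(src + j, src + j + Lout, cols.colptr(c * k + j));
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_fwd(const arma::cube& X, const arma::mat& W,
                          const arma::rowvec& b, int k) {
  const int Lout = (int)X.n_rows - k + 1, N = X.n_slices;
  if ((int)W.n_rows != k * (int)X.n_cols)
    stop("conv1d: weight rows do not match kernel * in_channels");
  if (Lout < 1) stop("conv1d: kernel exceeds input length");
  arma::cube Y(Lout, W.n_cols, N);
  arma::mat cols(Lout, W.n_rows);
  for (int n = 0; n < N; ++n) {
    im2col_into(X.slice(n), k, cols);
    Y.slice(n) = cols * W;
    Y.slice(n).each_row() += b;
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv1d_bwd(const arma::cube& X, const arma::mat& W,
                    const arma::cube& dY, int k) {
  const int L = X.n_rows, C = X.n_cols, N = X.n_slices;
  const int Lout = dY.n_rows;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::rowvec db(W.n_cols, arma::fill::zeros);
  arma::cube dX(L, C, N, arma::fill::zeros);
  arma::mat cols(Lout, W.n_rows), dCols(Lout, W.n_rows);
  for (int n = 0; n < N; ++n) {
    im2col_into(X.slice(n), k, cols);
    dW += cols.t() * dY.slice(n);
    db += arma::sum(dY.slice(n), 0);
    dCols = dY.slice(n) * W.t();            // Lout x (k*C)
    for (int c = 0; c < C; ++c) {
      double* dst = dX.slice(n).colptr(c);
      for (int j = 0; j < k; ++j) {
        const double* src = dCols.colptr(c * k + j);
        for (int t = 0; t < Lout; ++t) dst[t + j] += src[t];
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::cube& X, int p, int s) {
  const int L = X.n_rows, C = X.n_cols, N = X.n_slices;
  if (p > L) stop("maxpool: window exceeds input length");
  const int Lout = (L - p) / s + 1;
  arma::cube Y(Lout, C, N);
  IntegerVector idx(Lout * C * N);  // winning input row, 0-based
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* col = X.slice(n).colptr(c);
      double* out = Y.slice(n).colptr(c);
      for (int t = 0; t < Lout; ++t) {
        const int base = t * s;
        double best = col[base];
        int bi = base;
        for (int j = 1; j < p; ++j)
          if (col[base + j] > best) { best = col[base + j]; bi = base + j; }
        out[t] = best;
        *ip++ = bi;
      }
    }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const IntegerVector& idx, const arma::cube& dY,
                           int L_in) {
  const int Lout = dY.n_rows, C = dY.n_cols, N = dY.n_slices;
  arma::cube dX(L_in, C, N, arma::fill::zeros);
  const int* ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = dY.slice(n).colptr(c);
      double* dst = dX.slice(n).colptr(c);
      for (int t = 0; t < Lout; ++t) dst[ip[t]] += src[t];
      ip += Lout;
    }
  return dX;
}

// [[Rcpp::export]]
arma::cube cpp_relu_fwd(const arma::cube& X) {
  arma::cube Y(X.n_rows, X.n_cols, X.n_slices);
  const double* src = X.memptr();
  double* dst = Y.memptr();
  const size_t n = X.n_elem;
  for (size_t i = 0; i < n; ++i) dst[i] = src[i] > 0 ? src[i] : 0;
  return Y;
}

// dX = dY masked by the forward output (relu'(x) = 1 iff y > 0)
// [[Rcpp::export]]
arma::cube cpp_relu_bwd(const arma::cube& Y, const arma::cube& dY) {
  arma::cube dX(Y.n_rows, Y.n_cols, Y.n_slices);
  const double* y = Y.memptr();
  const double* dy = dY.memptr();
  double* dst = dX.memptr();
  const size_t n = Y.n_elem;
  for (size_t i = 0; i < n; ++i) dst[i] = y[i] > 0 ? dy[i] : 0;
  return dX;
}

// Batch normalization over the channel axis: statistics are taken across
// all temporal positions and all batch members of each channel.
// [[Rcpp::export]]
List cpp_bn_fwd_train(const arma::cube& X, const arma::vec& gamma,
                      const arma::vec& beta, double eps) {
  const int L = X.n_rows, C = X.n_cols, N = X.n_slices;
  const double m = (double)L * N;
  arma::vec mu(C), var(C);
  arma::cube Y(L, C, N);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* col = X.slice(n).colptr(c);
      for (int t = 0; t < L; ++t) { s += col[t]; s2 += col[t] * col[t]; }
    }
    const double mc = s / m;
    double vc = s2 / m - mc * mc;
    if (vc < 0) vc = 0;
    mu(c) = mc; var(c) = vc;
    const double a = gamma(c) / std::sqrt(vc + eps);
    const double bshift = beta(c) - a * mc;
    for (int n = 0; n < N; ++n) {
      const double* col = X.slice(n).colptr(c);
      double* out = Y.slice(n).colptr(c);
      for (int t = 0; t < L; ++t) out[t] = a * col[t] + bshift;
    }
  }
  return List::create(_["Y"] = Y, _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
arma::cube cpp_bn_fwd_infer(const arma::cube& X, const arma::vec& gamma,
                            const arma::vec& beta, const arma::vec& rmean,
                            const arma::vec& rvar, double eps) {
  const int L = X.n_rows, C = X.n_cols, N = X.n_slices;
  arma::cube Y(L, C, N);
  for (int c = 0; c < C; ++c) {
    const double a = gamma(c) / std::sqrt(rvar(c) + eps);
    const double bshift = beta(c) - a * rmean(c);
    for (int n = 0; n < N; ++n) {
      const double* col = X.slice(n).colptr(c);
      double* out = Y.slice(n).colptr(c);
      for (int t = 0; t < L; ++t) out[t] = a * col[t] + bshift;
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(const arma::cube& X, const arma::vec& gamma,
                const arma::vec& mu, const arma::vec& var, double eps,
                const arma::cube& dY) {
  const int L = X.n_rows, C = X.n_cols, N = X.n_slices;
  const double m = (double)L * N;
  arma::vec dgamma(C), dbeta(C);
  arma::cube dX(L, C, N);
  for (int c = 0; c < C; ++c) {
    const double invstd = 1.0 / std::sqrt(var(c) + eps);
    const double mc = mu(c);
    double sum_dy = 0, sum_dy_xhat = 0;
    for (int n = 0; n < N; ++n) {
      const double* x = X.slice(n).colptr(c);
      const double* dy = dY.slice(n).colptr(c);
      for (int t = 0; t < L; ++t) {
        sum_dy += dy[t];
        sum_dy_xhat += dy[t] * (x[t] - mc) * invstd;
      }
    }
    dgamma(c) = sum_dy_xhat;
    dbeta(c) = sum_dy;
    const double a = gamma(c) * invstd / m;
    for (int n = 0; n < N; ++n) {
      const double* x = X.slice(n).colptr(c);
      const double* dy = dY.slice(n).colptr(c);
      double* out = dX.slice(n).colptr(c);
      for (int t = 0; t < L; ++t) {
        const double xhat = (x[t] - mc) * invstd;
        out[t] = a * (m * dy[t] - sum_dy - xhat * sum_dy_xhat);
      }
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
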