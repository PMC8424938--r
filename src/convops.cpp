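// 3D convolution primitives for the volumetric residual U-Net.
// Activations are (side^3) x C matrices, voxel index flattened column-major
// (x fastest), matching R's array(dim = c(side, side, side, C)).
// Weights are (k^3 * Cin) x Cout with row = kx + k*(ky + k*(kz + k*cin)),
// i.e. the column-major flattening of array(k, k, k, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_side(int side, int stride) {
  return (side + stride - 1) / stride;
}

// 'same' padding: total = max((out-1)*stride + k - side, 0), left = total/2
static inline int pad_left(int side, int k, int stride) {
  int o = out_side(side, stride);
  int total = (o - 1) * stride + k - side;
  if (total < 0) total = 0;
  return total / 2;
}

static mat im2col3d(const mat& X, int side, int k, int stride) {
  const int cin = X.n_cols;
  const int os = out_side(side, stride);
  const int pl = pad_left(side, k, stride);
  const int n_out = os * os * os;
  mat cols(n_out, (size_t)k * k * k * cin, fill::zeros);
  for (int c = 0; c < cin; ++c) {
    const double* xc = X.colptr(c);
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const size_t col = (size_t)kx + k * ((size_t)ky + k * ((size_t)kz + k * (size_t)c));
          double* dst = cols.colptr(col);
          for (int oz = 0; oz < os; ++oz) {
            int iz = oz * stride - pl + kz;
            if (iz < 0 || iz >= side) continue;
            for (int oy = 0; oy < os; ++oy) {
              int iy = oy * stride - pl + ky;
              if (iy < 0 || iy >= side) continue;
              const size_t obase = (size_t)oy * os + (size_t)oz * os * os;
              const size_t ibase = (size_t)iy * side + (size_t)iz * side * side;
              for (int ox = 0; ox < os; ++ox) {
                int ixx = ox * stride - pl + kx;
                if (ixx < 0 || ixx >= side) continue;
                dst[(size_t)ox + obase] = xc[(size_t)ixx + ibase];
              }
            }
          }
        }
  }
  return cols;
}

// scatter-add of column matrix back to input layout
static mat col2im3d(const mat& dcols, int side, int k, int stride, int cin) {
  const int os = out_side(side, stride);
  const int pl = pad_left(side, k, stride);
  mat dX((size_t)side * side * side, cin, fill::zeros);
  for (int c = 0; c < cin; ++c) {
    double* xc = dX.colptr(c);
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const size_t col = (size_t)kx + k * ((size_t)ky + k * ((size_t)kz + k * (size_t)c));
          const double* src = dcols.colptr(col);
          for (int oz = 0; oz < os; ++oz) {
            int iz = oz * stride - pl + kz;
            if (iz < 0 || iz >= side) continue;
            for (int oy = 0; oy < os; ++oy) {
              int iy = oy * stride - pl + ky;
              if (iy < 0 || iy >= side) continue;
              const size_t obase = (size_t)oy * os + (size_t)oz * os * os;
              const size_t ibase = (size_t)iy * side + (size_t)iz * side * side;
              for (int ox = 0; ox < os; ++ox) {
                int ixx = ox * stride - pl + kx;
                if (ixx < 0 || ixx >= side) continue;
                xc[(size_t)ixx + ibase] += src[(size_t)ox + obase];
              }
            }
          }
        }
  }
  return dX;
}

// [[Rcpp::export]]
arma::mat conv3d_fw(const arma::mat& X, int side, int k, int stride,
                    const arma::mat& W, const arma::vec& b) {
  mat cols = im2col3d(X, side, k, stride);
  mat Y = cols * W;
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3d_bw(const arma::mat& X, int side, int k, int stride,
                     const arma::mat& W, const arma::mat& dY) {
  mat cols = im2col3d(X, side, k, stride);
  mat dW = cols.t() * dY;
  vec db = sum(dY, 0).t();
  mat dcols = dY * W.t();
  mat dX = col2im3d(dcols, side, k, stride, X.n_cols);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::mat im2col3d_r(const arma::mat& X, int side, int k, int stride) {
  return im2col3d(X, side, k, stride);
}

// [[Rcpp::export]]
arma::mat conv3d_fw_cols(const arma::mat& cols, const arma::mat& W,
                         const arma::vec& b) {
  mat Y = cols * W;
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3d_bw_cols(const arma::mat& cols, int side, int k, int stride,
                          const arma::mat& W, const arma::mat& dY, int cin) {
  mat dW = cols.t() * dY;
  vec db = sum(dY, 0).t();
  mat dcols = dY * W.t();
  mat dX = col2im3d(dcols, side, k, stride, cin);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List bn_fw(const arma::mat& X, const arma::vec& gamma,
                 const arma::vec& beta, double eps) {
  const int n = X.n_rows, C = X.n_cols;
  mat xhat(n, C);
  vec mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double m = mean(X.col(c));
    double v = mean(square(X.col(c))) - m * m;
    mu[c] = m; var[c] = v;
    xhat.col(c) = (X.col(c) - m) / std::sqrt(v + eps);
  }
  mat Y = xhat;
  for (int c = 0; c < C; ++c) Y.col(c) = Y.col(c) * gamma[c] + beta[c];
  return Rcpp::List::create(Rcpp::Named("y") = Y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("mu") = mu,
                            Rcpp::Named("var") = var);
}

// [[Rcpp::export]]
Rcpp::List bn_bw(const arma::mat& xhat, const arma::vec& var,
                 const arma::vec& gamma, const arma::mat& dY, double eps) {
  const int n = xhat.n_rows, C = xhat.n_cols;
  mat dX(n, C);
  vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    dgamma[c] = dot(dY.col(c), xhat.col(c));
    dbeta[c] = accu(dY.col(c));
    double invstd = 1.0 / std::sqrt(var[c] + eps);
    vec dxh = dY.col(c) * gamma[c];
    double m1 = mean(dxh);
    double m2 = mean(dxh % xhat.col(c));
    dX.col(c) = (dxh - m1 - xhat.col(c) * m2) * invstd;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
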