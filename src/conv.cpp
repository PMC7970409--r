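// Batched 3x3 "same" convolution primitives for the view-synthesis network.
//
// Images are stored column-major as an (B*H*W) x C matrix: sample b occupies
// rows [b*H*W, (b+1)*H*W), pixel (i, j) of a sample maps to row i + H*j within
// that block. Kernel weights are a (9*C) x F matrix whose row (k*C + c) holds
// the tap for spatial offset k (di = k % 3 - 1, dj = k / 3 - 1, i.e. the
// output pixel reads input pixel (i + di, j + dj)) and input channel c.
// The convolution is expressed as nine shifted GEMMs so that all the heavy
// lifting is done by BLAS. A single-precision path (single = true) is used
// for network training, where the ~1e-7 rounding is immaterial and SGEMM is
// about twice as fast; the double path serves exact oracle checks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// S(i, j) = A(i + di, j + dj) per sample, zero where out of bounds.
template <typename T>
static void shift_into(const Mat<T>& A, Mat<T>& S, int di, int dj,
                       int H, int W, int B) {
  S.zeros();
  const int j_lo = std::max(0, -dj), j_hi = std::min(W, W - dj);
  const int i_lo = std::max(0, -di), i_hi = std::min(H, H - di);
  if (j_lo >= j_hi || i_lo >= i_hi) return;
  const int nrow = i_hi - i_lo;
  for (int b = 0; b < B; ++b) {
    const int base = b * H * W;
    for (int j = j_lo; j < j_hi; ++j) {
      S.rows(base + j * H + i_lo, base + j * H + i_lo + nrow - 1) =
        A.rows(base + (j + dj) * H + i_lo + di,
               base + (j + dj) * H + i_lo + di + nrow - 1);
    }
  }
}

template <typename T>
static Mat<T> conv_fw(const Mat<T>& X, const Mat<T>& W,
                      const Col<T>& b, int H, int Wd, int B) {
  const int C = X.n_cols, F = W.n_cols;
  Mat<T> Y(X.n_rows, F);
  Y.each_row() = b.t();
  Mat<T> S(X.n_rows, C);
  for (int k = 0; k < 9; ++k) {
    shift_into(X, S, k % 3 - 1, k / 3 - 1, H, Wd, B);
    Y += S * W.rows(k * C, k * C + C - 1);
  }
  return Y;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::mat conv2d_fw(const arma::mat& X, const arma::mat& W,
                    const arma::vec& b, int H, int Wd, int B,
                    bool single = false) {
  if ((int)W.n_rows != 9 * (int)X.n_cols)
    Rcpp::stop("weight matrix has %d rows, expected 9*C = %d",
               (int)W.n_rows, 9 * (int)X.n_cols);
  if ((int)X.n_rows != B * H * Wd)
    Rcpp::stop("input has %d rows, expected B*H*W = %d",
               (int)X.n_rows, B * H * Wd);
  if (!single) return conv_fw<double>(X, W, b, H, Wd, B);
  fmat Y = conv_fw<float>(conv_to<fmat>::from(X), conv_to<fmat>::from(W),
                          conv_to<fvec>::from(b), H, Wd, B);
  return conv_to<mat>::from(Y);
}

template <typename T>
static void conv_bw(const Mat<T>& X, const Mat<T>& W, const Mat<T>& dY,
                    int H, int Wd, int B,
                    Mat<T>& dX, Mat<T>& dW, Col<T>& db) {
  const int C = X.n_cols, F = W.n_cols;
  dW.set_size(9 * C, F);
  dX.zeros(X.n_rows, C);
  db = sum(dY, 0).t();
  Mat<T> S(X.n_rows, C), G, Tm(X.n_rows, C);
  for (int k = 0; k < 9; ++k) {
    const int di = k % 3 - 1, dj = k / 3 - 1;
    shift_into(X, S, di, dj, H, Wd, B);
    dW.rows(k * C, k * C + C - 1) = S.t() * dY;
    G = dY * W.rows(k * C, k * C + C - 1).t();
    shift_into(G, Tm, -di, -dj, H, Wd, B);
    dX += Tm;
  }
}

// [[Rcpp::export(name = ".conv2d_bw")]]
Rcpp::List conv2d_bw(const arma::mat& X, const arma::mat& W,
                     const arma::mat& dY, int H, int Wd, int B,
                     bool single = false) {
  if (!single) {
    mat dX, dW; vec db;
    conv_bw<double>(X, W, dY, H, Wd, B, dX, dW, db);
    return Rcpp::List::create(
      Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
      Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
  }
  fmat dX, dW; fvec db;
  conv_bw<float>(conv_to<fmat>::from(X), conv_to<fmat>::from(W),
                 conv_to<fmat>::from(dY), H, Wd, B, dX, dW, db);
  return Rcpp::List::create(
    Rcpp::Named("dX") = conv_to<mat>::from(dX),
    Rcpp::Named("dW") = conv_to<mat>::from(dW),
    Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
}
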