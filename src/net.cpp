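// Fast single-precision training path for the view-synthesis network: the
// full 17-layer forward/backward pass runs in C++ with activations cached
// in float, so each batch converts the parameters once instead of once per
// layer. Layer layout matches R/net.R: stem, four residual blocks of three
// convolutions with an identity shortcut, four tail convolutions (the last
// linear); ReLU elsewhere. The loss gradient at the prediction is computed
// in R (it needs the SSIM machinery) and fed to the backward call through
// an external-pointer handle to the cached activations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

template <typename T>
static void shift_into_net(const Mat<T>& A, Mat<T>& S, int di, int dj,
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

static fmat fconv_fw(const fmat& X, const fmat& W, const fvec& b,
                     int H, int Wd, int B) {
  const int C = X.n_cols;
  fmat Y(X.n_rows, W.n_cols);
  Y.each_row() = b.t();
  fmat S(X.n_rows, C);
  for (int k = 0; k < 9; ++k) {
    shift_into_net(X, S, k % 3 - 1, k / 3 - 1, H, Wd, B);
    Y += S * W.rows(k * C, k * C + C - 1);
  }
  return Y;
}

static void fconv_bw(const fmat& X, const fmat& W, const fmat& dY,
                     int H, int Wd, int B,
                     fmat& dX, fmat& dW, fvec& db) {
  const int C = X.n_cols;
  dW.set_size(9 * C, W.n_cols);
  dX.zeros(X.n_rows, C);
  db = sum(dY, 0).t();
  fmat S(X.n_rows, C), G, Tm(X.n_rows, C);
  for (int k = 0; k < 9; ++k) {
    const int di = k % 3 - 1, dj = k / 3 - 1;
    shift_into_net(X, S, di, dj, H, Wd, B);
    dW.rows(k * C, k * C + C - 1) = S.t() * dY;
    G = dY * W.rows(k * C, k * C + C - 1).t();
    shift_into_net(G, Tm, -di, -dj, H, Wd, B);
    dX += Tm;
  }
}

struct NetState {
  std::vector<fmat> Wl;   // layer weights (float copies)
  std::vector<fvec> bl;
  std::vector<fmat> xin;  // input fed to each conv layer
  std::vector<fmat> act;  // post-activation output of each layer
  int H, W, B;
};

static std::vector<fmat> run_forward(NetState& st, const fmat& U) {
  const int H = st.H, W = st.W, B = st.B;
  st.xin.assign(17, fmat());
  st.act.assign(17, fmat());
  st.xin[0] = U;
  fmat h = fconv_fw(U, st.Wl[0], st.bl[0], H, W, B);
  h.transform([](float v) { return v > 0.f ? v : 0.f; });
  st.act[0] = h;
  for (int blk = 0; blk < 4; ++blk) {
    const int i = 1 + 3 * blk;
    st.xin[i] = h;
    fmat a1 = fconv_fw(h, st.Wl[i], st.bl[i], H, W, B);
    a1.transform([](float v) { return v > 0.f ? v : 0.f; });
    st.act[i] = a1;
    st.xin[i + 1] = a1;
    fmat a2 = fconv_fw(a1, st.Wl[i + 1], st.bl[i + 1], H, W, B);
    a2.transform([](float v) { return v > 0.f ? v : 0.f; });
    st.act[i + 1] = a2;
    st.xin[i + 2] = a2;
    fmat z3 = fconv_fw(a2, st.Wl[i + 2], st.bl[i + 2], H, W, B);
    h = z3 + h;
    h.transform([](float v) { return v > 0.f ? v : 0.f; });
    st.act[i + 2] = h;
  }
  for (int i = 13; i < 16; ++i) {
    st.xin[i] = h;
    h = fconv_fw(h, st.Wl[i], st.bl[i], H, W, B);
    h.transform([](float v) { return v > 0.f ? v : 0.f; });
    st.act[i] = h;
  }
  st.xin[16] = h;
  fmat corr = fconv_fw(h, st.Wl[16], st.bl[16], H, W, B);
  std::vector<fmat> out(2);
  out[0] = U + corr;
  out[1] = corr;
  return out;
}

// [[Rcpp::export(name = ".net_fw_fast")]]
Rcpp::List net_fw_fast(Rcpp::List params, const arma::mat& U,
                       int H, int W, int B, bool keep = true) {
  Rcpp::XPtr<NetState> st(new NetState(), true);
  st->H = H; st->W = W; st->B = B;
  st->Wl.resize(17); st->bl.resize(17);
  for (int i = 0; i < 17; ++i) {
    Rcpp::List li = params[i];
    st->Wl[i] = conv_to<fmat>::from(Rcpp::as<mat>(li["W"]));
    st->bl[i] = conv_to<fvec>::from(Rcpp::as<vec>(li["b"]));
  }
  fmat Uf = conv_to<fmat>::from(U);
  std::vector<fmat> out = run_forward(*st, Uf);
  Rcpp::List res = Rcpp::List::create(
    Rcpp::Named("pred") = conv_to<mat>::from(out[0]),
    Rcpp::Named("corr") = conv_to<mat>::from(out[1]));
  if (keep) res["state"] = st;
  return res;
}

// [[Rcpp::export(name = ".net_bw_fast")]]
Rcpp::List net_bw_fast(SEXP state, const arma::mat& dPred) {
  Rcpp::XPtr<NetState> st(state);
  const int H = st->H, W = st->W, B = st->B;
  Rcpp::List grads(17);
  fmat dX, dW; fvec db;
  auto relu_mask = [](fmat& g, const fmat& a) {
    for (uword i = 0; i < g.n_elem; ++i) if (a(i) <= 0.f) g(i) = 0.f;
  };
  fmat da = conv_to<fmat>::from(dPred);
  fconv_bw(st->xin[16], st->Wl[16], da, H, W, B, dX, dW, db);
  grads[16] = Rcpp::List::create(
    Rcpp::Named("dW") = conv_to<mat>::from(dW),
    Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
  da = dX;
  for (int i = 15; i >= 13; --i) {
    relu_mask(da, st->act[i]);
    fconv_bw(st->xin[i], st->Wl[i], da, H, W, B, dX, dW, db);
    grads[i] = Rcpp::List::create(
      Rcpp::Named("dW") = conv_to<mat>::from(dW),
      Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
    da = dX;
  }
  for (int blk = 3; blk >= 0; --blk) {
    const int i = 1 + 3 * blk;
    fmat ds = da;
    relu_mask(ds, st->act[i + 2]);
    fconv_bw(st->xin[i + 2], st->Wl[i + 2], ds, H, W, B, dX, dW, db);
    grads[i + 2] = Rcpp::List::create(
      Rcpp::Named("dW") = conv_to<mat>::from(dW),
      Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
    fmat dz2 = dX;
    relu_mask(dz2, st->act[i + 1]);
    fconv_bw(st->xin[i + 1], st->Wl[i + 1], dz2, H, W, B, dX, dW, db);
    grads[i + 1] = Rcpp::List::create(
      Rcpp::Named("dW") = conv_to<mat>::from(dW),
      Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
    fmat dz1 = dX;
    relu_mask(dz1, st->act[i]);
    fconv_bw(st->xin[i], st->Wl[i], dz1, H, W, B, dX, dW, db);
    grads[i] = Rcpp::List::create(
      Rcpp::Named("dW") = conv_to<mat>::from(dW),
      Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
    da = dX + ds;            // conv path + identity shortcut
  }
  relu_mask(da, st->act[0]);
  fconv_bw(st->xin[0], st->Wl[0], da, H, W, B, dX, dW, db);
  grads[0] = Rcpp::List::create(
    Rcpp::Named("dW") = conv_to<mat>::from(dW),
    Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
  return grads;
}
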