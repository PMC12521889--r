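// Transformer encoder kernel for spike-count token sequences.
//
// Tokens are the per-bin population vectors of one trial, linearly embedded
// to d_model, plus a learned class token at position 0 and sinusoidal
// positional encodings.  Post-LN layers: multi-head softmax attention with
// a per-trial key mask, then a ReLU MLP, each wrapped in residual +
// LayerNorm.  The backward pass is hand-derived and is checked against
// finite differences in the test suite.
//
// Layout conventions (column-major, Armadillo):
//   X     : cube  [cells x bins x trials]
//   mask  : imat  [bins x trials], 1 = attendable key.  The class token is
//           always attendable.  Masked bins are provably invisible to the
//           class-token read-out: no permitted query ever attends to them.
//   chi   : mat   [d_model x trials] class-token representation
//
// The forward pass can hand back its intermediate state as an external
// pointer; tf_kernel_grad() consumes it so that a training update costs
// one forward plus one backward instead of two forwards.  All randomness
// lives on the R side; this file is pure deterministic linear algebra.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const double MASK_NEG = -1e30;

static mat posenc(int n_pos, int d) {
  mat P(n_pos, d, fill::zeros);
  for (int pos = 0; pos < n_pos; ++pos)
    for (int i = 0; i < d; i += 2) {
      double freq = std::pow(10000.0, -((double)i) / d);
      P(pos, i) = std::sin(pos * freq);
      if (i + 1 < d) P(pos, i + 1) = std::cos(pos * freq);
    }
  return P;
}

static void ln_forward(const mat& X, const rowvec& g, const rowvec& b,
                       mat& Y, mat& xhat, vec& istd) {
  const double eps = 1e-5;
  vec mu = mean(X, 1);
  vec v  = var(X, 1, 1);
  istd = 1.0 / sqrt(v + eps);
  xhat = X;
  xhat.each_col() -= mu;
  xhat.each_col() %= istd;
  Y = xhat;
  Y.each_row() %= g;
  Y.each_row() += b;
}

static mat ln_backward(const mat& dY, const mat& xhat, const vec& istd,
                       const rowvec& g, rowvec& dg, rowvec& db) {
  dg += sum(dY % xhat, 0);
  db += sum(dY, 0);
  mat dxh = dY;
  dxh.each_row() %= g;
  vec m1 = mean(dxh, 1);
  vec m2 = mean(dxh % xhat, 1);
  mat dX = dxh;
  dX.each_col() -= m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= istd;
  return dX;
}

struct LayerParams {
  mat Wq, Wk, Wv, Wo, W1, W2;
  rowvec bq, bk, bv, bo, c1, c2, g1, d1, g2, d2;
};

static rowvec as_rowvec(SEXP s) { return rowvec(Rcpp::as<std::vector<double> >(s)); }

static LayerParams get_layer(const List& params, int l) {
  std::string p = "l" + std::to_string(l + 1) + "_";
  LayerParams lp;
  lp.Wq = Rcpp::as<mat>(params[p + "Wq"]);  lp.bq = as_rowvec(params[p + "bq"]);
  lp.Wk = Rcpp::as<mat>(params[p + "Wk"]);  lp.bk = as_rowvec(params[p + "bk"]);
  lp.Wv = Rcpp::as<mat>(params[p + "Wv"]);  lp.bv = as_rowvec(params[p + "bv"]);
  lp.Wo = Rcpp::as<mat>(params[p + "Wo"]);  lp.bo = as_rowvec(params[p + "bo"]);
  lp.W1 = Rcpp::as<mat>(params[p + "W1"]);  lp.c1 = as_rowvec(params[p + "c1"]);
  lp.W2 = Rcpp::as<mat>(params[p + "W2"]);  lp.c2 = as_rowvec(params[p + "c2"]);
  lp.g1 = as_rowvec(params[p + "ln1_g"]);   lp.d1 = as_rowvec(params[p + "ln1_b"]);
  lp.g2 = as_rowvec(params[p + "ln2_g"]);   lp.d2 = as_rowvec(params[p + "ln2_b"]);
  return lp;
}

struct LayerCache {
  mat Hin, Qs, Ks, Vs, A, O, Z, Fpre, Frelu;
  mat xh1, xh2; vec is1, is2;
};

struct TfState {
  int C, Tb, B, N, D, H, dh, L;
  cube X;
  imat mask;
  mat We; rowvec be, cls;
  std::vector<LayerParams> LP;
  std::vector<LayerCache> CC;
};

static void forward_impl(const List& params, const cube& X, const imat& mask,
                         int n_heads, int n_layers, TfState& st,
                         mat& chi, bool want_attn, Rcpp::List& attn_out) {
  const int C  = X.n_rows, Tb = X.n_cols, B = X.n_slices, N = Tb + 1;
  st.We = Rcpp::as<mat>(params["W_e"]);
  st.be = as_rowvec(params["b_e"]);
  st.cls = as_rowvec(params["cls"]);
  const int D = st.We.n_cols;
  if (D % n_heads != 0) Rcpp::stop("d_model not divisible by n_heads");
  const int dh = D / n_heads;
  const double sc = 1.0 / std::sqrt((double)dh);
  if ((int)mask.n_rows != Tb || (int)mask.n_cols != B)
    Rcpp::stop("mask must be bins x trials");
  st.C = C; st.Tb = Tb; st.B = B; st.N = N; st.D = D;
  st.H = n_heads; st.dh = dh; st.L = n_layers;
  st.X = X; st.mask = mask;

  mat P = posenc(N, D);
  mat H(B * N, D);
  for (int b = 0; b < B; ++b) {
    int r0 = b * N;
    H.row(r0) = st.cls + P.row(0);
    mat E = X.slice(b).t() * st.We;
    E.each_row() += st.be;
    E += P.rows(1, Tb);
    H.rows(r0 + 1, r0 + Tb) = E;
  }

  st.LP.resize(n_layers);
  st.CC.resize(n_layers);
  for (int l = 0; l < n_layers; ++l) st.LP[l] = get_layer(params, l);

  for (int l = 0; l < n_layers; ++l) {
    LayerParams& lp = st.LP[l];
    LayerCache& cc = st.CC[l];
    cc.Hin = H;
    cc.Qs = H * lp.Wq; cc.Qs.each_row() += lp.bq;
    cc.Ks = H * lp.Wk; cc.Ks.each_row() += lp.bk;
    cc.Vs = H * lp.Wv; cc.Vs.each_row() += lp.bv;
    cc.A.set_size(B * N * n_heads, N);
    cc.O.set_size(B * N, D);
    for (int b = 0; b < B; ++b) {
      int r0 = b * N;
      for (int h = 0; h < n_heads; ++h) {
        int c0 = h * dh;
        mat Q = cc.Qs.submat(r0, c0, r0 + N - 1, c0 + dh - 1);
        mat K = cc.Ks.submat(r0, c0, r0 + N - 1, c0 + dh - 1);
        mat V = cc.Vs.submat(r0, c0, r0 + N - 1, c0 + dh - 1);
        mat S = (Q * K.t()) * sc;
        for (int j = 0; j < Tb; ++j)
          if (mask(j, b) == 0) S.col(j + 1).fill(MASK_NEG);
        vec mx = max(S, 1);
        S.each_col() -= mx;
        S = exp(S);
        vec rs = sum(S, 1);
        S.each_col() /= rs;
        cc.A.rows((b * n_heads + h) * N, (b * n_heads + h) * N + N - 1) = S;
        cc.O.submat(r0, c0, r0 + N - 1, c0 + dh - 1) = S * V;
      }
    }
    mat At = cc.O * lp.Wo; At.each_row() += lp.bo;
    mat R1 = cc.Hin + At;
    ln_forward(R1, lp.g1, lp.d1, cc.Z, cc.xh1, cc.is1);
    cc.Fpre = cc.Z * lp.W1; cc.Fpre.each_row() += lp.c1;
    cc.Frelu = cc.Fpre;
    cc.Frelu.transform([](double x){ return x > 0 ? x : 0.0; });
    mat M = cc.Frelu * lp.W2; M.each_row() += lp.c2;
    mat R2 = cc.Z + M;
    ln_forward(R2, lp.g2, lp.d2, H, cc.xh2, cc.is2);
  }

  chi.set_size(D, B);
  for (int b = 0; b < B; ++b) chi.col(b) = H.row(b * N).t();

  if (want_attn) {
    Rcpp::List al(n_layers);
    for (int l = 0; l < n_layers; ++l) {
      Rcpp::List bl(B);
      for (int b = 0; b < B; ++b) {
        cube Ab(N, N, n_heads);
        for (int h = 0; h < n_heads; ++h)
          Ab.slice(h) = st.CC[l].A.rows((b * n_heads + h) * N,
                                        (b * n_heads + h) * N + N - 1);
        bl[b] = Ab;
      }
      al[l] = bl;
    }
    attn_out = al;
  }
}

static List backward_impl(TfState& st, const mat& dchi) {
  const int B = st.B, N = st.N, D = st.D, Tb = st.Tb, C = st.C;
  mat dH(B * N, D, fill::zeros);
  for (int b = 0; b < B; ++b) dH.row(b * N) = dchi.col(b).t();

  List grads;
  for (int l = st.L - 1; l >= 0; --l) {
    LayerParams& lp = st.LP[l];
    LayerCache& cc = st.CC[l];
    rowvec dg2(D, fill::zeros), dd2(D, fill::zeros);
    mat dR2 = ln_backward(dH, cc.xh2, cc.is2, lp.g2, dg2, dd2);
    mat dZ = dR2;
    mat dW2 = cc.Frelu.t() * dR2;
    rowvec dc2 = sum(dR2, 0);
    mat dFrelu = dR2 * lp.W2.t();
    mat relu_mask = conv_to<mat>::from(cc.Fpre > 0);
    mat dFpre = dFrelu % relu_mask;
    mat dW1 = cc.Z.t() * dFpre;
    rowvec dc1 = sum(dFpre, 0);
    dZ += dFpre * lp.W1.t();
    rowvec dg1(D, fill::zeros), dd1(D, fill::zeros);
    mat dR1 = ln_backward(dZ, cc.xh1, cc.is1, lp.g1, dg1, dd1);
    mat dHin = dR1;
    mat dWo = cc.O.t() * dR1;
    rowvec dbo = sum(dR1, 0);
    mat dO = dR1 * lp.Wo.t();
    mat dQs(B * N, D, fill::zeros), dKs(B * N, D, fill::zeros),
        dVs(B * N, D, fill::zeros);
    const double scl = 1.0 / std::sqrt((double)st.dh);
    for (int b = 0; b < B; ++b) {
      int r0 = b * N;
      for (int h = 0; h < st.H; ++h) {
        int c0 = h * st.dh;
        mat A = cc.A.rows((b * st.H + h) * N, (b * st.H + h) * N + N - 1);
        mat Q = cc.Qs.submat(r0, c0, r0 + N - 1, c0 + st.dh - 1);
        mat K = cc.Ks.submat(r0, c0, r0 + N - 1, c0 + st.dh - 1);
        mat V = cc.Vs.submat(r0, c0, r0 + N - 1, c0 + st.dh - 1);
        mat dOh = dO.submat(r0, c0, r0 + N - 1, c0 + st.dh - 1);
        mat dA = dOh * V.t();
        dVs.submat(r0, c0, r0 + N - 1, c0 + st.dh - 1) = A.t() * dOh;
        vec dot = sum(dA % A, 1);
        mat dS = dA;
        dS.each_col() -= dot;
        dS %= A;
        dS *= scl;
        dQs.submat(r0, c0, r0 + N - 1, c0 + st.dh - 1) = dS * K;
        dKs.submat(r0, c0, r0 + N - 1, c0 + st.dh - 1) = dS.t() * Q;
      }
    }
    mat dWq = cc.Hin.t() * dQs;  rowvec dbq = sum(dQs, 0);
    mat dWk = cc.Hin.t() * dKs;  rowvec dbk = sum(dKs, 0);
    mat dWv = cc.Hin.t() * dVs;  rowvec dbv = sum(dVs, 0);
    dHin += dQs * lp.Wq.t() + dKs * lp.Wk.t() + dVs * lp.Wv.t();
    std::string p = "l" + std::to_string(l + 1) + "_";
    grads[p + "Wq"] = dWq; grads[p + "bq"] = Rcpp::wrap(conv_to<std::vector<double> >::from(dbq));
    grads[p + "Wk"] = dWk; grads[p + "bk"] = Rcpp::wrap(conv_to<std::vector<double> >::from(dbk));
    grads[p + "Wv"] = dWv; grads[p + "bv"] = Rcpp::wrap(conv_to<std::vector<double> >::from(dbv));
    grads[p + "Wo"] = dWo; grads[p + "bo"] = Rcpp::wrap(conv_to<std::vector<double> >::from(dbo));
    grads[p + "W1"] = dW1; grads[p + "c1"] = Rcpp::wrap(conv_to<std::vector<double> >::from(dc1));
    grads[p + "W2"] = dW2; grads[p + "c2"] = Rcpp::wrap(conv_to<std::vector<double> >::from(dc2));
    grads[p + "ln1_g"] = Rcpp::wrap(conv_to<std::vector<double> >::from(dg1));
    grads[p + "ln1_b"] = Rcpp::wrap(conv_to<std::vector<double> >::from(dd1));
    grads[p + "ln2_g"] = Rcpp::wrap(conv_to<std::vector<double> >::from(dg2));
    grads[p + "ln2_b"] = Rcpp::wrap(conv_to<std::vector<double> >::from(dd2));
    dH = dHin;
  }

  mat dWe(C, D, fill::zeros);
  rowvec dbe(D, fill::zeros), dcls(D, fill::zeros);
  cube dX(C, Tb, B);
  for (int b = 0; b < B; ++b) {
    int r0 = b * N;
    dcls += dH.row(r0);
    mat dE = dH.rows(r0 + 1, r0 + Tb);
    dWe += st.X.slice(b) * dE;
    dbe += sum(dE, 0);
    dX.slice(b) = st.We * dE.t();
  }
  grads["W_e"] = dWe;
  grads["b_e"] = Rcpp::wrap(conv_to<std::vector<double> >::from(dbe));
  grads["cls"] = Rcpp::wrap(conv_to<std::vector<double> >::from(dcls));

  // caches are one-shot: release them eagerly rather than waiting for GC
  st.CC.clear();
  st.CC.shrink_to_fit();

  return List::create(Named("grads") = grads, Named("dX") = dX);
}

// [[Rcpp::export]]
List tf_kernel(List params, arma::cube X, arma::imat mask,
               int n_heads, int n_layers,
               Rcpp::Nullable<Rcpp::NumericMatrix> dchi_ = R_NilValue,
               bool return_attn = false, bool want_state = false) {
  mat chi;
  Rcpp::List attn_out;
  if (want_state) {
    Rcpp::XPtr<TfState> st(new TfState(), true);
    forward_impl(params, X, mask, n_heads, n_layers, *st, chi,
                 return_attn, attn_out);
    List out = List::create(Named("chi") = chi, Named("state") = st);
    if (return_attn) out["attn"] = attn_out;
    return out;
  }
  TfState st;
  forward_impl(params, X, mask, n_heads, n_layers, st, chi,
               return_attn, attn_out);
  List out = List::create(Named("chi") = chi);
  if (return_attn) out["attn"] = attn_out;
  if (dchi_.isNull()) return out;
  mat dchi = Rcpp::as<mat>(dchi_);
  List bk = backward_impl(st, dchi);
  out["grads"] = bk["grads"];
  out["dX"] = bk["dX"];
  return out;
}

// [[Rcpp::export]]
List tf_kernel_grad(SEXP state, arma::mat dchi) {
  Rcpp::XPtr<TfState> st(state);
  return backward_impl(*st, dchi);
}
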