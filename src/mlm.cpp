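// Compact transformer encoder with manual backpropagation.
//
// Parameters travel as an R list in a fixed order (see param_order() on the
// R side): E_tok, E_pos, then per layer {Wq,bq,Wk,bk,Wv,bv,Wo,bo,
// g1,be1,W1,b1,W2,b2,g2,be2}, then {gf,bf,Whd,bhd}. Pre-layer-norm blocks:
//   y  = x + Attn(LN1(x));  x' = y + FFN(LN2(y));  H = LNf(x_last)
// The masked-token head reads selected rows of H. All ids are 0-based.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;
using arma::uword;

static const double LN_EPS = 1e-5;

struct LayerParams {
  mat Wq, Wk, Wv, Wo, W1, W2;
  rowvec bq, bk, bv, bo, b1, b2, g1, be1, g2, be2;
};

struct LayerCache {
  mat x_in;          // input to the block (N x d)
  mat xhat1; vec istd1;
  mat y1;            // LN1 output
  mat Q, K, V;       // projections
  arma::cube A;      // attention weights (L x L x B*H)
  mat C;             // concatenated head outputs
  mat drop1;         // dropout mask on attention output (empty if p = 0)
  mat x2;            // after first residual
  mat xhat2; vec istd2;
  mat y2;            // LN2 output
  mat Fa;            // ReLU activations (N x ff)
  mat drop2;         // dropout mask on FFN output
};

static rowvec get_bias(const List& params, int i) {
  NumericMatrix m = params[i];
  rowvec b(m.ncol());
  for (int j = 0; j < m.ncol(); ++j) b[j] = m(0, j);
  return b;
}

static void ln_forward(const mat& X, const rowvec& g, const rowvec& b,
                       mat& Y, mat& xhat, vec& istd) {
  vec mu = arma::mean(X, 1);
  mat xc = X.each_col() - mu;
  vec v = arma::mean(xc % xc, 1);
  istd = 1.0 / arma::sqrt(v + LN_EPS);
  xhat = xc.each_col() % istd;
  Y = xhat.each_row() % g;
  Y.each_row() += b;
}

static mat ln_backward(const mat& dY, const mat& xhat, const vec& istd,
                       const rowvec& g, rowvec& dg, rowvec& db) {
  dg = arma::sum(dY % xhat, 0);
  db = arma::sum(dY, 0);
  mat dxhat = dY.each_row() % g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= istd;
  return dX;
}

static void softmax_rows_inplace(mat& S) {
  vec mx = arma::max(S, 1);
  S.each_col() -= mx;
  S = arma::exp(S);
  vec sums = arma::sum(S, 1);
  S.each_col() /= sums;
}

static mat dropout_mask(uword n, uword m, double p, std::mt19937_64& rng) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  mat M(n, m);
  double scale = 1.0 / (1.0 - p);
  for (uword j = 0; j < m; ++j)
    for (uword i = 0; i < n; ++i)
      M(i, j) = (unif(rng) >= p) ? scale : 0.0;
  return M;
}

// Forward pass over a stacked batch. tokens is B x L (0-based ids).
// Returns final hidden states H (B*L x d); fills caches when training.
static mat forward_pass(const IntegerMatrix& tokens, const List& params,
                        int n_layers, int n_heads, double dropout,
                        std::mt19937_64* rng, bool keep_cache,
                        std::vector<LayerCache>& caches,
                        mat& xhat_f, vec& istd_f, mat& x_last) {
  const mat E_tok = as<mat>(params[0]);
  const mat E_pos = as<mat>(params[1]);
  const int B = tokens.nrow(), L = tokens.ncol();
  const int d = E_tok.n_cols;
  const int dh = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  const int N = B * L;

  mat X(N, d);
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < L; ++p)
      X.row(b * L + p) = E_tok.row(tokens(b, p)) + E_pos.row(p);

  if (keep_cache) caches.resize(n_layers);

  for (int l = 0; l < n_layers; ++l) {
    int base = 2 + 16 * l;
    LayerParams P;
    P.Wq = as<mat>(params[base + 0]);  P.bq = get_bias(params, base + 1);
    P.Wk = as<mat>(params[base + 2]);  P.bk = get_bias(params, base + 3);
    P.Wv = as<mat>(params[base + 4]);  P.bv = get_bias(params, base + 5);
    P.Wo = as<mat>(params[base + 6]);  P.bo = get_bias(params, base + 7);
    P.g1 = get_bias(params, base + 8); P.be1 = get_bias(params, base + 9);
    P.W1 = as<mat>(params[base + 10]); P.b1 = get_bias(params, base + 11);
    P.W2 = as<mat>(params[base + 12]); P.b2 = get_bias(params, base + 13);
    P.g2 = get_bias(params, base + 14); P.be2 = get_bias(params, base + 15);

    mat y1, xhat1; vec istd1;
    ln_forward(X, P.g1, P.be1, y1, xhat1, istd1);
    mat Q = y1 * P.Wq; Q.each_row() += P.bq;
    mat K = y1 * P.Wk; K.each_row() += P.bk;
    mat V = y1 * P.Wv; V.each_row() += P.bv;

    mat C(N, d);
    arma::cube A;
    if (keep_cache) A.set_size(L, L, (uword)B * n_heads);
    for (int b = 0; b < B; ++b) {
      uword r0 = (uword)b * L, r1 = r0 + L - 1;
      for (int h = 0; h < n_heads; ++h) {
        uword c0 = (uword)h * dh, c1 = c0 + dh - 1;
        mat S = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() * scale;
        softmax_rows_inplace(S);
        C.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
        if (keep_cache) A.slice((uword)b * n_heads + h) = S;
      }
    }
    mat attn = C * P.Wo; attn.each_row() += P.bo;
    mat drop1;
    if (dropout > 0 && rng) { drop1 = dropout_mask(N, d, dropout, *rng); attn %= drop1; }
    mat x2 = X + attn;

    mat y2, xhat2; vec istd2;
    ln_forward(x2, P.g2, P.be2, y2, xhat2, istd2);
    mat F1 = y2 * P.W1; F1.each_row() += P.b1;
    mat Fa = arma::clamp(F1, 0.0, arma::datum::inf);
    mat F2 = Fa * P.W2; F2.each_row() += P.b2;
    mat drop2;
    if (dropout > 0 && rng) { drop2 = dropout_mask(N, F2.n_cols == (uword)d ? d : F2.n_cols, dropout, *rng); F2 %= drop2; }
    mat x_next = x2 + F2;

    if (keep_cache) {
      LayerCache& cc = caches[l];
      cc.x_in = X; cc.xhat1 = xhat1; cc.istd1 = istd1; cc.y1 = y1;
      cc.Q = Q; cc.K = K; cc.V = V; cc.A = A; cc.C = C; cc.drop1 = drop1;
      cc.x2 = x2; cc.xhat2 = xhat2; cc.istd2 = istd2; cc.y2 = y2;
      cc.Fa = Fa; cc.drop2 = drop2;
    }
    X = x_next;
  }

  const rowvec gf = get_bias(params, 2 + 16 * n_layers);
  const rowvec bf = get_bias(params, 2 + 16 * n_layers + 1);
  x_last = X;
  mat H;
  ln_forward(X, gf, bf, H, xhat_f, istd_f);
  return H;
}

// [[Rcpp::export]]
NumericMatrix cpp_mlm_hidden(IntegerMatrix tokens, List params,
                             int n_layers, int n_heads) {
  std::vector<LayerCache> caches;
  mat xhat_f; vec istd_f; mat x_last;
  mat H = forward_pass(tokens, params, n_layers, n_heads, 0.0, nullptr,
                       false, caches, xhat_f, istd_f, x_last);
  return wrap(H);
}

// Logits at selected (sequence, position) pairs; sel is n x 2, 1-based.
// [[Rcpp::export]]
NumericMatrix cpp_mlm_logits(IntegerMatrix tokens, IntegerMatrix sel,
                             List params, int n_layers, int n_heads) {
  std::vector<LayerCache> caches;
  mat xhat_f; vec istd_f; mat x_last;
  mat H = forward_pass(tokens, params, n_layers, n_heads, 0.0, nullptr,
                       false, caches, xhat_f, istd_f, x_last);
  const int L = tokens.ncol();
  const mat Whd = as<mat>(params[2 + 16 * n_layers + 2]);
  const rowvec bhd = get_bias(params, 2 + 16 * n_layers + 3);
  const int n = sel.nrow();
  mat Hsel(n, H.n_cols);
  for (int i = 0; i < n; ++i)
    Hsel.row(i) = H.row((uword)(sel(i, 0) - 1) * L + (sel(i, 1) - 1));
  mat logits = Hsel * Whd;
  logits.each_row() += bhd;
  return wrap(logits);
}

// Masked-token cross-entropy over target triplets (seq, pos, token id)
// with per-target weights; optionally returns gradients for every
// parameter (same list order).
// [[Rcpp::export]]
List cpp_mlm_train_batch(IntegerMatrix tokens, IntegerMatrix targets,
                         NumericVector weights,
                         List params, int n_layers, int n_heads,
                         double dropout, int dropout_seed, bool want_grad) {
  std::mt19937_64 rng((uint64_t)dropout_seed);
  std::vector<LayerCache> caches;
  mat xhat_f; vec istd_f; mat x_last;
  mat H = forward_pass(tokens, params, n_layers, n_heads, dropout,
                       dropout > 0 ? &rng : nullptr, want_grad, caches,
                       xhat_f, istd_f, x_last);
  const int B = tokens.nrow(), L = tokens.ncol();
  const mat E_tok = as<mat>(params[0]);
  const int d = E_tok.n_cols, k = E_tok.n_rows;
  const int dh = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  const mat Whd = as<mat>(params[2 + 16 * n_layers + 2]);
  const rowvec bhd = get_bias(params, 2 + 16 * n_layers + 3);
  const rowvec gf = get_bias(params, 2 + 16 * n_layers);

  const int n_t = targets.nrow();
  if (n_t == 0) stop("no prediction targets in batch");
  if (weights.size() != n_t) stop("one weight per target required");
  double wsum = 0.0;
  for (int i = 0; i < n_t; ++i) wsum += weights[i];
  if (wsum <= 0) stop("target weights must sum to a positive value");
  mat Hsel(n_t, d);
  for (int i = 0; i < n_t; ++i)
    Hsel.row(i) = H.row((uword)(targets(i, 0) - 1) * L + (targets(i, 1) - 1));
  mat logits = Hsel * Whd;
  logits.each_row() += bhd;
  mat Pm = logits;
  softmax_rows_inplace(Pm);
  double loss = 0.0;
  for (int i = 0; i < n_t; ++i)
    loss -= weights[i] * std::log(std::max(Pm(i, targets(i, 2)), 1e-300));
  loss /= wsum;

  if (!want_grad)
    return List::create(Named("loss") = loss);

  // ---- backward ----
  mat dlogits = Pm;
  for (int i = 0; i < n_t; ++i) dlogits(i, targets(i, 2)) -= 1.0;
  for (int i = 0; i < n_t; ++i) dlogits.row(i) *= weights[i];
  dlogits /= wsum;

  mat dWhd = Hsel.t() * dlogits;
  rowvec dbhd = arma::sum(dlogits, 0);
  mat dHsel = dlogits * Whd.t();
  mat dH(arma::size(H), arma::fill::zeros);
  for (int i = 0; i < n_t; ++i)
    dH.row((uword)(targets(i, 0) - 1) * L + (targets(i, 1) - 1)) += dHsel.row(i);

  rowvec dgf, dbf;
  mat dX = ln_backward(dH, xhat_f, istd_f, gf, dgf, dbf);

  List grads(params.size());
  grads[2 + 16 * n_layers] = wrap(mat(dgf));
  grads[2 + 16 * n_layers + 1] = wrap(mat(dbf));
  grads[2 + 16 * n_layers + 2] = wrap(dWhd);
  grads[2 + 16 * n_layers + 3] = wrap(mat(dbhd));

  for (int l = n_layers - 1; l >= 0; --l) {
    int base = 2 + 16 * l;
    const LayerCache& cc = caches[l];
    const mat Wq = as<mat>(params[base + 0]);
    const mat Wk = as<mat>(params[base + 2]);
    const mat Wv = as<mat>(params[base + 4]);
    const mat Wo = as<mat>(params[base + 6]);
    const rowvec g1 = get_bias(params, base + 8);
    const mat W1 = as<mat>(params[base + 10]);
    const mat W2 = as<mat>(params[base + 12]);
    const rowvec g2 = get_bias(params, base + 14);

    // FFN sub-block: x_next = x2 + drop2(relu(LN2(x2) W1 + b1) W2 + b2)
    mat dF2 = dX;
    if (!cc.drop2.is_empty()) dF2 %= cc.drop2;
    mat dW2 = cc.Fa.t() * dF2;
    rowvec db2 = arma::sum(dF2, 0);
    mat dFa = dF2 * W2.t();
    mat dF1 = dFa % arma::conv_to<mat>::from(cc.Fa > 0);
    mat dW1 = cc.y2.t() * dF1;
    rowvec db1 = arma::sum(dF1, 0);
    mat dy2 = dF1 * W1.t();
    rowvec dg2, dbe2;
    mat dx2 = dX + ln_backward(dy2, cc.xhat2, cc.istd2, g2, dg2, dbe2);

    // attention sub-block: x2 = x + drop1(C Wo + bo)
    mat dattn = dx2;
    if (!cc.drop1.is_empty()) dattn %= cc.drop1;
    mat dWo = cc.C.t() * dattn;
    rowvec dbo = arma::sum(dattn, 0);
    mat dC = dattn * Wo.t();

    mat dQ(arma::size(cc.Q), arma::fill::zeros);
    mat dK(arma::size(cc.K), arma::fill::zeros);
    mat dV(arma::size(cc.V), arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      uword r0 = (uword)b * L, r1 = r0 + L - 1;
      for (int h = 0; h < n_heads; ++h) {
        uword c0 = (uword)h * dh, c1 = c0 + dh - 1;
        const mat& A = cc.A.slice((uword)b * n_heads + h);
        mat dCh = dC.submat(r0, c0, r1, c1);
        mat Vh = cc.V.submat(r0, c0, r1, c1);
        mat dA = dCh * Vh.t();
        dV.submat(r0, c0, r1, c1) = A.t() * dCh;
        vec rowdot = arma::sum(dA % A, 1);
        dA.each_col() -= rowdot;
        mat dS = A % dA;
        dQ.submat(r0, c0, r1, c1) = dS * cc.K.submat(r0, c0, r1, c1) * scale;
        dK.submat(r0, c0, r1, c1) = dS.t() * cc.Q.submat(r0, c0, r1, c1) * scale;
      }
    }
    mat dWq = cc.y1.t() * dQ;  rowvec dbq = arma::sum(dQ, 0);
    mat dWk = cc.y1.t() * dK;  rowvec dbk = arma::sum(dK, 0);
    mat dWv = cc.y1.t() * dV;  rowvec dbv = arma::sum(dV, 0);
    mat dy1 = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
    rowvec dg1, dbe1;
    mat dx_in = dx2 + ln_backward(dy1, cc.xhat1, cc.istd1, g1, dg1, dbe1);

    grads[base + 0] = wrap(dWq);  grads[base + 1] = wrap(mat(dbq));
    grads[base + 2] = wrap(dWk);  grads[base + 3] = wrap(mat(dbk));
    grads[base + 4] = wrap(dWv);  grads[base + 5] = wrap(mat(dbv));
    grads[base + 6] = wrap(dWo);  grads[base + 7] = wrap(mat(dbo));
    grads[base + 8] = wrap(mat(dg1)); grads[base + 9] = wrap(mat(dbe1));
    grads[base + 10] = wrap(dW1); grads[base + 11] = wrap(mat(db1));
    grads[base + 12] = wrap(dW2); grads[base + 13] = wrap(mat(db2));
    grads[base + 14] = wrap(mat(dg2)); grads[base + 15] = wrap(mat(dbe2));
    dX = dx_in;
  }

  // embedding gradients: scatter-add dX by token id / position
  mat dEtok(k, d, arma::fill::zeros);
  mat dEpos(L, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < L; ++p) {
      dEtok.row(tokens(b, p)) += dX.row((uword)b * L + p);
      dEpos.row(p) += dX.row((uword)b * L + p);
    }
  grads[0] = wrap(dEtok);
  grads[1] = wrap(dEpos);

  return List::create(Named("loss") = loss, Named("grads") = grads);
}
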