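// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Multi-head scaled-dot-product self-attention over a batch laid out as
// (B*T) x d matrices with rows grouped by sample. `mask` is B x T (1 = real
// token); masked key positions receive zero attention weight exactly.
// Softmax rows are stabilized by their row maximum over unmasked entries.

static inline void masked_softmax_rows(arma::mat& S,
                                       const arma::uvec& pad) {
  for (arma::uword j = 0; j < pad.n_elem; j++) {
    S.col(pad[j]).fill(-arma::datum::inf);
  }
  arma::vec mx = arma::max(S, 1);
  S.each_col() -= mx;
  S = arma::exp(S);               // exp(-Inf) = 0: masked keys get weight 0
  arma::vec rs = arma::sum(S, 1);
  S.each_col() /= rs;
}

// [[Rcpp::export(name = ".attn_forward")]]
arma::mat attn_forward(const arma::mat& Q, const arma::mat& K,
                       const arma::mat& V, const arma::imat& mask,
                       int n_heads, double scale) {
  const int B = mask.n_rows, T = mask.n_cols;
  const int d = Q.n_cols, dh = d / n_heads;
  arma::mat O(Q.n_rows, d, arma::fill::zeros);
  for (int b = 0; b < B; b++) {
    arma::uvec pad = arma::find(mask.row(b).t() == 0);
    arma::uword r0 = (arma::uword)b * T, r1 = r0 + T - 1;
    for (int h = 0; h < n_heads; h++) {
      arma::uword c0 = (arma::uword)h * dh, c1 = c0 + dh - 1;
      arma::mat S = Q.submat(r0, c0, r1, c1) *
        K.submat(r0, c0, r1, c1).t() * scale;
      masked_softmax_rows(S, pad);
      O.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
    }
  }
  return O;
}

// Backward pass; recomputes the attention weights from Q and K rather than
// caching B*H TxT matrices. Returns gradients for Q, K, V.
// [[Rcpp::export(name = ".attn_backward")]]
Rcpp::List attn_backward(const arma::mat& Q, const arma::mat& K,
                         const arma::mat& V, const arma::mat& dO,
                         const arma::imat& mask, int n_heads, double scale) {
  const int B = mask.n_rows, T = mask.n_cols;
  const int d = Q.n_cols, dh = d / n_heads;
  arma::mat dQ(Q.n_rows, d, arma::fill::zeros);
  arma::mat dK(Q.n_rows, d, arma::fill::zeros);
  arma::mat dV(Q.n_rows, d, arma::fill::zeros);
  for (int b = 0; b < B; b++) {
    arma::uvec pad = arma::find(mask.row(b).t() == 0);
    arma::uword r0 = (arma::uword)b * T, r1 = r0 + T - 1;
    for (int h = 0; h < n_heads; h++) {
      arma::uword c0 = (arma::uword)h * dh, c1 = c0 + dh - 1;
      arma::mat Qb = Q.submat(r0, c0, r1, c1);
      arma::mat Kb = K.submat(r0, c0, r1, c1);
      arma::mat A = Qb * Kb.t() * scale;
      masked_softmax_rows(A, pad);
      arma::mat dOb = dO.submat(r0, c0, r1, c1);
      dV.submat(r0, c0, r1, c1) = A.t() * dOb;
      arma::mat dA = dOb * V.submat(r0, c0, r1, c1).t();
      arma::vec rs = arma::sum(dA % A, 1);
      arma::mat dS = A % (dA.each_col() - rs);
      dQ.submat(r0, c0, r1, c1) = dS * Kb * scale;
      dK.submat(r0, c0, r1, c1) = dS.t() * Qb * scale;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ,
                            Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}

// Fused sigmoid-approximation GELU and its derivative.
// [[Rcpp::export(name = ".gelu_fwd")]]
Rcpp::NumericMatrix gelu_fwd(Rcpp::NumericMatrix Z) {
  Rcpp::NumericMatrix out(Z.nrow(), Z.ncol());
  R_xlen_t n = Z.size();
  for (R_xlen_t i = 0; i < n; i++) {
    double z = Z[i];
    out[i] = z / (1.0 + std::exp(-1.702 * z));
  }
  return out;
}

// [[Rcpp::export(name = ".gelu_bwd")]]
Rcpp::NumericMatrix gelu_bwd(Rcpp::NumericMatrix Z) {
  Rcpp::NumericMatrix out(Z.nrow(), Z.ncol());
  R_xlen_t n = Z.size();
  for (R_xlen_t i = 0; i < n; i++) {
    double z = Z[i];
    double s = 1.0 / (1.0 + std::exp(-1.702 * z));
    out[i] = s + 1.702 * z * s * (1.0 - s);
  }
  return out;
}
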