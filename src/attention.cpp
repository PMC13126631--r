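#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Batched multi-head self-attention. Q, K, V are (B*T) x D with sample b
// occupying rows [b*T, (b+1)*T); head h occupies columns [h*dh, (h+1)*dh),
// dh = D / H. Returns the attention output (B*T) x D and the row-softmaxed
// attention weights as a T x T x (B*H) cube (slice index b*H + h), which the
// backward pass and attention rollout both consume.
// [[Rcpp::export(name = ".cpp_attn_forward")]]
List cpp_attn_forward(const arma::mat& Q, const arma::mat& K,
                      const arma::mat& V, int B, int T, int H) {
  int D = Q.n_cols, dh = D / H;
  double scale = 1.0 / std::sqrt((double)dh);
  arma::mat out(B * T, D);
  arma::cube A(T, T, B * H);
  for (int b = 0; b < B; ++b) {
    int r0 = b * T, r1 = r0 + T - 1;
    for (int h = 0; h < H; ++h) {
      int c0 = h * dh, c1 = c0 + dh - 1;
      arma::mat Qb = Q.submat(r0, c0, r1, c1);
      arma::mat Kb = K.submat(r0, c0, r1, c1);
      arma::mat Vb = V.submat(r0, c0, r1, c1);
      arma::mat S = (Qb * Kb.t()) * scale;
      S.each_col() -= arma::max(S, 1);
      arma::mat E = arma::exp(S);
      E.each_col() /= arma::sum(E, 1);
      A.slice(b * H + h) = E;
      out.submat(r0, c0, r1, c1) = E * Vb;
    }
  }
  return List::create(_["out"] = out, _["att"] = A);
}

// [[Rcpp::export(name = ".cpp_attn_backward")]]
List cpp_attn_backward(const arma::mat& dOut, const arma::mat& Q,
                       const arma::mat& K, const arma::mat& V,
                       const arma::cube& A, int B, int T, int H) {
  int D = Q.n_cols, dh = D / H;
  double scale = 1.0 / std::sqrt((double)dh);
  arma::mat dQ(B * T, D), dK(B * T, D), dV(B * T, D);
  for (int b = 0; b < B; ++b) {
    int r0 = b * T, r1 = r0 + T - 1;
    for (int h = 0; h < H; ++h) {
      int c0 = h * dh, c1 = c0 + dh - 1;
      arma::mat Qb = Q.submat(r0, c0, r1, c1);
      arma::mat Kb = K.submat(r0, c0, r1, c1);
      arma::mat Vb = V.submat(r0, c0, r1, c1);
      arma::mat dOb = dOut.submat(r0, c0, r1, c1);
      const arma::mat& Ab = A.slice(b * H + h);
      arma::mat dA = dOb * Vb.t();
      dV.submat(r0, c0, r1, c1) = Ab.t() * dOb;
      arma::vec rs = arma::sum(dA % Ab, 1);
      arma::mat dS = Ab % (dA.each_col() - rs);
      dQ.submat(r0, c0, r1, c1) = (dS * Kb) * scale;
      dK.submat(r0, c0, r1, c1) = (dS.t() * Qb) * scale;
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
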