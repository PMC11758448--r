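// Batched slice-wise matrix products for windowed attention.
// A cube holds one small matrix per slice (one per attention window);
// products are taken slice by slice, optionally transposing either factor.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Fused windowed attention forward: per slice S = scale * Q K^T, row-wise
// softmax P, output O = P V. Returns O and P (P is needed for backward).
// [[Rcpp::export]]
Rcpp::List attn_forward_cpp(const arma::cube& Q, const arma::cube& K,
                            const arma::cube& V, double scale) {
  const arma::uword ns = Q.n_slices;
  const arma::uword w = Q.n_rows;
  arma::cube O(w, V.n_cols, ns), P(w, K.n_rows, ns);
  for (arma::uword s = 0; s < ns; ++s) {
    arma::mat S = scale * (Q.slice(s) * K.slice(s).t());
    S.each_col() -= arma::max(S, 1);
    S = arma::exp(S);
    S.each_col() /= arma::sum(S, 1);
    P.slice(s) = S;
    O.slice(s) = S * V.slice(s);
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("P") = P);
}

// Backward of the fused attention: gradients w.r.t. Q, K, V.
// [[Rcpp::export]]
Rcpp::List attn_backward_cpp(const arma::cube& gO, const arma::cube& P,
                             const arma::cube& Q, const arma::cube& K,
                             const arma::cube& V, double scale) {
  const arma::uword ns = Q.n_slices;
  arma::cube gQ(arma::size(Q)), gK(arma::size(K)), gV(arma::size(V));
  for (arma::uword s = 0; s < ns; ++s) {
    const arma::mat& Ps = P.slice(s);
    gV.slice(s) = Ps.t() * gO.slice(s);
    arma::mat gP = gO.slice(s) * V.slice(s).t();
    arma::vec rs = arma::sum(Ps % gP, 1);
    arma::mat gS = gP;
    gS.each_col() -= rs;
    gS %= Ps;                 // gS = P % (gP - rowsum(P % gP))
    gQ.slice(s) = scale * (gS * K.slice(s));
    gK.slice(s) = scale * (gS.t() * Q.slice(s));
  }
  return Rcpp::List::create(Rcpp::Named("gQ") = gQ, Rcpp::Named("gK") = gK,
                            Rcpp::Named("gV") = gV);
}

// [[Rcpp::export]]
arma::cube cube_matmul_cpp(const arma::cube& A, const arma::cube& B,
                           bool ta, bool tb) {
  const arma::uword ns = A.n_slices;
  if (B.n_slices != ns) Rcpp::stop("slice counts differ");
  const arma::uword m = ta ? A.n_cols : A.n_rows;
  const arma::uword p = tb ? B.n_rows : B.n_cols;
  arma::cube C(m, p, ns);
  for (arma::uword s = 0; s < ns; ++s) {
    const arma::mat& As = A.slice(s);
    const arma::mat& Bs = B.slice(s);
    if (!ta && !tb)      C.slice(s) = As * Bs;
    else if (!ta && tb)  C.slice(s) = As * Bs.t();
    else if (ta && !tb)  C.slice(s) = As.t() * Bs;
    else                 C.slice(s) = As.t() * Bs.t();
  }
  return C;
}
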