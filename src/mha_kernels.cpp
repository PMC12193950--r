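// Batched masked multi-head attention kernels. The linear projections are
// done in R with BLAS; these kernels only run the per-sample, per-head
// attention (scores, masked softmax, weighted values) and its exact
// gradient, which would otherwise dominate runtime as interpreted loops.
// Layout: stacked sample-major streams, i.e. row (i-1)*L + t is token t of
// sample i; heads live in contiguous column blocks of width d/nh.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

static const double MASK_NEG = -1e30;

// row-softmax of S with masked key columns already set to MASK_NEG;
// an all-masked row degrades to a constant row and softmaxes to uniform
static void row_softmax(arma::mat& S) {
  arma::vec m = arma::max(S, 1);
  S.each_col() -= m;
  S = arma::exp(S);
  arma::vec rs = arma::sum(S, 1);
  S.each_col() /= rs;
}

// [[Rcpp::export(rng = false)]]
arma::mat mhaAttendFwd(const arma::mat& Q, const arma::mat& K,
                       const arma::mat& V, const arma::imat& mask,
                       int B, int Lq, int Lk, int nh) {
  const int d = Q.n_cols;
  const int dk = d / nh;
  const double scal = 1.0 / std::sqrt((double) dk);
  arma::mat C(B * Lq, d, arma::fill::zeros);
  for (int i = 0; i < B; ++i) {
    const arma::uvec nc = arma::find(mask.row(i) == 0);
    const int q0 = i * Lq, k0 = i * Lk;
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dk;
      arma::mat Qh = Q.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1);
      arma::mat Kh = K.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1);
      arma::mat S = Qh * Kh.t() * scal;
      for (arma::uword j = 0; j < nc.n_elem; ++j) S.col(nc(j)).fill(MASK_NEG);
      row_softmax(S);
      C.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1) =
        S * V.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1);
    }
  }
  return C;
}

// [[Rcpp::export(rng = false)]]
Rcpp::List mhaAttendBwd(const arma::mat& dC, const arma::mat& Q,
                        const arma::mat& K, const arma::mat& V,
                        const arma::imat& mask,
                        int B, int Lq, int Lk, int nh) {
  const int d = Q.n_cols;
  const int dk = d / nh;
  const double scal = 1.0 / std::sqrt((double) dk);
  arma::mat dQ(arma::size(Q), arma::fill::zeros);
  arma::mat dK(arma::size(K), arma::fill::zeros);
  arma::mat dV(arma::size(V), arma::fill::zeros);
  for (int i = 0; i < B; ++i) {
    const arma::uvec nc = arma::find(mask.row(i) == 0);
    const int q0 = i * Lq, k0 = i * Lk;
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dk;
      arma::mat Qh = Q.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1);
      arma::mat Kh = K.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1);
      arma::mat Vh = V.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1);
      arma::mat S = Qh * Kh.t() * scal;
      for (arma::uword j = 0; j < nc.n_elem; ++j) S.col(nc(j)).fill(MASK_NEG);
      row_softmax(S);                      // S is now the weight matrix A
      arma::mat dCh = dC.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1);
      arma::mat dA = dCh * Vh.t();
      arma::vec rs = arma::sum(dA % S, 1);
      arma::mat dS = S % (dA.each_col() - rs);
      dQ.submat(q0, c0, q0 + Lq - 1, c0 + dk - 1) = dS * Kh * scal;
      dK.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1) = dS.t() * Qh * scal;
      dV.submat(k0, c0, k0 + Lk - 1, c0 + dk - 1) = S.t() * dCh;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ,
                            Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}
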