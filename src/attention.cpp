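// Batched scaled-dot-product multi-head self-attention kernels.
// Activations arrive as one (nseq * S) x d matrix of sequence-contiguous
// blocks; the per-sequence, per-head S x S softmax kernels loop here rather
// than in R. Gradients mirror the forward pass exactly and are pinned by
// finite-difference tests on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void softmax_rows_inplace(mat& s) {
  for (uword r = 0; r < s.n_rows; ++r) {
    rowvec row = s.row(r);
    row -= row.max();
    row = exp(row);
    s.row(r) = row / accu(row);
  }
}

// [[Rcpp::export(name = ".attn_fwd")]]
Rcpp::List attn_fwd(const arma::mat& Q, const arma::mat& K,
                    const arma::mat& V, int S, int h, double scale) {
  const int n = Q.n_rows;
  const int d = Q.n_cols;
  const int dk = d / h;
  const int nseq = n / S;
  mat O(n, d, fill::zeros);
  cube A(S, S * h, nseq); // head j occupies columns [j*S, (j+1)*S)
  for (int q = 0; q < nseq; ++q) {
    const uword r0 = (uword)q * S, r1 = r0 + S - 1;
    for (int j = 0; j < h; ++j) {
      const uword c0 = (uword)j * dk, c1 = c0 + dk - 1;
      mat sc = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() / scale;
      softmax_rows_inplace(sc);
      A.slice(q).cols((uword)j * S, (uword)(j + 1) * S - 1) = sc;
      O.submat(r0, c0, r1, c1) = sc * V.submat(r0, c0, r1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("A") = A);
}

// [[Rcpp::export(name = ".attn_bwd")]]
Rcpp::List attn_bwd(const arma::mat& dO, const arma::mat& Q,
                    const arma::mat& K, const arma::mat& V,
                    const arma::cube& A, int S, int h, double scale) {
  const int n = Q.n_rows;
  const int d = Q.n_cols;
  const int dk = d / h;
  const int nseq = n / S;
  mat dQ(n, d, fill::zeros), dK(n, d, fill::zeros), dV(n, d, fill::zeros);
  for (int q = 0; q < nseq; ++q) {
    const uword r0 = (uword)q * S, r1 = r0 + S - 1;
    for (int j = 0; j < h; ++j) {
      const uword c0 = (uword)j * dk, c1 = c0 + dk - 1;
      const mat Aq = A.slice(q).cols((uword)j * S, (uword)(j + 1) * S - 1);
      const mat dOh = dO.submat(r0, c0, r1, c1);
      const mat Vh = V.submat(r0, c0, r1, c1);
      mat dA = dOh * Vh.t();
      dV.submat(r0, c0, r1, c1) = Aq.t() * dOh;
      // softmax backward: dS = A * (dA - rowsum(A % dA))
      vec rs = sum(Aq % dA, 1);
      mat dS = (Aq % (dA - repmat(rs, 1, S))) / scale;
      dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1);
      dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}
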