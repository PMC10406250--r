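// Per-voxel symmetric 4x4 eigendecomposition and spectral rebuild for
// structure-tensor fields.  Fields are stored as n x 10 matrices of unique
// components in the order (11, 12, 13, 14, 22, 23, 24, 33, 34, 44).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void unpack(const arma::mat& comp, arma::uword v, arma::mat44& M) {
  M(0, 0) = comp(v, 0);
  M(0, 1) = M(1, 0) = comp(v, 1);
  M(0, 2) = M(2, 0) = comp(v, 2);
  M(0, 3) = M(3, 0) = comp(v, 3);
  M(1, 1) = comp(v, 4);
  M(1, 2) = M(2, 1) = comp(v, 5);
  M(1, 3) = M(3, 1) = comp(v, 6);
  M(2, 2) = comp(v, 7);
  M(2, 3) = M(3, 2) = comp(v, 8);
  M(3, 3) = comp(v, 9);
}

// Eigendecompose every voxel's tensor.  Eigenvalues are returned in
// descending order with matching eigenvector columns (vectors stored
// column-major per voxel: vectors(v, 4*k + i) = Q[i, k]).
// [[Rcpp::export]]
List eig4_field_cpp(const arma::mat& comp) {
  const arma::uword n = comp.n_rows;
  arma::mat values(n, 4), vectors(n, 16);
  arma::mat44 M;
  arma::vec eval;
  arma::mat evec;
  for (arma::uword v = 0; v < n; ++v) {
    unpack(comp, v, M);
    if (!arma::eig_sym(eval, evec, M)) {
      stop("eigendecomposition failed at voxel %d", (int)(v + 1));
    }
    // arma returns ascending order; flip to descending
    for (int k = 0; k < 4; ++k) {
      values(v, k) = eval(3 - k);
      for (int i = 0; i < 4; ++i) vectors(v, 4 * k + i) = evec(i, 3 - k);
    }
  }
  return List::create(Named("values") = values, Named("vectors") = vectors);
}

// Rebuild sum_k lambda_k q_k q_k^T from per-voxel eigenvalues/vectors.
// [[Rcpp::export]]
arma::mat rebuild4_field_cpp(const arma::mat& values, const arma::mat& vectors) {
  const arma::uword n = values.n_rows;
  arma::mat comp(n, 10);
  for (arma::uword v = 0; v < n; ++v) {
    double d[10] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
    for (int k = 0; k < 4; ++k) {
      const double lam = values(v, k);
      const double q0 = vectors(v, 4 * k + 0), q1 = vectors(v, 4 * k + 1),
                   q2 = vectors(v, 4 * k + 2), q3 = vectors(v, 4 * k + 3);
      d[0] += lam * q0 * q0;
      d[1] += lam * q0 * q1;
      d[2] += lam * q0 * q2;
      d[3] += lam * q0 * q3;
      d[4] += lam * q1 * q1;
      d[5] += lam * q1 * q2;
      d[6] += lam * q1 * q3;
      d[7] += lam * q2 * q2;
      d[8] += lam * q2 * q3;
      d[9] += lam * q3 * q3;
    }
    for (int j = 0; j < 10; ++j) comp(v, j) = d[j];
  }
  return comp;
}
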