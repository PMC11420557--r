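// Batch principal-strain computation for element-centroid strain tensors.
// Voigt convention: [exx, eyy, ezz, gxy, gyz, gxz] with engineering shears.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List principal_strains_batch(const arma::mat& voigt, bool directions) {
  const arma::uword n = voigt.n_rows;
  arma::mat vals(n, 3);
  arma::mat dirs;
  if (directions) dirs.set_size(n, 3);
  arma::mat33 A;
  arma::vec3 ev;
  arma::mat33 V;
  for (arma::uword i = 0; i < n; ++i) {
    const double exx = voigt(i, 0), eyy = voigt(i, 1), ezz = voigt(i, 2);
    const double exy = 0.5 * voigt(i, 3);
    const double eyz = 0.5 * voigt(i, 4);
    const double exz = 0.5 * voigt(i, 5);
    A(0, 0) = exx; A(0, 1) = exy; A(0, 2) = exz;
    A(1, 0) = exy; A(1, 1) = eyy; A(1, 2) = eyz;
    A(2, 0) = exz; A(2, 1) = eyz; A(2, 2) = ezz;
    arma::eig_sym(ev, V, A);  // ascending
    vals(i, 0) = ev(2);
    vals(i, 1) = ev(1);
    vals(i, 2) = ev(0);
    if (directions) {
      dirs(i, 0) = V(0, 2);
      dirs(i, 1) = V(1, 2);
      dirs(i, 2) = V(2, 2);
    }
  }
  if (directions) {
    return Rcpp::List::create(Rcpp::Named("values") = vals,
                              Rcpp::Named("max_dir") = dirs);
  }
  return Rcpp::List::create(Rcpp::Named("values") = vals);
}
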