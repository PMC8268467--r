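// Hot loop of the classifier: for one group (summarized by its mean vector,
// standard deviations and correlation matrix, with the reference spectral
// decomposition precomputed in R) and one new sample, evaluate the distorted
// correlation matrix and the spectral distortion metric phi at every
// effective sample count in n_red.  Mirrors distorted_correlation() +
// spectral_decompose() + phi_distortion(); equality with the R path is
// asserted in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static int select_components(const vec& values_desc, double alpha) {
  double total = accu(values_desc);
  double cum = 0.0;
  int m = values_desc.n_elem;
  for (int i = 0; i < m; ++i) {
    cum += values_desc(i);
    if (cum / total >= (1.0 - alpha) - 1e-12) return i + 1;
  }
  return m;
}

// [[Rcpp::export(name = ".phi_profile_cpp")]]
Rcpp::NumericVector phi_profile_cpp(const arma::vec& b,
                                    const arma::vec& sd,
                                    const arma::mat& S,
                                    const arma::vec& ref_values,
                                    const arma::mat& ref_vectors,
                                    const int ref_a,
                                    const arma::vec& x_p,
                                    const arma::ivec& n_red,
                                    const double alpha) {
  const int m = S.n_rows;
  const int K = n_red.n_elem;
  Rcpp::NumericVector out(K);

  vec eigval;
  mat eigvec;

  for (int k = 0; k < K; ++k) {
    const double ne = static_cast<double>(n_red(k));
    const vec b_t = (ne / (ne + 1.0)) * b + (1.0 / (ne + 1.0)) * x_p;
    const vec db = b_t - b;
    const vec xc = x_p - b_t;
    const vec sd_t = sqrt(((ne - 1.0) / ne) * square(sd) + square(db) +
                          (1.0 / ne) * square(xc));
    const vec ratio = sd / sd_t;
    const vec db_n = db / sd_t;
    const vec xp_n = xc / sd_t;

    mat S_t = ((ne - 1.0) / ne) * ((ratio * ratio.t()) % S) +
              db_n * db_n.t() + (1.0 / ne) * (xp_n * xp_n.t());
    S_t = 0.5 * (S_t + S_t.t());

    eig_sym(eigval, eigvec, S_t);  // ascending

    // descending order
    const vec lam_t = reverse(eigval);
    const int a_t = select_components(lam_t, alpha);
    const int jmax = std::max(ref_a, a_t);

    double phi = 0.0;
    for (int j = 0; j < jmax; ++j) {
      const double l1 = ref_values(j);
      const double l2 = lam_t(j);
      double d = std::abs(dot(ref_vectors.col(j), eigvec.col(m - 1 - j)));
      if (d > 1.0) d = 1.0;
      phi += std::max(l1, l2) * (l1 - l2) * std::acos(d);
    }
    out[k] = phi;
  }
  return out;
}
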