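#include <Rcpp.h>
#include "model_core.h"

using namespace Rcpp;

// Vectorised kernels behind the user-facing R functions in R/model-core.R.
// Argument recycling and validation happen on the R side.

// [[Rcpp::export]]
NumericVector cpp_mate_value(IntegerVector s_i, IntegerVector s_j,
                             IntegerVector y_j, NumericVector alpha_i,
                             NumericVector a_j, NumericVector w_s,
                             NumericVector w_y, NumericVector w_a,
                             double s_max, double y_max, double a_max) {
  R_xlen_t n = s_i.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k)
    out[k] = eamsim::mate_value(s_i[k], s_j[k], y_j[k], alpha_i[k], a_j[k],
                                w_s[k], w_y[k], w_a[k], s_max, y_max, a_max);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_seek_probability(NumericVector c, NumericVector beta) {
  R_xlen_t n = c.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k)
    out[k] = eamsim::seek_probability(c[k], beta[k]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_date_probability(NumericVector a, NumericVector v,
                                   NumericVector c, NumericVector sigma,
                                   NumericVector beta) {
  R_xlen_t n = a.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k)
    out[k] = eamsim::date_probability(a[k], v[k], c[k], sigma[k], beta[k]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_marry_probability(NumericVector a, NumericVector v,
                                    NumericVector c, NumericVector sigma,
                                    NumericVector beta) {
  R_xlen_t n = a.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k)
    out[k] = eamsim::marry_probability(a[k], v[k], c[k], sigma[k], beta[k]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_death_probability_step(NumericVector a, NumericVector d,
                                         NumericVector w_d, double a_max) {
  R_xlen_t n = a.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k)
    out[k] = eamsim::death_probability_step(a[k], d[k], w_d[k], a_max);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_enrolment_status(NumericVector age, IntegerVector edu) {
  R_xlen_t n = age.size();
  IntegerVector out(n);
  for (R_xlen_t k = 0; k < n; ++k)
    out[k] = eamsim::enrolment_status(age[k], edu[k]);
  return out;
}
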