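#include <Rcpp.h>
#include "tf.h"
using namespace Rcpp;

// Vectorised transfer-function evaluation. qe/qi are the synaptic quanta in
// effect (they default to the reference quanta the function was fitted at;
// regional E/I perturbations pass modified values).
// [[Rcpp::export]]
NumericVector tf_eval_cpp(List tf_list, NumericVector nuE, NumericVector nuI,
                          NumericVector w, double qe, double qi) {
  TransferFun tf = tf_from_list(tf_list);
  R_xlen_t n = nuE.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = tf_rate(tf, nuE[i], nuI[i], w[i], qe, qi);
  return out;
}

// Membrane statistics (mu_V mV, sigma_V mV, tau_V s) for the conductance
// form; used by the fitting routine so that fit and evaluation share one
// implementation.
// [[Rcpp::export]]
NumericMatrix tf_stats_cpp(List tf_list, NumericVector nuE, NumericVector nuI,
                           NumericVector w, double qe, double qi) {
  TransferFun tf = tf_from_list(tf_list);
  R_xlen_t n = nuE.size();
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    double muV, sigV, tauV;
    double e = tf_clamp(nuE[i], tf.dom[0], tf.dom[1]);
    double v = tf_clamp(nuI[i], tf.dom[2], tf.dom[3]);
    double ww = tf_clamp(w[i], tf.dom[4], tf.dom[5]);
    tf_stats(tf, e, v, ww, qe, qi, muV, sigV, tauV);
    out(i, 0) = muV;
    out(i, 1) = sigV;
    out(i, 2) = tauV;
  }
  return out;
}
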