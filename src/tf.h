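#ifndef MFBRAIN_TF_H
#define MFBRAIN_TF_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

// Transfer function of one population type, shared between the R-facing
// evaluator and the network integrator.
//
// form 0: "threshold_poly" -- semi-analytic conductance-based form.
//   Membrane statistics (mu_V, sigma_V, tau_V) are computed from the
//   presynaptic rates and the adaptation current via the conductance
//   equations; the effective spike threshold is a second-order polynomial
//   in the normalised statistics; the output rate is
//   erfc((Vthr_eff - mu_V)/(sqrt(2) sigma_V)) / (2 tau_V).
// form 1: "sigmoid" -- saturating logistic fallback for fast tests.
//   coef = (r_max, theta, slope, a_E, a_I, a_w); drive
//   x = a_E (qe/qe0) nuE - a_I (qi/qi0) nuI - a_w w.
struct TransferFun {
  int form;
  std::vector<double> coef;
  // membrane / synaptic constants (threshold_poly)
  double Cm;     // pF
  double gL;     // nS
  double EL;     // mV
  double Ee;     // mV
  double Ei;     // mV
  double taus;   // synaptic decay, seconds
  double Ke;     // effective number of excitatory synapses
  double Ki;     // effective number of inhibitory synapses
  double qe0;    // reference excitatory quantum, nS
  double qi0;    // reference inhibitory quantum, nS
  // domain box: nuE lo/hi, nuI lo/hi, w lo/hi
  double dom[6];
  // normalisation constants for the polynomial basis
  double mu0, dmu;   // mV
  double sg0, dsg;   // mV
  double tau0;       // s (membrane time at rest, Cm/gL)
};

inline TransferFun tf_from_list(const Rcpp::List &x) {
  TransferFun tf;
  tf.form = Rcpp::as<int>(x["form_code"]);
  tf.coef = Rcpp::as<std::vector<double> >(x["coefficients"]);
  Rcpp::List p = x["membrane"];
  tf.Cm = Rcpp::as<double>(p["Cm"]);
  tf.gL = Rcpp::as<double>(p["gL"]);
  tf.EL = Rcpp::as<double>(p["EL"]);
  tf.Ee = Rcpp::as<double>(p["E_rev_e"]);
  tf.Ei = Rcpp::as<double>(p["E_rev_i"]);
  tf.taus = Rcpp::as<double>(p["tau_syn"]) * 1e-3;  // ms -> s
  tf.Ke = Rcpp::as<double>(p["K_e"]);
  tf.Ki = Rcpp::as<double>(p["K_i"]);
  tf.qe0 = Rcpp::as<double>(p["Qe"]);
  tf.qi0 = Rcpp::as<double>(p["Qi"]);
  Rcpp::NumericVector dom = x["domain"];
  for (int k = 0; k < 6; ++k) tf.dom[k] = dom[k];
  Rcpp::NumericVector nrm = x["norm"];
  tf.mu0 = nrm[0]; tf.dmu = nrm[1];
  tf.sg0 = nrm[2]; tf.dsg = nrm[3];
  tf.tau0 = nrm[4];
  return tf;
}

inline double tf_clamp(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Membrane statistics; rates in Hz, w in pA; outputs mu_V, sigma_V in mV
// and tau_V in seconds.
inline void tf_stats(const TransferFun &tf, double nuE, double nuI, double w,
                     double qe, double qi,
                     double &muV, double &sigV, double &tauV) {
  double muGe = nuE * tf.Ke * tf.taus * qe;
  double muGi = nuI * tf.Ki * tf.taus * qi;
  double muG = tf.gL + muGe + muGi;
  double tauM = tf.Cm / muG * 1e-3;  // pF / nS = ms -> s
  muV = (muGe * tf.Ee + muGi * tf.Ei + tf.gL * tf.EL - w) / muG;
  double Ue = qe / muG * (tf.Ee - muV);
  double Ui = qi / muG * (tf.Ei - muV);
  double se = tf.Ke * nuE * (Ue * tf.taus) * (Ue * tf.taus);
  double si = tf.Ki * nuI * (Ui * tf.taus) * (Ui * tf.taus);
  double sv2 = se / (2.0 * (tf.taus + tauM)) + si / (2.0 * (tf.taus + tauM));
  sigV = std::sqrt(sv2 > 0.0 ? sv2 : 0.0);
  double num = se + si;
  tauV = (sv2 > 0.0) ? num / (2.0 * sv2) : tauM;
}

inline double tf_rate(const TransferFun &tf, double nuE, double nuI, double w,
                      double qe, double qi) {
  nuE = tf_clamp(nuE, tf.dom[0], tf.dom[1]);
  nuI = tf_clamp(nuI, tf.dom[2], tf.dom[3]);
  w = tf_clamp(w, tf.dom[4], tf.dom[5]);
  if (tf.form == 1) {
    const std::vector<double> &c = tf.coef;
    double x = c[3] * (qe / tf.qe0) * nuE - c[4] * (qi / tf.qi0) * nuI -
               c[5] * w;
    double r = c[0] / (1.0 + std::exp(-(x - c[1]) / c[2]));
    return (r > 0.0 && std::isfinite(r)) ? r : 0.0;
  }
  double muV, sigV, tauV;
  tf_stats(tf, nuE, nuI, w, qe, qi, muV, sigV, tauV);
  if (sigV < 1e-6) sigV = 1e-6;  // mV floor: silent input
  double xm = (muV - tf.mu0) / tf.dmu;
  double xs = (sigV - tf.sg0) / tf.dsg;
  double xt = tauV / tf.tau0 - 0.5;
  const std::vector<double> &P = tf.coef;
  double vthre = P[0] + P[1] * xm + P[2] * xs + P[3] * xt + P[4] * xm * xm +
                 P[5] * xs * xs + P[6] * xt * xt + P[7] * xm * xs +
                 P[8] * xm * xt + P[9] * xs * xt;
  double z = (vthre - muV) / (M_SQRT2 * sigV);
  double r = std::erfc(z) / (2.0 * tauV);
  return (r > 0.0 && std::isfinite(r)) ? r : 0.0;
}

#endif
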