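#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "tf.h"
using namespace Rcpp;

namespace {

struct Net {
  int n;
  // per-target edge lists
  std::vector<std::vector<int> > src;
  std::vector<std::vector<double> > wgt;
  std::vector<std::vector<int> > dly;  // delay in steps, >= 1
  TransferFun tfE, tfI;
  std::vector<double> qe, qi, b;
  double tauw_ms, T_ms, RE, RI, gscale, drive_E;
  std::vector<int> stim;  // 0/1 per region
  double stim_amp, stim_onset, stim_width, stim_period;  // ms
  int stim_npulses;  // < 0: unlimited
  bool stim_to_I;
  double rate_floor;
};

inline bool stim_on(const Net &net, double t_ms) {
  if (net.stim_amp <= 0.0 || t_ms < net.stim_onset) return false;
  double ph = t_ms - net.stim_onset;
  double pulse = std::floor(ph / net.stim_period);
  if (net.stim_npulses >= 0 && pulse >= net.stim_npulses) return false;
  return (ph - pulse * net.stim_period) < net.stim_width;
}

// afferent excitatory rate from other regions, evaluated at state step s
// (delays are >= 1 step so only already-written history is read)
inline void afferent(const Net &net, const std::vector<double> &hist, int H,
                     int s, const std::vector<double> &noise, double t_ms,
                     std::vector<double> &affE, std::vector<double> &affI) {
  const bool on = stim_on(net, t_ms);
  for (int i = 0; i < net.n; ++i) {
    double a = 0.0;
    const std::vector<int> &sj = net.src[i];
    const std::vector<double> &wj = net.wgt[i];
    const std::vector<int> &dj = net.dly[i];
    for (size_t e = 0; e < sj.size(); ++e) {
      int slot = (s - dj[e]) % H;
      if (slot < 0) slot += H;
      a += wj[e] * hist[(size_t)sj[e] * H + slot];
    }
    a = net.gscale * a + net.drive_E + noise[i];
    double aE = a, aI = a;
    if (on && net.stim[i]) {
      aE += net.stim_amp;
      if (net.stim_to_I) aI += net.stim_amp;
    }
    affE[i] = aE > 0.0 ? net.RE * aE : 0.0;
    affI[i] = aI > 0.0 ? net.RI * aI : 0.0;
  }
}

inline void drift(const Net &net, const std::vector<double> &rE,
                  const std::vector<double> &rI, const std::vector<double> &w,
                  const std::vector<double> &affE,
                  const std::vector<double> &affI, std::vector<double> &dE,
                  std::vector<double> &dI, std::vector<double> &dW) {
  for (int i = 0; i < net.n; ++i) {
    double FE = tf_rate(net.tfE, rE[i] + affE[i], rI[i], w[i], net.qe[i],
                        net.qi[i]);
    double FI = tf_rate(net.tfI, rE[i] + affI[i], rI[i], 0.0, net.qe[i],
                        net.qi[i]);
    dE[i] = (FE - rE[i]) / net.T_ms;
    dI[i] = (FI - rI[i]) / net.T_ms;
    // b is the per-spike adaptation increment; rE in Hz -> pA/ms
    dW[i] = -w[i] / net.tauw_ms + net.b[i] * rE[i] * 1e-3;
  }
}

}  // namespace

// Delay-coupled mean-field network integrator.
//
// W: target-row / source-column weight matrix; dsteps: transmission delays
// in integration steps (entries < 1 are promoted to 1 so the explicit
// scheme never reads the unwritten current step). Only excitatory rates
// propagate between regions; the common afferent drive
//   a_i(t) = gscale * sum_j W[i,j] rE_j(t - d_ij) + drive_E + noise_i(t)
//            (+ stimulus on target regions)
// reaches the E population as RE * a and the I population as RI * a.
// noise is an Ornstein-Uhlenbeck process (stationary sd noise_amp Hz,
// timescale noise_tau ms); regions with noise_partner[i] < i share the
// partner's realization (mirror-symmetric noise). method: 0 Euler,
// 1 stochastic Heun. Uses the R RNG (set.seed-reproducible).
// [[Rcpp::export]]
List simulate_network_cpp(NumericMatrix W, IntegerMatrix dsteps, List tfE,
                          List tfI, NumericVector qe, NumericVector qi,
                          NumericVector b, double tauw_ms, double T_ms,
                          double RE, double RI, double gscale, double dt_ms,
                          int n_steps, int record_every, NumericVector rE0,
                          NumericVector rI0, NumericVector w0, double drive_E,
                          double noise_amp, double noise_tau_ms,
                          IntegerVector noise_partner, IntegerVector stim_idx,
                          double stim_amp, double stim_onset_ms,
                          double stim_width_ms, double stim_period_ms,
                          int stim_npulses, bool stim_to_I, int method,
                          double rate_floor) {
  const int n = W.nrow();
  Net net;
  net.n = n;
  net.src.resize(n);
  net.wgt.resize(n);
  net.dly.resize(n);
  int maxd = 1;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && W(i, j) != 0.0) {
        int d = dsteps(i, j) < 1 ? 1 : dsteps(i, j);
        net.src[i].push_back(j);
        net.wgt[i].push_back(W(i, j));
        net.dly[i].push_back(d);
        if (d > maxd) maxd = d;
      }
  net.tfE = tf_from_list(tfE);
  net.tfI = tf_from_list(tfI);
  net.qe = as<std::vector<double> >(qe);
  net.qi = as<std::vector<double> >(qi);
  net.b = as<std::vector<double> >(b);
  net.tauw_ms = tauw_ms;
  net.T_ms = T_ms;
  net.RE = RE;
  net.RI = RI;
  net.gscale = gscale;
  net.drive_E = drive_E;
  net.stim.assign(n, 0);
  for (int k = 0; k < stim_idx.size(); ++k) net.stim[stim_idx[k]] = 1;
  net.stim_amp = stim_amp;
  net.stim_onset = stim_onset_ms;
  net.stim_width = stim_width_ms;
  net.stim_period = stim_period_ms;
  net.stim_npulses = stim_npulses;
  net.stim_to_I = stim_to_I;
  net.rate_floor = rate_floor;

  const int H = maxd + 1;
  std::vector<double> hist((size_t)n * H);
  std::vector<double> rE(rE0.begin(), rE0.end());
  std::vector<double> rI(rI0.begin(), rI0.end());
  std::vector<double> w(w0.begin(), w0.end());
  for (int j = 0; j < n; ++j)
    for (int s = 0; s < H; ++s) hist[(size_t)j * H + s] = rE[j];

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix recE(n, n_rec), recI(n, n_rec), recW(n, n_rec);
  NumericVector rec_t(n_rec);
  int ir = 0;
  for (int i = 0; i < n; ++i) {
    recE(i, 0) = rE[i];
    recI(i, 0) = rI[i];
    recW(i, 0) = w[i];
  }
  rec_t[0] = 0.0;
  ir = 1;

  // OU noise: exact discretisation, one shared stream in fixed region order
  const double edec = noise_tau_ms > 0 ? std::exp(-dt_ms / noise_tau_ms) : 0.0;
  const double sfac = noise_amp * std::sqrt(1.0 - edec * edec);
  std::vector<double> x_cur(n, 0.0), x_next(n, 0.0);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    int p = noise_partner[i];
    if (p >= 0 && p < i)
      x_cur[i] = x_cur[p];
    else
      x_cur[i] = noise_amp > 0 ? noise_amp * norm_rand() : 0.0;
  }

  std::vector<double> affE(n), affI(n), dE1(n), dI1(n), dW1(n), dE2(n),
      dI2(n), dW2(n), pE(n), pI(n), pW(n);

  for (int s = 1; s <= n_steps; ++s) {
    const double t_prev = (s - 1) * dt_ms;
    const double t_cur = s * dt_ms;
    // advance OU
    for (int i = 0; i < n; ++i) {
      int p = noise_partner[i];
      if (p >= 0 && p < i)
        x_next[i] = x_next[p];
      else
        x_next[i] = noise_amp > 0 ? x_cur[i] * edec + sfac * norm_rand()
                                  : 0.0;
    }
    afferent(net, hist, H, s - 1, x_cur, t_prev, affE, affI);
    drift(net, rE, rI, w, affE, affI, dE1, dI1, dW1);
    if (method == 1) {
      for (int i = 0; i < n; ++i) {
        pE[i] = rE[i] + dt_ms * dE1[i];
        pI[i] = rI[i] + dt_ms * dI1[i];
        pW[i] = w[i] + dt_ms * dW1[i];
        if (pE[i] < rate_floor) pE[i] = rate_floor;
        if (pI[i] < rate_floor) pI[i] = rate_floor;
      }
      afferent(net, hist, H, s, x_next, t_cur, affE, affI);
      drift(net, pE, pI, pW, affE, affI, dE2, dI2, dW2);
      for (int i = 0; i < n; ++i) {
        rE[i] += 0.5 * dt_ms * (dE1[i] + dE2[i]);
        rI[i] += 0.5 * dt_ms * (dI1[i] + dI2[i]);
        w[i] += 0.5 * dt_ms * (dW1[i] + dW2[i]);
      }
    } else {
      for (int i = 0; i < n; ++i) {
        rE[i] += dt_ms * dE1[i];
        rI[i] += dt_ms * dI1[i];
        w[i] += dt_ms * dW1[i];
      }
    }
    for (int i = 0; i < n; ++i) {
      if (rE[i] < rate_floor) rE[i] = rate_floor;
      if (rI[i] < rate_floor) rI[i] = rate_floor;
      if (!std::isfinite(rE[i]) || !std::isfinite(rI[i]) ||
          !std::isfinite(w[i]))
        stop("network integration diverged at t = %g s (region %d)",
             t_cur * 1e-3, i + 1);
      hist[(size_t)i * H + (s % H)] = rE[i];
    }
    std::swap(x_cur, x_next);
    if (s % record_every == 0 && ir < n_rec) {
      for (int i = 0; i < n; ++i) {
        recE(i, ir) = rE[i];
        recI(i, ir) = rI[i];
        recW(i, ir) = w[i];
      }
      rec_t[ir] = t_cur * 1e-3;
      ++ir;
    }
  }
  return List::create(_["time"] = rec_t, _["rE"] = recE, _["rI"] = recI,
                      _["w"] = recW);
}
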