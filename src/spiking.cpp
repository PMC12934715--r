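#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// AdEx spiking network, Euler-Maruyama integration.
//
// Neurons 0..NE-1 are excitatory, NE..NE+NI-1 inhibitory. Each neuron
// carries membrane voltage V (mV), synaptic conductances GE, GI (nS) with
// exponential decay (tau_syn ms), and an adaptation current w (pA).
// Connectivity is a directed edge list (pre, post); a presynaptic spike
// increments the matching conductance of every target by Qe or Qi
// depending on the presynaptic cell type. External drive is delivered as
// independent Poisson trains of E-type and I-type events at total rates
// rateE/rateI (Hz) per neuron. Spikes are detected at V >= Vcut, voltage
// reset to EL, and w incremented by b.
//
// parE/parI: c(Cm pF, gL nS, EL mV, Delta mV, Vthr mV, sigma pA, b pA, tauw ms)
//
// Uses the R RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List simulate_spiking_cpp(int NE, int NI, IntegerVector pre, IntegerVector post,
                          NumericVector parE, NumericVector parI, double Qe,
                          double Qi, double Ee, double Ei, double taus_ms,
                          double rateE, double rateI, double Iext,
                          double duration_s, double dt_ms, double vcut_mult,
                          bool w_fixed, double w0, int record_neuron) {
  const int N = NE + NI;
  const double dt_s = dt_ms * 1e-3;
  const int n_steps = (int)std::llround(duration_s * 1000.0 / dt_ms);

  // CSR adjacency over presynaptic neurons
  std::vector<int> deg(N, 0), off(N + 1, 0);
  const int n_edges = pre.size();
  for (int e = 0; e < n_edges; ++e) deg[pre[e]]++;
  for (int i = 0; i < N; ++i) off[i + 1] = off[i] + deg[i];
  std::vector<int> tgt(n_edges);
  {
    std::vector<int> cur(off.begin(), off.end() - 1);
    for (int e = 0; e < n_edges; ++e) tgt[cur[pre[e]]++] = post[e];
  }

  std::vector<double> V(N), GE(N, 0.0), GI(N, 0.0), w(N, w0);
  std::vector<double> Cm(N), gL(N), EL(N), Del(N), Vthr(N), sig(N), bb(N),
      tauw(N), Vcut(N);
  for (int i = 0; i < N; ++i) {
    const NumericVector &p = (i < NE) ? parE : parI;
    Cm[i] = p[0]; gL[i] = p[1]; EL[i] = p[2]; Del[i] = p[3];
    Vthr[i] = p[4]; sig[i] = p[5]; bb[i] = p[6]; tauw[i] = p[7];
    Vcut[i] = p[4] + vcut_mult * p[3];  // Vthr + mult * Delta
    V[i] = p[2];  // start at leak reversal
  }
  const double dec = std::exp(-dt_ms / taus_ms);
  const double sqdt = std::sqrt(dt_ms);
  const double lamE = rateE * dt_s, lamI = rateI * dt_s;

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(1024);
  sp_t.reserve(1024);
  const bool rec = record_neuron >= 0 && record_neuron < N;
  NumericMatrix trace(rec ? n_steps : 0, rec ? 4 : 0);

  RNGScope scope;
  for (int k = 0; k < n_steps; ++k) {
    const double t_s = (k + 1) * dt_s;
    for (int i = 0; i < N; ++i) {
      GE[i] *= dec;
      GI[i] *= dec;
      if (lamE > 0) GE[i] += Qe * R::rpois(lamE);
      if (lamI > 0) GI[i] += Qi * R::rpois(lamI);
      double expterm = 0.0;
      if (Del[i] > 0) {
        double a = (V[i] - Vthr[i]) / Del[i];
        if (a > 30.0) a = 30.0;
        expterm = gL[i] * Del[i] * std::exp(a);
      }
      double dV = (gL[i] * (EL[i] - V[i]) + expterm + GE[i] * (Ee - V[i]) +
                   GI[i] * (Ei - V[i]) - w[i] + Iext) /
                  Cm[i] * dt_ms;
      if (sig[i] > 0) dV += sig[i] * sqdt * norm_rand() / Cm[i];
      V[i] += dV;
      if (!w_fixed) w[i] -= dt_ms * w[i] / tauw[i];
      if (!std::isfinite(V[i]) || std::fabs(V[i]) > 1e4)
        stop("spiking integration diverged at t = %g s (neuron %d); "
             "reduce dt", t_s, i + 1);
    }
    for (int i = 0; i < N; ++i) {
      if (V[i] >= Vcut[i]) {
        sp_id.push_back(i + 1);
        sp_t.push_back(t_s);
        V[i] = EL[i];
        if (!w_fixed) w[i] += bb[i];
        const double q = (i < NE) ? Qe : Qi;
        for (int e = off[i]; e < off[i + 1]; ++e) {
          if (i < NE)
            GE[tgt[e]] += q;
          else
            GI[tgt[e]] += q;
        }
      }
    }
    if (rec) {
      trace(k, 0) = V[record_neuron];
      trace(k, 1) = GE[record_neuron];
      trace(k, 2) = GI[record_neuron];
      trace(k, 3) = w[record_neuron];
    }
  }
  List out = List::create(_["neuron"] = wrap(sp_id), _["time"] = wrap(sp_t));
  if (rec) out["trace"] = trace;
  return out;
}
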