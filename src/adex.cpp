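// Adaptive exponential integrate-and-fire neuron, forward Euler, used to
// obtain empirical f-I curves. Units: mV, ms, pA, pF, nS.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_adex_fi")]]
NumericVector cpp_adex_fi(NumericVector I_pA, double duration_s, double dt_ms,
                          double noise_frac,
                          double C, double gL, double EL, double VT,
                          double DeltaT, double tau_w, double a, double b,
                          double Vr, double Vpeak) {
  RNGScope scope;
  int nI = I_pA.size();
  NumericVector rate(nI);
  long n_steps = (long)std::ceil(duration_s * 1000.0 / dt_ms);
  for (int i = 0; i < nI; ++i) {
    double I0 = I_pA[i];
    double V = EL, w = 0.0;
    long spikes = 0;
    for (long s = 0; s < n_steps; ++s) {
      double I = I0;
      if (noise_frac > 0.0) I += noise_frac * I0 * norm_rand();
      double ex = gL * DeltaT * std::exp((V - VT) / DeltaT);
      if (ex > 1e6) ex = 1e6;  // cap the exponential blow-up between V and Vpeak
      double dV = (-gL * (V - EL) + ex - w + I) / C;
      double dw = (a * (V - EL) - w) / tau_w;
      V += dt_ms * dV;
      w += dt_ms * dw;
      if (!std::isfinite(V) || !std::isfinite(w))
        stop("AdEx integration diverged (reduce dt)");
      if (V >= Vpeak) { V = Vr; w += b; ++spikes; }
    }
    rate[i] = spikes / duration_s;   // Hz
  }
  return rate;
}
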