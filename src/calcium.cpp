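// Calcium-threshold plasticity rule: the calcium trace decays exponentially
// and jumps at pre-/postsynaptic spikes; the weight relaxes towards
// gp/(gp+gd) while the calcium is above the potentiation threshold, decays
// while only above the depression threshold, and is frozen otherwise.
// Between spikes everything is piecewise exponential, so the integration is
// event-driven and exact up to floating point. A brute-force Euler
// integrator is provided as an independent cross-check.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct CaPar {
  double tau_w, gp, gd, thp, thd, tau_c;
};

// advance (c, w) over an interval of length dt with no spikes; theta_p >= theta_d
static void ca_advance(double& c, double& w, double dt, const CaPar& P) {
  if (dt <= 0.0) { return; }
  double t_p = 0.0, t_d = 0.0;
  if (c > P.thp) t_p = std::min(dt, P.tau_c * std::log(c / P.thp));
  if (c > P.thd) t_d = std::min(dt, P.tau_c * std::log(c / P.thd));
  if (t_p > 0.0) {            // both processes active
    double winf = P.gp / (P.gp + P.gd);
    double rate = (P.gp + P.gd) / P.tau_w;
    w = winf + (w - winf) * std::exp(-rate * t_p);
  }
  if (t_d > t_p) {            // depression only
    w *= std::exp(-P.gd * (t_d - t_p) / P.tau_w);
  }
  if (w < 0.0) w = 0.0;
  if (w > 1.0) w = 1.0;
  c *= std::exp(-dt / P.tau_c);
}

// [[Rcpp::export(name = ".cpp_ca_events")]]
List cpp_ca_events(NumericVector times, NumericVector amps, double T,
                   double w0, double c0,
                   double tau_w, double gp, double gd,
                   double thp, double thd, double tau_c) {
  CaPar P{tau_w, gp, gd, thp, thd, tau_c};
  if (thp < thd) stop("theta_p must be >= theta_d");
  double c = c0, w = w0, t = 0.0;
  int n = times.size();
  for (int i = 0; i < n; ++i) {
    double ti = times[i];
    if (ti < t - 1e-12) stop("spike times must be sorted");
    if (ti > T) break;
    ca_advance(c, w, ti - t, P);
    c += amps[i];
    t = ti;
  }
  ca_advance(c, w, T - t, P);
  return List::create(_["w"] = w, _["c"] = c);
}

// Independent forward-Euler reference with fixed step dt (spikes applied at
// the start of the step whose window contains them).
// [[Rcpp::export(name = ".cpp_ca_euler")]]
List cpp_ca_euler(NumericVector times, NumericVector amps, double T,
                  double w0, double c0, double dt,
                  double tau_w, double gp, double gd,
                  double thp, double thd, double tau_c) {
  double c = c0, w = w0;
  long n_steps = (long)std::ceil(T / dt);
  int i = 0, n = times.size();
  for (long s = 0; s < n_steps; ++s) {
    double t = s * dt;
    while (i < n && times[i] <= t) { c += amps[i]; ++i; }
    double dw = 0.0;
    if (c > thp) dw += gp * (1.0 - w);
    if (c > thd) dw -= gd * w;
    w += dt * dw / tau_w;
    if (w < 0.0) w = 0.0;
    if (w > 1.0) w = 1.0;
    c -= dt * c / tau_c;
  }
  while (i < n && times[i] <= T) { c += amps[i]; ++i; }
  return List::create(_["w"] = w, _["c"] = c);
}

// Advance an ensemble of independent connections by one block of duration
// T_block under independent pre/post Poisson drive; states updated in place.
// [[Rcpp::export(name = ".cpp_ca_ensemble_block")]]
List cpp_ca_ensemble_block(NumericVector c_state, NumericVector w_state,
                           double rate_pre, double rate_post, double T_block,
                           double C_pre, double C_post,
                           double tau_w, double gp, double gd,
                           double thp, double thd, double tau_c) {
  RNGScope scope;
  CaPar P{tau_w, gp, gd, thp, thd, tau_c};
  int n = c_state.size();
  NumericVector c_out = clone(c_state), w_out = clone(w_state);
  for (int j = 0; j < n; ++j) {
    double c = c_out[j], w = w_out[j], t = 0.0;
    double t_pre = R::rexp(1.0 / rate_pre);
    double t_post = R::rexp(1.0 / rate_post);
    while (true) {
      double t_next = std::min(t_pre, t_post);
      if (t_next > T_block) break;
      ca_advance(c, w, t_next - t, P);
      t = t_next;
      if (t_pre <= t_post) {
        c += C_pre;  t_pre += R::rexp(1.0 / rate_pre);
      } else {
        c += C_post; t_post += R::rexp(1.0 / rate_post);
      }
    }
    ca_advance(c, w, T_block - t, P);
    c_out[j] = c; w_out[j] = w;
  }
  return List::create(_["c"] = c_out, _["w"] = w_out);
}
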