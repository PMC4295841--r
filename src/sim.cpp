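// Time-stepped stochastic simulation of one multi-synaptic connection.
// The weight rule integrated here is the fixed-threshold BCM rule with
// weight-dependent synaptic scaling (the reference rule of the rate model);
// generic rules are handled by the slower R-level stepper.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// dw/dt = mu * (vj*vi*(vi - theta) - (vi - v_tss) * w^2 / kappa), vi held
// fixed across the RK4 block (rates are recomputed once per structural step)
static inline double bcm_rhs(double w, double A, double B, double mu) {
  return mu * (A - B * w * w);
}

// integrate all weights over `substeps` unit-time RK4 steps; A,B precomputed.
// Once every weight is at its fixed point the remaining substeps are no-ops,
// so the block exits early (keeps speedup = substeps runs affordable).
static void rk4_weights(std::vector<double>& w, double A, double B, double mu,
                        int substeps) {
  const double dt = 1.0;
  for (int s = 0; s < substeps; ++s) {
    double max_dw = 0.0;
    for (size_t k = 0; k < w.size(); ++k) {
      double w0 = w[k];
      double k1 = bcm_rhs(w0, A, B, mu);
      double k2 = bcm_rhs(w0 + 0.5 * dt * k1, A, B, mu);
      double k3 = bcm_rhs(w0 + 0.5 * dt * k2, A, B, mu);
      double k4 = bcm_rhs(w0 + dt * k3, A, B, mu);
      double wn = w0 + dt / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
      if (wn < 0.0) wn = 0.0;           // weights are nonnegative
      if (wn > 100.0) wn = 100.0;       // runaway guard (never hit in practice)
      double d = std::fabs(wn - w0);
      if (d > max_dw) max_dw = d;
      w[k] = wn;
    }
    if (max_dw < 1e-12) break;
  }
}

// [[Rcpp::export(name = ".cpp_sim_bcm")]]
List cpp_sim_bcm(int n_steps, int burn_in, int P,
                 double p_build, double log_pdel0, double a2, double q,
                 double mu, double theta, double kappa, double v_tss,
                 double v_j, double I, bool feedback,
                 double w_init, int substeps, double speedup,
                 int record_stride, int S0, NumericVector w0) {
  RNGScope scope;
  std::vector<double> w(w0.begin(), w0.end());
  if ((int)w.size() != S0) stop("w0 must have length S0");
  NumericVector occ(P + 1);
  double pb_eff = std::min(1.0, p_build * speedup);
  int n_rec = (record_stride > 0) ? n_steps / record_stride : 0;
  NumericMatrix trace(n_rec, 3); // S, mean_w, v_i
  int rec = 0;
  double v_i = 0.0;
  for (int t = 0; t < n_steps; ++t) {
    int S_pre = (int)w.size();
    // (1) rates
    double wsum = 0.0;
    for (double wk : w) wsum += wk;
    double vj_eff = v_j;
    if (feedback) {
      // self-consistent instantaneous rate for v_j = v_i: fixed-point iterate
      double v = logistic(wsum * 0.5 + I);
      for (int it = 0; it < 50; ++it) {
        double vn = logistic(wsum * v + I);
        if (std::fabs(vn - v) < 1e-12) { v = vn; break; }
        v = vn;
      }
      v_i = v; vj_eff = v_i;
    } else {
      v_i = logistic(wsum * v_j + I);
    }
    // (2) weights
    double A = vj_eff * v_i * (v_i - theta);
    double B = (v_i - v_tss) / kappa;
    rk4_weights(w, A, B, mu, substeps);
    // (3) deletion, evaluated on the updated weights
    for (int k = (int)w.size() - 1; k >= 0; --k) {
      double pdel = std::exp(log_pdel0 - a2 * std::pow(w[k], q)) * speedup;
      if (pdel > 1.0) pdel = 1.0;
      if (unif_rand() < pdel) w.erase(w.begin() + k);
    }
    // (4) creation at the sites that were vacant at the start of the step
    int nb = (int)R::rbinom(P - S_pre, pb_eff);
    for (int b = 0; b < nb; ++b) w.push_back(w_init);
    int S = (int)w.size();
    if (t >= burn_in) occ[S] += 1.0;
    if (record_stride > 0 && (t + 1) % record_stride == 0 && rec < n_rec) {
      double mw = 0.0;
      for (double wk : w) mw += wk;
      trace(rec, 0) = S;
      trace(rec, 1) = S > 0 ? mw / S : NA_REAL;
      trace(rec, 2) = v_i;
      ++rec;
    }
  }
  NumericVector w_final(w.begin(), w.end());
  return List::create(_["occupancy"] = occ, _["trace"] = trace,
                      _["w_final"] = w_final);
}

// Occupancy of the chain with weights pinned at per-state fixed points:
// pure birth-death-with-batches process, used to validate the analytic
// stationary distribution against long simulations.
// [[Rcpp::export(name = ".cpp_sim_pinned")]]
NumericVector cpp_sim_pinned(int n_steps, int burn_in, int P, double p_build,
                             NumericVector pdel_by_S, int S0) {
  RNGScope scope;
  if (pdel_by_S.size() != P + 1) stop("pdel_by_S must have length P + 1");
  NumericVector occ(P + 1);
  int S = S0;
  for (int t = 0; t < n_steps; ++t) {
    int removed = (S > 0) ? (int)R::rbinom(S, pdel_by_S[S]) : 0;
    int built = (int)R::rbinom(P - S, p_build);
    S = S - removed + built;
    if (t >= burn_in) occ[S] += 1.0;
  }
  return occ;
}

// Hysteresis protocol: sweep one stimulation level up and down repeatedly,
// dwell a fixed number of structural steps per level, record the
// time-averaged synapse count per level and branch, averaged over cycles.
// vary_post: levels are v_i(S=0) (converted to I); otherwise levels are v_j.
// [[Rcpp::export(name = ".cpp_hysteresis_bcm")]]
List cpp_hysteresis_bcm(NumericVector levels, int dwell, int cycles, int P,
                        double p_build, double log_pdel0, double a2, double q,
                        double mu, double theta, double kappa, double v_tss,
                        bool vary_post, double v_j0, double I0,
                        double w_init, int substeps, double speedup) {
  RNGScope scope;
  int L = levels.size();
  NumericVector up_sum(L), down_sum(L);
  std::vector<double> w;
  double pb_eff = std::min(1.0, p_build * speedup);
  for (int cyc = 0; cyc < cycles; ++cyc) {
    for (int dir = 0; dir < 2; ++dir) {
      for (int li = 0; li < L; ++li) {
        int lev = (dir == 0) ? li : (L - 1 - li);
        double level = levels[lev];
        double v_j = vary_post ? v_j0 : level;
        double I = vary_post ? std::log(level / (1.0 - level)) : I0;
        double acc = 0.0;
        for (int t = 0; t < dwell; ++t) {
          int S_pre = (int)w.size();
          double wsum = 0.0;
          for (double wk : w) wsum += wk;
          double v_i = logistic(wsum * v_j + I);
          double A = v_j * v_i * (v_i - theta);
          double B = (v_i - v_tss) / kappa;
          rk4_weights(w, A, B, mu, substeps);
          for (int k = (int)w.size() - 1; k >= 0; --k) {
            double pdel = std::exp(log_pdel0 - a2 * std::pow(w[k], q)) * speedup;
            if (pdel > 1.0) pdel = 1.0;
            if (unif_rand() < pdel) w.erase(w.begin() + k);
          }
          int nb = (int)R::rbinom(P - S_pre, pb_eff);
          for (int b = 0; b < nb; ++b) w.push_back(w_init);
          acc += (double)w.size();
        }
        if (dir == 0) up_sum[lev] += acc / dwell;
        else down_sum[lev] += acc / dwell;
      }
    }
  }
  return List::create(_["level"] = levels,
                      _["mean_up"] = up_sum / (double)cycles,
                      _["mean_down"] = down_sum / (double)cycles);
}
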