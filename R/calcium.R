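#' Calcium-rule parameters
#'
#' Parameters of the calcium-threshold spiking plasticity rule: a calcium
#' trace `c(t)` decays with time constant `tau_c` and jumps by `C_pre` /
#' `C_post` at pre-/postsynaptic spikes; the weight obeys
#' \deqn{\tau_w \dot w = \gamma_p (1-w)\,\Theta[c-\theta_p] - \gamma_d w\,\Theta[c-\theta_d].}
#' The bistable potential term of the original rule is neglected, which makes
#' the dynamics piecewise linear and allows exact event-driven integration.
#' Defaults are the cortical-slice parameter set.
#'
#' @param tau_w weight time constant (s).
#' @param gamma_p,gamma_d potentiation / depression rates (dimensionless).
#' @param theta_p,theta_d calcium thresholds, `theta_p >= theta_d`.
#' @param tau_c calcium decay time (s; cortical value 22.7 ms).
#' @param C_pre,C_post calcium jump per pre-/postsynaptic spike.
#' @export
ca_rule_params <- function(tau_w = 346.361, gamma_p = 725.085,
                           gamma_d = 331.909, theta_p = 1.3, theta_d = 1.0,
                           tau_c = 0.0227, C_pre = 0.5617, C_post = 1.2396) {
  stopifnot(tau_w > 0, gamma_p > 0, gamma_d > 0, theta_p > 0, theta_d > 0,
            tau_c > 0, C_pre > 0, C_post > 0, theta_p >= theta_d)
  structure(list(tau_w = tau_w, gamma_p = gamma_p, gamma_d = gamma_d,
                 theta_p = theta_p, theta_d = theta_d, tau_c = tau_c,
                 C_pre = C_pre, C_post = C_post),
            class = "ca_rule_params")
}

#' Spike trains
#'
#' @param times nonnegative, strictly increasing spike times (s).
#' @param source `"pre"` or `"post"`.
#' @export
spike_train <- function(times, source = c("pre", "post")) {
  source <- match.arg(source)
  times <- as.numeric(times)
  if (length(times) && (any(times < 0) || any(diff(times) <= 0)))
    stop("spike times must be nonnegative and strictly increasing")
  structure(list(times = times, source = source), class = "spike_train")
}

#' Poisson spike train
#' @param rate rate in Hz (> 0).
#' @param T duration (s).
#' @param source `"pre"` or `"post"`.
#' @export
poisson_train <- function(rate, T, source = c("pre", "post")) {
  stopifnot(rate > 0, T > 0)
  t <- cumsum(stats::rexp(ceiling(rate * T + 5 * sqrt(rate * T)) + 10, rate))
  spike_train(t[t <= T], match.arg(source))
}

merge_events <- function(pre, post, params) {
  times <- c(pre$times, post$times)
  amps <- c(rep(params$C_pre, length(pre$times)),
            rep(params$C_post, length(post$times)))
  o <- order(times)
  list(times = times[o], amps = amps[o])
}

#' Event-driven integration of the calcium rule
#'
#' Integrates the rule exactly: between spikes the calcium decays as
#' `c0 * exp(-t/tau_c)`, the downward threshold crossings are at
#' `tau_c * log(c0/theta)`, and within each constant-indicator interval the
#' weight relaxes exponentially. No time-stepping error is introduced.
#'
#' @param params [ca_rule_params()].
#' @param pre,post [spike_train()] objects within `[0, T]`.
#' @param w0 initial weight in `[0, 1]`.
#' @param T duration (s).
#' @param c0 initial calcium (default 0).
#' @return list with final `w` and `c`.
#' @export
ca_integrate <- function(params, pre, post, w0, T, c0 = 0) {
  stopifnot(inherits(params, "ca_rule_params"), w0 >= 0, w0 <= 1, T >= 0)
  ev <- merge_events(pre, post, params)
  if (length(ev$times) && max(ev$times) > T)
    stop("spike trains must lie within [0, T]")
  .cpp_ca_events(ev$times, ev$amps, T, w0, c0,
                 params$tau_w, params$gamma_p, params$gamma_d,
                 params$theta_p, params$theta_d, params$tau_c)
}

#' Brute-force Euler reference for the calcium rule
#'
#' Fixed-step forward Euler used as an independent cross-check of
#' [ca_integrate()]; agreement within 1e-3 absolute weight at `dt = 1e-6` s
#' is part of the acceptance suite.
#'
#' @inheritParams ca_integrate
#' @param dt Euler step (s).
#' @export
ca_integrate_euler <- function(params, pre, post, w0, T, dt = 1e-6, c0 = 0) {
  ev <- merge_events(pre, post, params)
  .cpp_ca_euler(ev$times, ev$amps, T, w0, c0, dt,
                params$tau_w, params$gamma_p, params$gamma_d,
                params$theta_p, params$theta_d, params$tau_c)
}

#' Ensemble fixed weight under Poisson drive
#'
#' Simulates `n_ensemble` independent connections driven by independent pre-
#' and postsynaptic Poisson trains and evaluates the ensemble mean weight at
#' block boundaries; each block covers at least `block_spikes` expected spikes
#' from each site. The run stops when the block-to-block change of the
#' ensemble mean stays below `tol` for three consecutive blocks ("fluctuating
#' around a stationary value"), and returns the mean and standard deviation
#' at the stop.
#'
#' @param params [ca_rule_params()].
#' @param rate_pre,rate_post Poisson rates (Hz, > 0).
#' @param n_ensemble ensemble size (reference value 500).
#' @param block_spikes minimum expected spikes per site per block.
#' @param tol target accuracy on the ensemble mean (reference value 0.005).
#' @param w0 initial weight.
#' @param max_blocks give up after this many blocks.
#' @param seed optional RNG seed.
#' @return list with `mean`, `sd`, `n_blocks`, `converged`.
#' @export
ca_fixed_weight <- function(params, rate_pre, rate_post, n_ensemble = 500,
                            block_spikes = 200, tol = 0.005, w0 = 0.5,
                            max_blocks = 200, seed = NULL) {
  stopifnot(rate_pre > 0, rate_post > 0, n_ensemble >= 2)
  if (!is.null(seed)) set.seed(seed)
  T_block <- block_spikes / min(rate_pre, rate_post)
  c_st <- rep(0, n_ensemble)
  w_st <- rep(w0, n_ensemble)
  prev_mean <- mean(w_st)
  stable_blocks <- 0L
  for (b in seq_len(max_blocks)) {
    res <- .cpp_ca_ensemble_block(c_st, w_st, rate_pre, rate_post, T_block,
                                  params$C_pre, params$C_post,
                                  params$tau_w, params$gamma_p,
                                  params$gamma_d, params$theta_p,
                                  params$theta_d, params$tau_c)
    c_st <- res$c; w_st <- res$w
    m <- mean(w_st)
    stable_blocks <- if (abs(m - prev_mean) < tol) stable_blocks + 1L else 0L
    prev_mean <- m
    if (stable_blocks >= 3L)
      return(list(mean = m, sd = stats::sd(w_st), n_blocks = b,
                  converged = TRUE))
  }
  warning("ca_fixed_weight: no convergence after ", max_blocks, " blocks")
  list(mean = prev_mean, sd = stats::sd(w_st), n_blocks = max_blocks,
       converged = FALSE)
}

#' Sampled curves with linear interpolation
#'
#' @param x strictly increasing abscissa.
#' @param y ordinate.
#' @param units optional metadata.
#' @return object of class `empirical_curve`; calling it evaluates the
#'   piecewise-linear interpolant, with an error outside the sampled domain.
#' @export
empirical_curve <- function(x, y, units = c(x = "", y = "")) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (any(diff(x) <= 0)) stop("empirical_curve: abscissa must be strictly increasing")
  f <- stats::approxfun(x, y)
  g <- function(xq) {
    if (any(xq < x[1] - 1e-12) || any(xq > x[length(x)] + 1e-12))
      stop("empirical_curve: query outside the sampled domain (no extrapolation)")
    f(xq)
  }
  structure(g, x = x, y = y, units = units, class = "empirical_curve")
}

#' @export
print.empirical_curve <- function(x, ...) {
  cat(sprintf("<empirical_curve> %d nodes on [%g, %g]\n",
              length(attr(x, "x")), min(attr(x, "x")), max(attr(x, "x"))))
  invisible(x)
}

#' Adaptive exponential integrate-and-fire parameters and f-I curve
#'
#' `adex_params()` collects the neuron constants (defaults: the regular/tonic
#' spiking set of the standard two-variable adaptive exponential model;
#' C = 281 pF, gL = 30 nS, EL = -70.6 mV, VT = -50.4 mV, DeltaT = 2 mV,
#' tau_w = 144 ms, a = 4 nS, b = 80.5 pA, Vr = -70.6 mV). `adex_fi_curve()`
#' integrates the neuron with forward Euler under a noisy current
#' (`sigma = noise_frac * I`, white per Euler step) and returns the mean
#' firing rate per current level as an [empirical_curve()].
#'
#' @param C membrane capacitance (pF).
#' @param gL leak conductance (nS).
#' @param EL,VT,DeltaT,Vr,Vpeak voltages (mV).
#' @param tau_w adaptation time constant (ms).
#' @param a adaptation conductance (nS).
#' @param b spike-triggered adaptation increment (pA).
#' @export
adex_params <- function(C = 281, gL = 30, EL = -70.6, VT = -50.4, DeltaT = 2,
                        tau_w = 144, a = 4, b = 80.5, Vr = -70.6, Vpeak = 0) {
  structure(list(C = C, gL = gL, EL = EL, VT = VT, DeltaT = DeltaT,
                 tau_w = tau_w, a = a, b = b, Vr = Vr, Vpeak = Vpeak),
            class = "adex_params")
}

#' @rdname adex_params
#' @param pars [adex_params()].
#' @param I_min,I_max,I_step current range (pA; reference sweep 600-1450 pA in
#'   0.5 pA steps).
#' @param duration simulated time per current level (s).
#' @param dt Euler step (s, <= 5e-5 for stability).
#' @param noise_frac relative current noise (reference value 0.05).
#' @param seed optional RNG seed.
#' @export
adex_fi_curve <- function(pars = adex_params(), I_min, I_max, I_step = 0.5,
                          duration = 2500, dt = 5e-5, noise_frac = 0.05,
                          seed = NULL) {
  stopifnot(I_min < I_max, dt <= 5e-5, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  I <- seq(I_min, I_max, by = I_step)
  rate <- .cpp_adex_fi(I, duration, dt * 1000, noise_frac,
                       pars$C, pars$gL, pars$EL, pars$VT, pars$DeltaT,
                       pars$tau_w, pars$a, pars$b, pars$Vr, pars$Vpeak)
  # enforce monotonicity against residual sampling noise (cumulative max)
  rate_mono <- cummax(rate)
  empirical_curve(I, rate_mono, units = c(x = "pA", y = "Hz"))
}

#' Fixed-weight surface of the calcium rule over a rate grid
#'
#' Runs [ca_fixed_weight()] on a grid of pre/post rates and returns, per
#' presynaptic rate, an [empirical_curve()] of the fixed weight against the
#' postsynaptic rate, scaled by `w_scale` (nA/Hz) into current units.
#'
#' @param params [ca_rule_params()].
#' @param rates_pre,rates_post rate grids (Hz).
#' @param w_scale multiplicative conversion of the dimensionless weight into
#'   nA/Hz of postsynaptic drive (reference value 0.035).
#' @param ... passed to [ca_fixed_weight()] (`n_ensemble`, `tol`, `seed`, ...).
#' @return named list of `empirical_curve`s (one per presynaptic rate), with
#'   the raw grid as attribute `grid`.
#' @export
ca_vw_surface <- function(params, rates_pre, rates_post, w_scale = 0.035,
                          ...) {
  grid <- expand.grid(pre = rates_pre, post = rates_post)
  grid$w <- NA_real_
  grid$sd <- NA_real_
  for (i in seq_len(nrow(grid))) {
    fw <- ca_fixed_weight(params, grid$pre[i], grid$post[i], ...)
    grid$w[i] <- fw$mean * w_scale
    grid$sd[i] <- fw$sd * w_scale
  }
  curves <- lapply(rates_pre, function(rp) {
    g <- grid[grid$pre == rp, ]
    empirical_curve(g$post, g$w, units = c(x = "Hz", y = "nA"))
  })
  names(curves) <- paste0("pre_", rates_pre, "Hz")
  attr(curves, "grid") <- grid
  curves
}
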