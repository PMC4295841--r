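#' Simulation configuration
#'
#' Controls of the time-stepped stochastic simulation. One structural step
#' executes: (1) update the firing rate from the IO curve, (2) integrate all
#' weights with classical 4th-order Runge-Kutta (`substeps` unit-time steps,
#' rate held fixed), (3) draw deletions against the updated weights, (4) build
#' synapses at the sites that were vacant at the start of the step.
#'
#' `speedup` multiplies both structural probabilities (`p_build` and `p_del`)
#' by a common factor. Because the equilibrium distribution depends only on
#' their ratio, this compresses the structural time axis without changing the
#' stationary state or the fixed-point structure; pair it with a matching
#' `substeps` so the weight dynamics keep their head start over deletion
#' (a new synapse must outgrow the high deletion probability of weak
#' synapses). Used to bring multi-million-step protocols to desk scale.
#'
#' @param n_steps number of structural steps.
#' @param w_init weight of a newly built synapse. Default
#'   `0.05 * kappa * (1 - v_tss)^(-1/2)` (evaluated against the rule when
#'   `NULL`); the literal reading of the reference simulations. The
#'   alternative reading `0.05 * sqrt(kappa / (1 - v_tss))` can be supplied
#'   explicitly.
#' @param substeps RK4 unit-time steps per structural step (>= 1).
#' @param burn_in_frac fraction of steps discarded before collecting the
#'   occupancy histogram.
#' @param speedup common multiplier on the structural probabilities (>= 1).
#' @param record_stride if > 0, record (S, mean weight, rate) every this many
#'   steps.
#' @export
sim_config <- function(n_steps, w_init = NULL, substeps = 1L,
                       burn_in_frac = 0.1, speedup = 1, record_stride = 0L) {
  stopifnot(n_steps >= 1, substeps >= 1, speedup >= 1,
            burn_in_frac >= 0, burn_in_frac < 1)
  if (!is.null(w_init)) stopifnot(w_init > 0)
  structure(list(n_steps = as.integer(n_steps), w_init = w_init,
                 substeps = as.integer(substeps),
                 burn_in_frac = burn_in_frac, speedup = speedup,
                 record_stride = as.integer(record_stride)),
            class = "sim_config")
}

default_w_init <- function(rule) 0.05 * rule$kappa / sqrt(1 - rule$v_tss)

#' One structural step of the stochastic connection (reference stepper)
#'
#' Pure-R implementation of the step order (rates, RK4 weights, deletion,
#' creation) for arbitrary [rule_spec()] kinds. Deletion draws are consumed
#' first (descending synapse index), then one binomial creation draw, so runs
#' are reproducible under a fixed seed. Creation acts on the sites that were
#' vacant at the start of the step, matching the one-step transition matrix.
#'
#' @param state list with `weights` (numeric vector; `S` is its length).
#' @param sp [structural_params()].
#' @param rule,io,point,fb model components.
#' @param config [sim_config()] (only `w_init`, `substeps`, `speedup` used).
#' @return updated state list with `weights`, `S`, `v_i`.
#' @export
step_connection <- function(state, sp, rule, io, point, fb = feedforward(),
                            config = sim_config(1)) {
  w <- state$weights
  S_pre <- length(w)
  w_init <- if (is.null(config$w_init)) default_w_init(rule) else config$w_init
  # (1) rates
  v_i <- io$forward(sum(w) * point$v_j + point$I)
  if (!is_feedforward(fb)) {
    for (it in 1:50) {
      vj <- fb$r0 + fb$r1 * v_i
      v_new <- io$forward(sum(w) * vj + point$I)
      if (abs(v_new - v_i) < 1e-12) { v_i <- v_new; break }
      v_i <- v_new
    }
  }
  v_j <- presyn_rate(fb, v_i, point$v_j)
  # (2) RK4 on each weight, rate held fixed
  if (S_pre > 0) {
    f <- function(wk) rule_rhs(rule, wk, v_i, v_j)
    for (s in seq_len(config$substeps)) {
      k1 <- f(w); k2 <- f(w + k1 / 2); k3 <- f(w + k2 / 2); k4 <- f(w + k3)
      w <- w + (k1 + 2 * k2 + 2 * k3 + k4) / 6
      if (rule$kind %in% c("hebb_hard", "bcm_fixed_hard"))
        w <- pmin(pmax(w, rule$w_min), rule$w_max)
      w <- pmax(w, 0)
    }
  }
  # (3) deletion against updated weights
  if (length(w) > 0) {
    pdel <- pmin(1, deletion_prob(sp, w) * config$speedup)
    keep <- rev(stats::runif(length(w)) >= rev(pdel))
    w <- w[keep]
  }
  # (4) creation at sites vacant at step start
  nb <- stats::rbinom(1, sp$P - S_pre, min(1, sp$p_build * config$speedup))
  if (nb > 0) w <- c(w, rep(w_init, nb))
  list(weights = w, S = length(w), v_i = v_i)
}

#' Long-run occupancy of the stochastic simulation
#'
#' Runs the full stochastic dynamics and returns the empirical distribution
#' of the synapse count after burn-in. The reference BCM-with-scaling rule in
#' a feed-forward or linear-feedback system uses the compiled fast path;
#' other rules fall back to the R stepper.
#'
#' @param config [sim_config()].
#' @param sp,rule,io,point,fb model components.
#' @param seed optional RNG seed (set locally).
#' @param pinned_pdel optional per-state deletion probabilities `S = 0..P`;
#'   when given, weights are ignored and the pure birth-death-with-batches
#'   chain is simulated (time-scale-separation limit).
#' @return empirical [synapse_distribution] with the recorded trace (if any)
#'   as attribute `trace`.
#' @export
run_equilibrium_sim <- function(config, sp, rule, io, point,
                                fb = feedforward(), seed = NULL,
                                pinned_pdel = NULL) {
  if (!is.null(seed)) set.seed(seed)
  burn <- as.integer(config$burn_in_frac * config$n_steps)
  if (!is.null(pinned_pdel)) {
    check_pdel(sp, pinned_pdel)
    occ <- .cpp_sim_pinned(config$n_steps, burn, sp$P,
                           min(1, sp$p_build * config$speedup),
                           pmin(1, pinned_pdel * config$speedup), 0L)
    return(synapse_distribution(occ / sum(occ), method = "simulation_pinned"))
  }
  w_init <- if (is.null(config$w_init)) default_w_init(rule) else config$w_init
  if (rule$kind == "bcm_scaling" && io$kind == "logistic") {
    res <- .cpp_sim_bcm(config$n_steps, burn, sp$P, sp$p_build,
                        sp$rho * log(sp$p_build), sp$a^2, sp$q,
                        rule$mu, rule$theta, rule$kappa, rule$v_tss,
                        point$v_j, point$I, !is_feedforward(fb),
                        w_init, config$substeps, config$speedup,
                        config$record_stride, 0L, numeric(0))
    occ <- res$occupancy
    out <- synapse_distribution(occ / sum(occ), method = "simulation")
    if (config$record_stride > 0) {
      tr <- as.data.frame(res$trace)
      names(tr) <- c("S", "mean_w", "v_i")
      attr(out, "trace") <- tr
    }
    return(out)
  }
  # generic R path
  state <- list(weights = numeric(0))
  occ <- numeric(sp$P + 1)
  for (t in seq_len(config$n_steps)) {
    state <- step_connection(state, sp, rule, io, point, fb, config)
    if (t > burn) occ[state$S + 1] <- occ[state$S + 1] + 1
  }
  synapse_distribution(occ / sum(occ), method = "simulation_r")
}

#' Hysteresis stimulation protocol
#'
#' One cycle raises the stimulation level from `lower` to `upper` in steps of
#' `step` and lowers it back; each level is held for `dwell` structural steps.
#' The varied side is either the presynaptic activity (`"pre"`) or the
#' postsynaptic stimulation (`"post"`, levels are the rate at zero synapses).
#'
#' @param vary `"post"` or `"pre"`.
#' @param step level increment (reference protocol: 0.01).
#' @param lower,upper level bounds (reference protocol: 0.05 and 1.0; an
#'   upper level of 1 is clipped to 0.99 to stay in the IO range).
#' @param dwell structural steps per level.
#' @param cycles number of stimulation cycles.
#' @export
hysteresis_protocol <- function(vary = c("post", "pre"), step = 0.01,
                                lower = 0.05, upper = 1.0, dwell = 1e4,
                                cycles = 20) {
  vary <- match.arg(vary)
  stopifnot(lower > 0, upper <= 1, lower <= upper, step > 0,
            dwell >= 1, cycles >= 1)
  levels <- seq(lower, upper, by = step)
  levels[levels >= 1] <- 0.99
  structure(list(vary = vary, levels = levels, dwell = as.integer(dwell),
                 cycles = as.integer(cycles)),
            class = "hysteresis_protocol")
}

#' Run the hysteresis protocol
#'
#' Simulates the reference BCM-with-scaling connection through repeated
#' up/down stimulation sweeps and returns the per-level time-averaged synapse
#' count for the increasing and decreasing branches, averaged over cycles.
#' An open loop (decreasing branch above increasing branch at intermediate
#' levels) is the stochastic signature of the underlying bistability.
#'
#' @param protocol [hysteresis_protocol()].
#' @param config [sim_config()]; its `n_steps` is ignored (the protocol sets
#'   the step count) but `w_init`, `substeps` and `speedup` apply.
#' @param sp,rule,io model components (rule must be `bcm_scaling`, logistic IO).
#' @param v_j presynaptic rate held fixed when varying the postsynaptic side.
#' @param I postsynaptic influence held fixed when varying the presynaptic side.
#' @param seed optional RNG seed.
#' @return object of class `hysteresis_trace`: data.frame with `level`,
#'   `mean_up`, `mean_down`; attribute `loop_area` (sum of
#'   `mean_down - mean_up` times the level step).
#' @export
run_hysteresis <- function(protocol, config, sp, rule, io,
                           v_j = NULL, I = NULL, seed = NULL) {
  if (rule$kind != "bcm_scaling" || io$kind != "logistic")
    stop("run_hysteresis implements the reference bcm_scaling/logistic system")
  if (!is.null(seed)) set.seed(seed)
  vary_post <- protocol$vary == "post"
  if (vary_post && is.null(v_j)) stop("varying the postsynaptic side needs v_j")
  if (!vary_post && is.null(I)) stop("varying the presynaptic side needs I")
  w_init <- if (is.null(config$w_init)) default_w_init(rule) else config$w_init
  res <- .cpp_hysteresis_bcm(protocol$levels, protocol$dwell, protocol$cycles,
                             sp$P, sp$p_build, sp$rho * log(sp$p_build),
                             sp$a^2, sp$q, rule$mu, rule$theta, rule$kappa,
                             rule$v_tss, vary_post,
                             if (vary_post) v_j else 0,
                             if (vary_post) 0 else I,
                             w_init, config$substeps, config$speedup)
  out <- data.frame(level = res$level, mean_up = res$mean_up,
                    mean_down = res$mean_down)
  dl <- diff(protocol$levels)
  gap <- res$mean_down - res$mean_up
  area <- sum((gap[-1] + gap[-length(gap)]) / 2 * dl)
  structure(out, loop_area = area, vary = protocol$vary,
            cycles = protocol$cycles,
            class = c("hysteresis_trace", "data.frame"))
}

#' @export
print.hysteresis_trace <- function(x, ...) {
  cat(sprintf("<hysteresis_trace> %s sweep, %d levels, %d cycle(s); loop area %.3g\n",
              attr(x, "vary"), nrow(x), attr(x, "cycles"), attr(x, "loop_area")))
  invisible(x)
}
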