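# Shared model fixtures. The "reference" configuration is the working point
# of the rate model: BCM with synaptic scaling, feed-forward, logistic IO,
# P = 12, ln p_build = -16, rho = 0.125, a = 2.

ref_io <- function() logistic_io()
ref_rule <- function() rule_spec("bcm_scaling", mu = 0.2, theta = 0.08,
                                 kappa = 9, v_tss = 0.1)
ref_sp <- function(...) structural_params(p_build = exp(-16), rho = 0.125,
                                          a = 2, q = 4 / 3, P = 12, ...)
ref_point <- function(io = ref_io()) {
  system_point(v_j = 0.656, v_i_S0 = 0.2975, io = io)
}

# plain probability vector (drop class and attributes) for comparisons
pvec <- function(d) as.numeric(unclass(d))

ref_first_step <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- ref_sp()
      cache <<- first_step_distribution(sp, pdel_profile(sp, ref_profile()))
    }
    cache
  }
})

ref_profile <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- activity_profile(12, ref_point(), ref_rule(), ref_io())
    cache
  }
})

# rule set and parameters used for the condition-table figure:
# w_min = 0.04, w_max = 0.95, v_j = 0.08, v_tss = 0.05, kappa = 1,
# theta = 0.1, sliding-threshold fixed weight pinned at 0.5
condition_table_rules <- function() {
  list(
    hebb_hard = rule_spec("hebb_hard", w_min = 0.04, w_max = 0.95),
    bcm_fixed_hard = rule_spec("bcm_fixed_hard", theta = 0.1,
                               w_min = 0.04, w_max = 0.95),
    bcm_sliding = rule_spec("bcm_sliding", theta = 0.1, theta_tilde = 2,
                            vw_fun = NULL),
    oja = rule_spec("oja"),
    hebb_scaling = rule_spec("hebb_scaling", v_tss = 0.05, kappa = 1),
    bcm_scaling = rule_spec("bcm_scaling", theta = 0.1, v_tss = 0.05,
                            kappa = 1)
  )
}

# independent oracle for the self-consistent state: dense scan of
# g(v) = F(S w*(v) v_j + I) - v plus bisection refinement, sharing nothing
# with the production grid-plus-uniroot path
oracle_consistent_v <- function(S, point, rule, io, fb = feedforward(),
                                grid_step = 1e-4) {
  g <- function(v) {
    w <- structplast:::weight_map_extended(
      rule, v, v_j = if (fb$r1 == 0) rep(point$v_j, length(v)) else NULL,
      fb = fb, io = io, I = point$I)
    vj <- if (fb$r1 == 0) point$v_j else fb$r0 + fb$r1 * v
    io$forward(S * w * vj + point$I) - v
  }
  v <- seq(grid_step, 1 - grid_step, by = grid_step)
  gv <- g(v)
  ok <- is.finite(gv)
  roots <- c()
  for (i in which(ok[-length(ok)] & ok[-1] & gv[-length(gv)] * gv[-1] < 0)) {
    lo <- v[i]; hi <- v[i + 1]
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots
}

# RK4 integration of rule_rhs to convergence -- an independent route to the
# fixed weight (bounds applied for the hard-bounded kinds)
integrate_rule_to_fp <- function(rule, w0, v_i, v_j, dt = 0.5,
                                 n_max = 200000, tol = 1e-10) {
  w <- w0
  for (i in seq_len(n_max)) {
    k1 <- rule_rhs(rule, w, v_i, v_j)
    k2 <- rule_rhs(rule, w + dt * k1 / 2, v_i, v_j)
    k3 <- rule_rhs(rule, w + dt * k2 / 2, v_i, v_j)
    k4 <- rule_rhs(rule, w + dt * k3, v_i, v_j)
    w_new <- w + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    if (rule$kind %in% c("hebb_hard", "bcm_fixed_hard"))
      w_new <- min(max(w_new, rule$w_min), rule$w_max)
    w_new <- max(w_new, 0)
    if (abs(w_new - w) < tol) return(w_new)
    w <- w_new
  }
  w
}
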