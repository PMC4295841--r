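RULE_KINDS <- c("hebb_hard", "bcm_fixed_hard", "bcm_sliding", "oja",
                "hebb_scaling", "bcm_scaling", "empirical")

#' Rate-based synaptic plasticity rules
#'
#' A `rule_spec` names one rate-based plasticity rule together with its
#' parameters. Supported kinds:
#'
#' * `hebb_hard`: \eqn{\dot w = \mu v_j v_i}, hard bounds `[w_min, w_max]`.
#' * `bcm_fixed_hard`: BCM with fixed LTP/LTD threshold `theta` and hard
#'   bounds `[w_min, w_max]`.
#' * `bcm_sliding`: BCM whose threshold slides to \eqn{\tilde\theta v_i^2}.
#' * `oja`: \eqn{\dot w = \mu (v_j v_i - w v_i^2)}.
#' * `hebb_scaling`: Hebb plus weight-dependent synaptic scaling towards the
#'   target rate `v_tss`: \eqn{\dot w = \mu(v_j v_i - \kappa^{-1}(v_i - v_{tss}) w^2)}.
#' * `bcm_scaling`: fixed-threshold BCM plus the same scaling term:
#'   \eqn{\dot w = \mu(v_j v_i (v_i-\theta) - \kappa^{-1}(v_i - v_{tss}) w^2)}.
#' * `empirical`: a user-supplied fixed-weight map `vw_fun(v_i, v_j)`,
#'   typically obtained from a spiking plasticity rule (see [ca_vw_surface()]).
#'
#' Defaults follow the reference simulations of the rate model:
#' `mu = 0.2, kappa = 9, theta = 0.08, v_tss = 0.1`.
#'
#' @param kind one of the rule names above.
#' @param mu learning rate (1/time-step). Sets the synaptic time scale only.
#' @param theta LTP/LTD threshold rate of the BCM rules.
#' @param kappa synaptic scaling influence parameter (> 0).
#' @param v_tss characteristic target rate of synaptic scaling, in (0,1).
#' @param w_min,w_max hard weight bounds where the rule uses them.
#' @param theta_tilde sliding-threshold coefficient of `bcm_sliding`.
#' @param vw_fun for `kind = "empirical"`: function `(v_i, v_j) -> w` giving
#'   the stable fixed weight directly.
#' @return object of class `rule_spec`.
#' @export
rule_spec <- function(kind, mu = 0.2, theta = 0.08, kappa = 9, v_tss = 0.1,
                      w_min = 0, w_max = 1, theta_tilde = NULL, vw_fun = NULL) {
  kind <- match.arg(kind, RULE_KINDS)
  stopifnot(mu > 0, kappa > 0, v_tss > 0, v_tss < 1)
  if (!(w_min >= 0 && w_min < w_max)) stop("need 0 <= w_min < w_max")
  if (kind == "empirical" && !is.function(vw_fun))
    stop("empirical rule needs vw_fun(v_i, v_j)")
  structure(list(kind = kind, mu = mu, theta = theta, kappa = kappa,
                 v_tss = v_tss, w_min = w_min, w_max = w_max,
                 theta_tilde = theta_tilde, vw_fun = vw_fun),
            class = "rule_spec")
}

#' @export
print.rule_spec <- function(x, ...) {
  cat("<rule_spec>", x$kind, "\n")
  p <- switch(x$kind,
    hebb_hard = sprintf("mu=%g bounds=[%g,%g]", x$mu, x$w_min, x$w_max),
    bcm_fixed_hard = sprintf("mu=%g theta=%g bounds=[%g,%g]", x$mu, x$theta, x$w_min, x$w_max),
    bcm_sliding = sprintf("mu=%g theta_tilde=%s", x$mu, format(x$theta_tilde)),
    oja = sprintf("mu=%g", x$mu),
    sprintf("mu=%g theta=%g kappa=%g v_tss=%g", x$mu, x$theta, x$kappa, x$v_tss))
  cat(" ", p, "\n")
  invisible(x)
}

#' Right-hand side of a plasticity rule
#'
#' Instantaneous weight change \eqn{dw/dt} of the rule at the given weight and
#' activities. Hard bounds of the bounded rules are applied after integration,
#' not inside the derivative.
#'
#' @param rule a [rule_spec()].
#' @param w synaptic weight.
#' @param v_i,v_j post- and presynaptic rates.
#' @export
rule_rhs <- function(rule, w, v_i, v_j) {
  stopifnot(all(is.finite(w)), all(is.finite(v_i)), all(is.finite(v_j)))
  switch(rule$kind,
    hebb_hard      = rule$mu * v_j * v_i,
    bcm_fixed_hard = rule$mu * v_j * v_i * (v_i - rule$theta),
    bcm_sliding    = {
      if (is.null(rule$theta_tilde)) stop("bcm_sliding needs theta_tilde")
      rule$mu * v_j * v_i * (v_i - rule$theta_tilde * v_i^2)
    },
    oja            = rule$mu * (v_j * v_i - w * v_i^2),
    hebb_scaling   = rule$mu * (v_j * v_i - (v_i - rule$v_tss) * w^2 / rule$kappa),
    bcm_scaling    = rule$mu * (v_j * v_i * (v_i - rule$theta) -
                                (v_i - rule$v_tss) * w^2 / rule$kappa),
    stop("rule_rhs not defined for kind ", rule$kind))
}

# Hebbian drive h(v_i, v_j) of the scaling rules: dw/dt = mu*(h - (v_i-v_tss) w^2 / kappa)
scaling_drive <- function(rule, v_i, v_j) {
  switch(rule$kind,
    hebb_scaling = v_j * v_i,
    bcm_scaling  = v_j * v_i * (v_i - rule$theta),
    stop("not a scaling rule"))
}

#' Stable fixed weight of a plasticity rule
#'
#' Returns the weight at which the rule's dynamics come to rest for fixed
#' activities. Hard-bounded rules rest at the admissible bound; the scaling
#' rules have the closed-form interior fixed point
#' \eqn{w^* = \sqrt{\kappa\, h(v_i,v_j) / (v_i - v_{tss})}} with Hebbian drive
#' `h`. The sliding-threshold BCM fixed point pins the postsynaptic rate to
#' \eqn{\tilde\theta^{-1}} and therefore needs the inverse IO curve and the
#' external influence `I`; it is only available for invertible curves with
#' \eqn{\tilde\theta^{-1}} in range.
#'
#' A domain error is raised when no finite stable fixed point exists at the
#' requested activities (e.g. scaling rules with `v_i <= v_tss`, or negative
#' Hebbian drive making \eqn{w^{*2} < 0}). The error is deliberate: silently
#' clamping would corrupt downstream log-probability profiles.
#'
#' @inheritParams rule_rhs
#' @param fb a [feedback_spec()]; only used to resolve `v_j` when `NULL`.
#' @param io,I IO curve and external influence, needed by `bcm_sliding` only.
#' @return the fixed weight (scalar or vector along `v_i`).
#' @export
fixed_weight <- function(rule, v_i, v_j = NULL, fb = feedforward(),
                         io = NULL, I = NULL) {
  if (is.null(v_j)) {
    if (is_feedforward(fb)) stop("feed-forward system: v_j must be supplied")
    v_j <- fb$r0 + fb$r1 * v_i
  }
  switch(rule$kind,
    hebb_hard = rep(rule$w_max, length.out = length(v_i)),
    bcm_fixed_hard = ifelse(v_i < rule$theta, rule$w_min, rule$w_max),
    bcm_sliding = {
      if (is.null(rule$theta_tilde)) stop("bcm_sliding needs theta_tilde")
      vt <- 1 / rule$theta_tilde
      if (is.null(io) || is.null(I))
        stop("bcm_sliding fixed weight needs io and I")
      if (vt <= max(0, io$range[1]) || vt >= io$range[2])
        stop("bcm_sliding: 1/theta_tilde outside the IO range; fixed weight not applicable")
      vj_at <- if (is_feedforward(fb)) v_j else fb$r0 + fb$r1 * vt
      rep((io$inverse(vt) - I) / vj_at, length.out = length(v_i))
    },
    oja = {
      if (any(v_i <= 0)) stop("oja fixed weight needs v_i > 0")
      v_j / v_i
    },
    hebb_scaling = ,
    bcm_scaling = {
      if (any(v_i <= rule$v_tss))
        stop("scaling rule: no stable finite fixed weight for v_i <= v_tss")
      h <- scaling_drive(rule, v_i, v_j)
      ratio <- rule$kappa * h / (v_i - rule$v_tss)
      if (any(ratio < 0))
        stop("scaling rule: negative Hebbian drive, w*^2 < 0 (domain error)")
      sqrt(ratio)
    },
    empirical = rule$vw_fun(v_i, v_j),
    stop("fixed_weight not defined for kind ", rule$kind))
}

# Extended weight map used by the self-consistency solver and the simulator
# analysis: where the strict fixed point does not exist, the weight dynamics
# clamped to w >= 0 either collapse to the boundary w = 0 (stable there) or
# run away (NA). Scaling rules:
#   v_i >  v_tss : interior w* if drive h > 0, else w = 0
#   v_i <= v_tss : w = 0 if h < 0 (locally stable boundary), NA if h >= 0
weight_map_extended <- function(rule, v_i, v_j = NULL, fb = feedforward(),
                                io = NULL, I = NULL) {
  if (is.null(v_j)) v_j <- fb$r0 + fb$r1 * v_i
  if (rule$kind %in% c("hebb_scaling", "bcm_scaling")) {
    h <- scaling_drive(rule, v_i, v_j)
    w <- rep(NA_real_, length(v_i))
    hi <- v_i > rule$v_tss
    w[hi & h > 0] <- sqrt(rule$kappa * h[hi & h > 0] /
                          (v_i[hi & h > 0] - rule$v_tss))
    w[hi & h <= 0] <- 0
    w[!hi & h < 0] <- 0
    w
  } else {
    out <- try(fixed_weight(rule, v_i, v_j, fb = fb, io = io, I = I), silent = TRUE)
    if (inherits(out, "try-error")) rep(NA_real_, length(v_i)) else out
  }
}

#' Does the fixed weight grow with postsynaptic activity?
#'
#' The necessary condition for the experimentally observed bimodal
#' synapse-count distribution (two intersections of the combinatorial and
#' deletion terms) is a strictly positive slope of the fixed weight as a
#' function of the postsynaptic rate, \eqn{dw^*/dv_i > 0}, over the activity
#' range of interest. The slope is measured by central differences
#' (step 1e-4) on a 200-point grid; activities where the rule has no fixed
#' weight shrink the evaluable range and are reported.
#'
#' @param rule a [rule_spec()].
#' @param fb [feedback_spec()]: feed-forward (`r1 = 0`, presynaptic rate fixed
#'   at `v_j`) or feedback (`v_j = r0 + r1 v_i`).
#' @param v_range postsynaptic activity interval to test.
#' @param v_j presynaptic rate for the feed-forward system.
#' @param io,I passed to [fixed_weight()] for `bcm_sliding`.
#' @param n grid resolution.
#' @return list with `ok` (TRUE iff the slope is positive throughout the
#'   evaluable range and at least half the range is evaluable), the slope
#'   profile, and the evaluable fraction.
#' @export
necessary_condition <- function(rule, fb = feedforward(), v_range = c(0.15, 0.95),
                                v_j = 0.08, io = NULL, I = NULL, n = 200) {
  stopifnot(length(v_range) == 2, v_range[1] < v_range[2])
  v <- seq(v_range[1], v_range[2], length.out = n)
  h <- 1e-4
  wf <- function(vv) {
    vapply(vv, function(v1) {
      vj1 <- if (is_feedforward(fb)) v_j else fb$r0 + fb$r1 * v1
      out <- try(fixed_weight(rule, v1, vj1, fb = fb, io = io, I = I),
                 silent = TRUE)
      if (inherits(out, "try-error")) NA_real_ else out
    }, numeric(1))
  }
  slope <- (wf(v + h) - wf(v - h)) / (2 * h)
  evaluable <- mean(is.finite(slope))
  ok <- evaluable >= 0.5 && all(slope[is.finite(slope)] > 0) && any(is.finite(slope))
  structure(list(ok = ok, v = v, slope = slope, evaluable_fraction = evaluable,
                 rule = rule$kind, system = if (is_feedforward(fb)) "feedforward" else "feedback"),
            class = "condition_check")
}

#' @export
print.condition_check <- function(x, ...) {
  cat(sprintf("<condition_check> %s (%s): %s (evaluable %.0f%%)\n",
              x$rule, x$system, if (isTRUE(x$ok)) "slope > 0" else "fails",
              100 * x$evaluable_fraction))
  invisible(x)
}

# mean inner curvature of a discrete profile between its outermost pair of
# zero crossings; NA when fewer than two crossings exist
delta_mean_curvature <- function(delta) {
  s <- sign(delta)
  nz <- which(s != 0)
  cross <- nz[which(diff(s[nz]) != 0)]   # last index before each crossing
  if (length(cross) < 2) return(NA_real_)
  i1 <- cross[1]; i2 <- cross[length(cross)] + 1
  if (i2 - i1 < 2) {
    # crossings in adjacent gaps: single interior point, use local curvature
    idx <- max(2, min(i1 + 1, length(delta) - 1))
    return(delta[idx + 1] - 2 * delta[idx] + delta[idx - 1])
  }
  d2 <- diff(diff(delta[i1:i2]))
  mean(d2)
}

#' Sufficient condition: ordering of the distribution extrema
#'
#' Given two sign changes of the log-probability increment
#' \eqn{\Delta_{\ln p}[S]} (the necessary condition), the experimentally
#' observed shape additionally requires the crossings to occur in the order
#' minimum-then-maximum, i.e. the average curvature of \eqn{\Delta_{\ln p}}
#' between its two zero crossings must be negative. The curvature can be
#' supplied by a concave IO curve or by a sublinearly growing fixed-weight
#' relation; the report states the mean curvature of both candidate sources.
#'
#' @inheritParams necessary_condition
#' @param io the [io_curve].
#' @param sp [structural_params()] of the deletion model.
#' @param point [system_point()] at which the profile is evaluated.
#' @return list with `ok` (TRUE iff two crossings exist and the mean inner
#'   curvature is negative), `applicable` (FALSE when fewer than two
#'   crossings), the crossing positions and the curvature report.
#' @export
sufficient_condition <- function(rule, io, fb, sp, point) {
  prof <- activity_profile(sp$P, point, rule, io, fb)
  pdel <- pdel_profile(sp, prof)
  delta <- delta_ln_p(sp, pdel)
  s <- sign(delta)
  nz <- which(s != 0)
  n_cross <- if (length(nz)) sum(diff(s[nz]) != 0) else 0L
  if (n_cross < 2) {
    return(structure(list(ok = NA, applicable = FALSE, n_crossings = n_cross,
                          mean_curvature = NA_real_, delta = delta),
                     class = "condition_check2"))
  }
  curv <- delta_mean_curvature(delta)
  # attribute the curvature source: IO concavity at the visited activities vs
  # concavity of the v-w relation along the profile
  v <- prof$v_i_star
  io_curv <- if (length(v) >= 3) mean(diff(diff(io$inverse(pmin(pmax(v, 1e-9), 1 - 1e-9))))) else NA
  vw_curv <- if (length(v) >= 3 && !anyNA(prof$w_star[-1]))
    mean(diff(diff(prof$w_star[-1]))) else NA
  structure(list(ok = curv < 0, applicable = TRUE, n_crossings = n_cross,
                 mean_curvature = curv,
                 vw_curvature = vw_curv, io_inverse_curvature = io_curv,
                 mechanism = if (is.finite(vw_curv) && vw_curv < 0)
                   "concave v-w relation (case 6_1)" else "concave IO curve (case 6_2)",
                 delta = delta),
            class = "condition_check2")
}

#' @export
print.condition_check2 <- function(x, ...) {
  if (!x$applicable)
    cat("<sufficient_condition> not applicable:", x$n_crossings, "zero crossing(s)\n")
  else
    cat(sprintf("<sufficient_condition> %s (mean inner curvature %.4g; %s)\n",
                if (isTRUE(x$ok)) "fulfilled" else "violated",
                x$mean_curvature, x$mechanism))
  invisible(x)
}
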