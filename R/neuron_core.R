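#' Self-consistent activity and weight for a fixed synapse count
#'
#' Under time-scale separation, the weights of all `S` realised synapses sit
#' at the rule's fixed point before the next structural change. The
#' postsynaptic rate and the per-synapse weight then solve jointly
#' \deqn{v_i^* = F(S\, w^*\, v_j + I), \qquad w^* = w^*_{rule}(v_i^*, v_j),}
#' with \eqn{v_j} replaced by \eqn{r_0 + r_1 v_i^*} in a feedback system.
#'
#' The solver scans the admissible activity interval on a fine grid for sign
#' changes of \eqn{g(v) = F(S w^*(v) v_j(v) + I) - v} and bisects each
#' bracket. Where the rule has no finite stable fixed weight the clamped
#' weight dynamics (w >= 0) may rest at the boundary w = 0; the corresponding
#' "collapsed" state \eqn{v = F(I)} is a valid root and is detected
#' explicitly. If several roots exist, the one reached by forward iteration
#' from \eqn{v = F(I)} (the branch continued from the zero-synapse state) is
#' returned as primary and all roots are reported.
#'
#' @param S synapse count, `0 <= S <= P` (real values are allowed; they are
#'   used by the continuous fixed-point analysis).
#' @param point a [system_point()].
#' @param rule a [rule_spec()].
#' @param io an [io_curve].
#' @param fb a [feedback_spec()].
#' @param n_grid scan resolution.
#' @return object of class `consistent_state`: list with `S`, `v_i_star`,
#'   `w_star` (NA at S = 0), `collapsed`, `all_roots` (data.frame `v`, `w`),
#'   `multiple` flag.
#' @export
consistent_state <- function(S, point, rule, io, fb = feedforward(),
                             n_grid = 400) {
  stopifnot(S >= 0)
  I <- point$I
  v0 <- io$forward(I)
  if (S == 0) {
    return(structure(list(S = 0, v_i_star = v0, w_star = NA_real_,
                          collapsed = FALSE, multiple = FALSE,
                          all_roots = data.frame(v = v0, w = NA_real_)),
                     class = "consistent_state"))
  }
  wmap <- function(v) weight_map_extended(rule, v, v_j = if (is_feedforward(fb))
    rep(point$v_j, length(v)) else NULL, fb = fb, io = io, I = I)
  gfun <- function(v) {
    w <- wmap(v)
    vj <- presyn_rate(fb, v, point$v_j)
    io$forward(S * w * vj + I) - v
  }
  eps <- 1e-9
  v_grid <- seq(eps, 1 - eps, length.out = n_grid)
  g <- gfun(v_grid)
  roots <- numeric(0)
  ok <- is.finite(g)
  for (i in seq_len(n_grid - 1)) {
    if (ok[i] && ok[i + 1] && g[i] * g[i + 1] < 0) {
      r <- stats::uniroot(gfun, c(v_grid[i], v_grid[i + 1]), tol = 1e-13)
      roots <- c(roots, r$root)
    }
    # exact zeros on the grid (measure-zero, but cheap to honour)
    if (ok[i] && g[i] == 0) roots <- c(roots, v_grid[i])
  }
  # collapsed root: weights rest at 0, so v = F(I) exactly, provided w = 0 is
  # the stable clamped state there
  w_at_v0 <- wmap(v0)
  if (is.finite(w_at_v0) && w_at_v0 == 0) {
    roots <- c(v0, roots[abs(roots - v0) >= 1e-8])  # v0 is exact there
  }
  # saturated branch: with strong total drive the root sits between the top
  # grid point and 1 (numerically equal to 1); recover it by forward iteration
  top <- max(which(ok))
  if (length(top) && ok[top] && gfun(v_grid[top]) > 0) {
    v <- v_grid[top]
    for (it in 1:200) {
      w <- wmap(v)
      if (!is.finite(w)) break
      v_new <- io$forward(S * w * presyn_rate(fb, v, point$v_j) + I)
      if (abs(v_new - v) < 1e-15) { v <- v_new; break }
      v <- v_new
    }
    if (is.finite(wmap(v)) && abs(gfun(v)) < 1e-12 &&
        !any(abs(roots - v) < 1e-12)) roots <- c(roots, v)
  }
  roots <- sort(unique(roots))
  if (!length(roots))
    stop("consistent_state: no self-consistent activity found for S = ", S)
  # primary root: forward iteration from the zero-synapse state
  primary <- forward_iterate(v0, S, point, rule, io, fb, roots)
  w_primary <- wmap(primary)
  res <- abs(gfun(primary))
  if (is.finite(res) && res > 1e-10)
    stop(sprintf("consistent_state: residual %.3g above tolerance at S = %g", res, S))
  structure(list(S = S, v_i_star = primary, w_star = w_primary,
                 collapsed = is.finite(w_primary) && w_primary == 0,
                 multiple = length(roots) > 1,
                 all_roots = data.frame(v = roots, w = wmap(roots))),
            class = "consistent_state")
}

# iterate v <- F(S w(v) v_j(v) + I) from v0; weights without a stable fixed
# point are treated as collapsed-to-zero during the iteration (new synapses
# start small, so the continued branch grows from below). Returns the root
# nearest to the limit point.
forward_iterate <- function(v0, S, point, rule, io, fb, roots) {
  v <- v0
  I <- point$I
  for (it in 1:2000) {
    w <- weight_map_extended(rule, v, v_j = if (is_feedforward(fb))
      point$v_j else NULL, fb = fb, io = io, I = I)
    if (!is.finite(w)) w <- 0
    vj <- presyn_rate(fb, v, point$v_j)
    v_new <- io$forward(S * w * vj + I)
    if (abs(v_new - v) < 1e-13) { v <- v_new; break }
    v <- v_new
  }
  roots[which.min(abs(roots - v))]
}

#' @export
print.consistent_state <- function(x, ...) {
  cat(sprintf("<consistent_state> S = %g: v_i* = %.6g, w* = %s%s\n",
              x$S, x$v_i_star,
              if (is.na(x$w_star)) "NA" else sprintf("%.6g", x$w_star),
              if (x$multiple) sprintf(" (%d roots, primary branch shown)",
                                      nrow(x$all_roots)) else ""))
  invisible(x)
}

#' Activity profile over all synapse counts
#'
#' Solves [consistent_state()] for every `S = 0..P` and collects the fixed
#' activities and weights. The profile is the input to every equilibrium
#' computation of the structural Markov model.
#'
#' @inheritParams consistent_state
#' @param P number of potential synapses.
#' @return object of class `activity_profile`: list with vectors `S`,
#'   `v_i_star`, `w_star`, logical `collapsed` and `multiple`, and a
#'   `monotone` flag (TRUE iff `v_i_star` is strictly increasing).
#' @export
activity_profile <- function(P, point, rule, io, fb = feedforward(), ...) {
  stopifnot(P >= 0)
  S <- 0:P
  states <- vector("list", P + 1)
  fails <- character(0)
  for (s in S) {
    st <- try(consistent_state(s, point, rule, io, fb, ...), silent = TRUE)
    if (inherits(st, "try-error")) {
      fails <- c(fails, sprintf("S=%d: %s", s, attr(st, "condition")$message))
      states[[s + 1]] <- list(v_i_star = NA_real_, w_star = NA_real_,
                              collapsed = NA, multiple = NA)
    } else states[[s + 1]] <- st
  }
  if (length(fails))
    stop("activity_profile: consistent_state failed at ",
         paste(fails, collapse = "; "))
  v <- vapply(states, `[[`, numeric(1), "v_i_star")
  w <- vapply(states, `[[`, numeric(1), "w_star")
  structure(list(S = S, v_i_star = v, w_star = w,
                 collapsed = vapply(states, `[[`, logical(1), "collapsed"),
                 multiple = vapply(states, `[[`, logical(1), "multiple"),
                 monotone = all(diff(v) > 0),
                 point = point, rule_kind = rule$kind),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> P = %d, v_i*: %.4g .. %.4g (%s)\n",
              max(x$S), x$v_i_star[1], x$v_i_star[length(x$v_i_star)],
              if (x$monotone) "strictly increasing" else "NOT monotone"))
  invisible(x)
}

#' @export
as.data.frame.activity_profile <- function(x, ...) {
  data.frame(S = x$S, v_i_star = x$v_i_star, w_star = x$w_star,
             collapsed = x$collapsed, multiple = x$multiple)
}
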