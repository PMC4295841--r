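#' Structural plasticity parameters
#'
#' The stochastic rewiring model: at each time step every vacant potential
#' site forms a synapse with probability `p_build`, and every realised synapse
#' with weight `w` is removed with the weight-dependent probability
#' \deqn{p_{del}(w) = p_{build}^{\,\rho}\, \exp(-a^2 w^{q}),}
#' a decreasing function of the weight (strong synapses live longer). `rho`
#' scales the maximal deletion probability relative to the building
#' probability (for `p_build < 1`, `rho < 1` makes deletion of weak synapses
#' faster than build-up) and `a` sets how strongly the weight protects a
#' synapse. The exponent `q = 4/3` is motivated by spine-volume dynamics; the
#' results are insensitive to its exact value and it is configurable.
#'
#' @param p_build per-site, per-step synapse creation probability, in (0,1).
#' @param rho deletion/creation scale (> 0), exponent on `p_build`.
#' @param a weight-sensitivity (>= 0).
#' @param q weight exponent (default 4/3).
#' @param P number of potential synapses (>= 1).
#' @return object of class `structural_params`.
#' @examples
#' sp <- structural_params()      # reference parameter set
#' deletion_prob(sp, c(0, 1, 2))
#' @export
structural_params <- function(p_build = exp(-16), rho = 0.125, a = 2,
                              q = 4 / 3, P = 12) {
  stopifnot(p_build > 0, p_build < 1, rho > 0, a >= 0, q > 0,
            P >= 1, P == round(P))
  structure(list(p_build = p_build, rho = rho, a = a, q = q, P = as.integer(P)),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat(sprintf("<structural_params> P = %d, ln p_build = %.4g, rho = %g, a = %g, q = %g\n",
              x$P, log(x$p_build), x$rho, x$a, x$q))
  cat(sprintf("  p_del range: (0, %.4g]\n", x$p_build^x$rho))
  invisible(x)
}

#' Weight-dependent deletion probability
#'
#' \eqn{p_{del}(w) = p_{build}^{\rho} \exp(-a^2 w^q)}, vectorised over `w`.
#'
#' @param sp [structural_params()].
#' @param w nonnegative weight(s).
#' @export
deletion_prob <- function(sp, w) {
  if (any(w < 0)) stop("deletion_prob: negative weight")
  exp(sp$rho * log(sp$p_build) - sp$a^2 * w^sp$q)
}

# deletion probability per state S = 0..P from an activity profile; the S = 0
# entry is a placeholder (nothing can be deleted there)
#' Per-state deletion probabilities from an activity profile
#'
#' @param sp [structural_params()].
#' @param profile an [activity_profile()] (its `P` must equal `sp$P`).
#' @return named numeric vector of length `P + 1` (states `S = 0..P`); entry
#'   `S = 0` is a placeholder.
#' @export
pdel_profile <- function(sp, profile) {
  stopifnot(max(profile$S) == sp$P)
  w <- profile$w_star
  w[1] <- 0                       # S = 0: no synapse to delete; placeholder
  out <- deletion_prob(sp, w)
  names(out) <- paste0("S", profile$S)
  out
}

check_pdel <- function(sp, pdel_by_S) {
  if (length(pdel_by_S) != sp$P + 1)
    stop("pdel_by_S must have length P + 1 (states S = 0..P)")
  if (any(!is.finite(pdel_by_S[-1])) || any(pdel_by_S[-1] <= 0) ||
      any(pdel_by_S[-1] >= 1))
    stop("deletion probabilities for S = 1..P must lie in (0,1)")
  invisible(TRUE)
}

#' Exact one-step transition matrix of the synapse-count chain
#'
#' Entry `(k, l)` (1-based indices for states `k-1`, `l-1`) is the probability
#' to move from `l` to `k` synapses in one step: each of the `l` realised
#' synapses is removed independently with probability `pdel_by_S[l+1]`, and
#' each of the `P - l` sites that were vacant at the start of the step builds
#' independently with `p_build`. The matrix is column-stochastic and strictly
#' positive for probabilities in (0,1).
#'
#' @param sp [structural_params()].
#' @param pdel_by_S deletion probability per state, length `P + 1` (the
#'   `S = 0` entry is unused).
#' @return a `(P+1) x (P+1)` matrix of class `transition_matrix`.
#' @export
build_transition_matrix <- function(sp, pdel_by_S) {
  check_pdel(sp, pdel_by_S)
  P <- sp$P
  M <- matrix(0, P + 1, P + 1)
  for (l in 0:P) {
    # distribution of k = (l - X) + B, X ~ Bin(l, pdel_l), B ~ Bin(P-l, p_build)
    pd <- if (l > 0) pdel_by_S[l + 1] else 0
    p_rm <- stats::dbinom(0:l, l, pd)              # X = 0..l
    p_bl <- stats::dbinom(0:(P - l), P - l, sp$p_build)
    col <- numeric(P + 1)
    for (x in 0:l) {
      ks <- (l - x) + 0:(P - l)
      col[ks + 1] <- col[ks + 1] + p_rm[x + 1] * p_bl
    }
    M[, l + 1] <- col
  }
  dimnames(M) <- list(paste0("S", 0:P), paste0("S", 0:P))
  class(M) <- c("transition_matrix", "matrix")
  M
}

#' Stationary distribution from the transition matrix
#'
#' Solves \eqn{Mp = p} with \eqn{\sum_S p[S] = 1} by direct linear solve of
#' the singular system (one balance row replaced by the normalisation). The
#' chain is strictly positive under the model assumptions, so the stationary
#' distribution exists and is unique.
#'
#' @param M a column-stochastic matrix (class `transition_matrix` or plain).
#' @return [synapse_distribution] over `S = 0..P`.
#' @export
stationary_from_matrix <- function(M) {
  M <- unclass(M)
  n <- nrow(M)
  if (any(abs(colSums(M) - 1) > 1e-9) || any(M < 0))
    stop("stationary_from_matrix: input is not column-stochastic")
  A <- diag(n) - M
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  p <- tryCatch(solve(A, b), error = function(e) {
    ev <- eigen(M)                     # fallback for near-singular solves
    v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
    v / sum(v)
  })
  if (any(p < -1e-10)) stop("stationary_from_matrix: negative probabilities")
  p <- pmax(p, 0); p <- p / sum(p)
  res <- max(abs(M %*% p - p))
  if (res > 1e-10)
    stop(sprintf("stationary_from_matrix: residual %.3g above 1e-10", res))
  synapse_distribution(p, method = "matrix")
}

#' Synapse-count distributions
#'
#' A probability vector over `S = 0..P`, the central analysis object. Entries
#' are nonnegative and sum to one (enforced to 1e-12).
#'
#' @param p probabilities over `S = 0..P`.
#' @param log_p optional log-probabilities (kept as attribute; useful because
#'   equilibrium probabilities span hundreds of orders of magnitude).
#' @param method provenance tag.
#' @export
synapse_distribution <- function(p, log_p = NULL, method = "unspecified") {
  stopifnot(is.numeric(p), all(is.finite(p)), all(p >= 0))
  s <- sum(p)
  if (abs(s - 1) > 1e-9) stop("synapse_distribution: probabilities must sum to 1")
  p <- p / s
  structure(as.numeric(p), names = paste0("S", seq_along(p) - 1),
            log_p = log_p, method = method, class = "synapse_distribution")
}

#' @export
print.synapse_distribution <- function(x, ...) {
  cat(sprintf("<synapse_distribution> P = %d (%s)\n", length(x) - 1,
              attr(x, "method")))
  print(signif(unclass(x), 4))
  invisible(x)
}

#' Total variation distance between two distributions on 0..P
#'
#' Shorter vectors are zero-padded.
#' @param p,q probability vectors.
#' @export
tv_distance <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(unclass(p), rep(0, n - length(p)))
  q <- c(unclass(q), rep(0, n - length(q)))
  sum(abs(p - q)) / 2
}

#' First-step (detailed-balance) stationary distribution
#'
#' Restricting the chain to one structural change per step makes it a
#' birth-death chain in detailed balance, giving the closed recursion
#' \deqn{p[S] = p[0]\binom{P}{S} p_{build}^S \prod_{\hat S = 1}^{S} p_{del,\hat S}^{-1}}
#' normalised so the probabilities sum to one. All arithmetic is in log-space
#' because the unnormalised terms span `~ e^(16 P)` scales at the reference
#' parameters.
#'
#' @inheritParams build_transition_matrix
#' @return [synapse_distribution] with the log-probabilities attached.
#' @export
first_step_distribution <- function(sp, pdel_by_S) {
  check_pdel(sp, pdel_by_S)
  P <- sp$P
  S <- 0:P
  lp <- lchoose(P, S) + S * log(sp$p_build) -
    c(0, cumsum(log(pdel_by_S[2:(P + 1)])))
  lp <- lp - max(lp)
  p <- exp(lp)
  p <- p / sum(p)
  synapse_distribution(p, log_p = lp - log(sum(exp(lp))), method = "first_step")
}

#' Discrete log-derivative of the equilibrium distribution
#'
#' \deqn{\Delta_{\ln p}[S] = \ln p_{build} + \ln\frac{P-S+1}{S} - \ln p_{del,S}}
#' for `S = 1..P`; equals `ln(p[S]/p[S-1])` of the first-step distribution and
#' behaves like a discrete derivative of `ln p[S]`. Its zero crossings locate
#' the extrema of the distribution.
#'
#' @inheritParams build_transition_matrix
#' @return numeric vector indexed by `S = 1..P`.
#' @export
delta_ln_p <- function(sp, pdel_by_S) {
  check_pdel(sp, pdel_by_S)
  P <- sp$P
  S <- 1:P
  out <- log(sp$p_build) + log((P - S + 1) / S) - log(pdel_by_S[S + 1])
  names(out) <- paste0("S", S)
  out
}

#' Classify the shape of an equilibrium distribution
#'
#' The sign pattern of \eqn{\Delta_{\ln p}} determines the number and
#' arrangement of the distribution's extrema; with at most two sign changes
#' there are six qualitative cases:
#'
#' | case | crossings | signs  | shape |
#' |------|-----------|--------|-------|
#' | 1    | 0         | +      | one maximum at the upper boundary (P) |
#' | 2    | 0         | -      | one maximum at the lower boundary (0) |
#' | 3    | 1         | + -    | maximum at the sign change (attractive) |
#' | 4    | 1         | - +    | maxima at both boundaries, repulsive point between |
#' | 5    | 2         | + - +  | maxima at the first sign change and at P |
#' | 6    | 2         | - + -  | maxima at 0 and at the second sign change |
#'
#' Case 6 is the experimentally observed bimodal connectivity. Exact zeros of
#' `delta` are counted as crossings at that state, with the maximum assigned
#' to the larger-probability neighbour.
#'
#' @param delta \eqn{\Delta_{\ln p}} values for `S = 1..P` (see
#'   [delta_ln_p()]), or a `synapse_distribution` whose log-ratios are used.
#' @return object of class `case_result` with fields `case` (1-6 or NA for
#'   patterns with more than two crossings), `crossings` (states after which
#'   the sign changes), `maxima`, `sign_pattern`, `degenerate`.
#' @export
classify_case <- function(delta) {
  if (inherits(delta, "synapse_distribution")) {
    lp <- attr(delta, "log_p")
    delta <- if (!is.null(lp)) diff(lp) else diff(log(pmax(unclass(delta), 1e-300)))
  }
  P <- length(delta)
  s <- sign(unname(delta))
  if (all(s == 0))
    return(structure(list(case = NA_integer_, degenerate = TRUE,
                          crossings = integer(0), maxima = integer(0),
                          sign_pattern = s), class = "case_result"))
  nz <- which(s != 0)
  runs <- rle(s[nz])$values
  n_cross <- length(runs) - 1
  # crossing position: the last state S (1-based over delta) before the sign flips
  flip_at <- nz[cumsum(rle(s[nz])$lengths)[-length(runs)]]
  case <- if (n_cross == 0) {
    if (runs[1] > 0) 1L else 2L
  } else if (n_cross == 1) {
    if (runs[1] > 0) 3L else 4L
  } else if (n_cross == 2) {
    if (runs[1] > 0) 5L else 6L
  } else NA_integer_
  maxima <- switch(as.character(case),
    "1" = P,
    "2" = 0L,
    "3" = flip_at[1],
    "4" = c(0L, P),
    "5" = c(flip_at[1], P),
    "6" = c(0L, flip_at[2]),
    integer(0))
  structure(list(case = case, degenerate = FALSE, crossings = flip_at,
                 maxima = maxima, sign_pattern = s, n_crossings = n_cross),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  if (x$degenerate) { cat("<case_result> degenerate (all-zero delta)\n"); return(invisible(x)) }
  cat(sprintf("<case_result> case %s; %d sign change(s); maxima at S = {%s}\n",
              ifelse(is.na(x$case), "beyond 6-case taxonomy", x$case),
              x$n_crossings, paste(x$maxima, collapse = ", ")))
  invisible(x)
}

#' Combinatorial and deletion terms as functions of postsynaptic activity
#'
#' Rewrites the zero-crossing condition of \eqn{\Delta_{\ln p}} as the
#' intersection of two curves over the continuous postsynaptic activity:
#' \deqn{p_{cf}(v) = -\ln p_{build} - \ln\frac{P - S(v) + 1}{S(v)}, \qquad
#'       p_d(v) = -\ln p_{del}(w^*(v)),}
#' where `S(v)` inverts the strictly increasing activity profile (monotone
#' spline interpolation; the combinatorial factor is continued to real `S`).
#' Intersections of the two curves coincide with the zero crossings of the
#' discrete \eqn{\Delta_{\ln p}}; the number and order of intersections gives
#' the distribution's case.
#'
#' @param sp [structural_params()].
#' @param profile an [activity_profile()] with strictly increasing `v_i_star`.
#' @return list with functions `p_cf(v)`, `p_d(v)`, `S_of_v(v)`, the activity
#'   interval `v_range` covering `S = 1..P`, and `intersections` (activities
#'   where the curves cross).
#' @export
pcf_pd_curves <- function(sp, profile) {
  if (!profile$monotone)
    stop("pcf_pd_curves: activity profile is not strictly increasing, cannot invert")
  v <- profile$v_i_star
  S <- profile$S
  S_of_v <- stats::splinefun(v, S, method = "hyman")
  w_of_v <- stats::splinefun(v[-1], profile$w_star[-1], method = "monoH.FC")
  p_cf <- function(vv) {
    Sv <- pmin(pmax(S_of_v(vv), 1e-9), sp$P + 1 - 1e-9)
    -log(sp$p_build) - log((sp$P - Sv + 1) / Sv)
  }
  p_d <- function(vv) -log(deletion_prob(sp, pmax(w_of_v(vv), 0)))
  v_range <- c(v[2], v[length(v)])
  grid <- seq(v_range[1], v_range[2], length.out = 2000)
  d <- p_cf(grid) - p_d(grid)
  idx <- which(d[-1] * d[-length(d)] < 0)
  inter <- vapply(idx, function(i)
    stats::uniroot(function(x) p_cf(x) - p_d(x), grid[c(i, i + 1)],
                   tol = 1e-12)$root, numeric(1))
  list(p_cf = p_cf, p_d = p_d, S_of_v = S_of_v, v_range = v_range,
       intersections = inter)
}

#' Continuous-synapse fixed points of the structural flow
#'
#' Treating the synapse count as continuous, the net probability flow is
#' \deqn{h(S) = (P - S)\, p_{build} - S\, p_{del}(w^*(S)),} whose roots are
#' the fixed points of the structural dynamics. Roots where the flow changes
#' from positive to negative are stable (attractors); stable roots below one
#' synapse are flagged as the effective `S = 0` attractor, and pairs of roots
#' closer than one synapse are flagged as unresolvable by the discrete chain.
#'
#' @inheritParams consistent_state
#' @param sp [structural_params()].
#' @param n_grid resolution of the scan over `S`.
#' @return data.frame with columns `S`, `stable`, `effectively_zero`,
#'   `merged`; attribute `bistable` is TRUE when at least two stable roots are
#'   separated by an unstable one.
#' @export
continuous_fixed_points <- function(sp, rule, io, point, fb = feedforward(),
                                    n_grid = 201) {
  P <- sp$P
  wS <- function(S) {
    vapply(S, function(s) {
      st <- try(consistent_state(s, point, rule, io, fb), silent = TRUE)
      if (inherits(st, "try-error")) NA_real_
      else if (s == 0) 0 else st$w_star
    }, numeric(1))
  }
  h <- function(S) (P - S) * sp$p_build - S * deletion_prob(sp, pmax(wS(S), 0))
  Sg <- seq(0, P, length.out = n_grid)
  hg <- h(Sg)
  ok <- is.finite(hg)
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1)) {
    if (ok[i] && ok[i + 1] && hg[i] * hg[i + 1] < 0)
      roots <- c(roots, stats::uniroot(h, Sg[c(i, i + 1)], tol = 1e-10)$root)
  }
  stable <- vapply(roots, function(r) {
    d <- min(0.01, P * 1e-3)
    h(max(r - d, 0)) > 0 && h(min(r + d, P)) < 0
  }, logical(1))
  # boundary attractors: flow pointing into a boundary
  if (length(hg) && is.finite(hg[1]) && hg[1] <= 0) { roots <- c(0, roots); stable <- c(TRUE, stable) }
  if (is.finite(hg[n_grid]) && hg[n_grid] >= 0) { roots <- c(roots, P); stable <- c(stable, TRUE) }
  ord <- order(roots)
  roots <- roots[ord]; stable <- stable[ord]
  merged <- rep(FALSE, length(roots))
  if (length(roots) > 1) {
    close <- which(diff(roots) < 1)
    merged[close] <- TRUE; merged[close + 1] <- TRUE
  }
  out <- data.frame(S = roots, stable = stable,
                    effectively_zero = stable & roots < 1, merged = merged)
  attr(out, "bistable") <- sum(stable) >= 2 && any(!stable) &&
    (max(roots[stable]) - min(roots[stable]) >= 1)
  out
}

#' Fixed-point diagram along a stimulation sweep
#'
#' Sweeps either the postsynaptic stimulation (parameterised by the rate at
#' zero synapses, `v_i(S=0)`) or the presynaptic activity and records the
#' continuous-synapse fixed points at every level, yielding the bifurcation
#' diagram of the connection.
#'
#' @param sp,rule,io,fb model components.
#' @param levels stimulation levels in (0,1).
#' @param vary `"post"` (levels are `v_i(S=0)`, presynaptic rate fixed at
#'   `v_j`) or `"pre"` (levels are `v_j`, influence fixed at `I`).
#' @param v_j,I the value of the non-varied side.
#' @return object of class `fixed_point_diagram`: list of per-level root
#'   tables plus a `bistable` logical vector and the detected `bistable_band`
#'   (range of levels with coexisting attractors).
#' @export
fixed_point_diagram <- function(sp, rule, io, fb = feedforward(),
                                levels, vary = c("post", "pre"),
                                v_j = NULL, I = NULL, n_grid = 151) {
  vary <- match.arg(vary)
  res <- lapply(levels, function(lv) {
    point <- if (vary == "post")
      system_point(v_j = v_j, v_i_S0 = lv, io = io)
    else system_point(v_j = lv, I = I, io = io)
    tryCatch(continuous_fixed_points(sp, rule, io, point, fb, n_grid = n_grid),
             error = function(e) NULL)
  })
  bist <- vapply(res, function(r) !is.null(r) && isTRUE(attr(r, "bistable")),
                 logical(1))
  band <- if (any(bist)) range(levels[bist]) else c(NA_real_, NA_real_)
  structure(list(levels = levels, vary = vary, roots = res, bistable = bist,
                 bistable_band = band),
            class = "fixed_point_diagram")
}

#' @export
print.fixed_point_diagram <- function(x, ...) {
  cat(sprintf("<fixed_point_diagram> %s sweep, %d levels; bistable at %d levels",
              x$vary, length(x$levels), sum(x$bistable)))
  if (any(x$bistable))
    cat(sprintf(" (band %.3g - %.3g)", x$bistable_band[1], x$bistable_band[2]))
  cat("\n")
  invisible(x)
}
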