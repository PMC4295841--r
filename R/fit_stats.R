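#' Experimental synapse-count histograms
#'
#' Sparse relative-frequency histograms of the number of synapses per
#' connected pair, together with the number of sampled pairs `N_exp` (which
#' experimental studies sometimes only report indirectly, as the number of
#' connected pairs divided by the connection probability).
#'
#' @param S synapse counts (nonnegative integers).
#' @param freq relative frequencies (or counts; normalised with a warning
#'   unless they already sum to 1 within 1e-9).
#' @param N_exp number of sampled neuron pairs (>= 1).
#' @param normalize if `FALSE`, non-normalised frequencies are an error
#'   instead of a warning ("strict" mode).
#' @return object of class `experiment_data`: probability vector over
#'   `S = 0..max(S)` plus `N_exp`.
#' @export
experiment_data <- function(S, freq, N_exp, normalize = TRUE) {
  stopifnot(length(S) == length(freq), N_exp >= 1)
  if (any(S < 0) || any(S != round(S))) stop("S must be nonnegative integers")
  if (any(freq < 0)) stop("negative frequencies")
  if (any(duplicated(S))) stop("duplicated S values")
  tot <- sum(freq)
  if (abs(tot - 1) > 1e-9) {
    if (!normalize)
      stop(sprintf("frequencies sum to %.6g, not 1 (strict mode)", tot))
    if (abs(tot - round(tot)) > 1e-9 || tot < 1)
      warning(sprintf("frequencies sum to %.6g; normalising", tot))
    freq <- freq / tot
  }
  p <- numeric(max(S) + 1)
  p[S + 1] <- freq
  structure(list(p = p, N_exp = as.integer(N_exp)), class = "experiment_data")
}

#' @export
print.experiment_data <- function(x, ...) {
  cat(sprintf("<experiment_data> N_exp = %d, support 0..%d, p[0] = %.3g\n",
              x$N_exp, length(x$p) - 1, x$p[1]))
  invisible(x)
}

#' Squared error between two synapse-count distributions
#'
#' \eqn{SE = \sum_S (p[S] - p_{sample}[S])^2}; shorter supports are padded
#' with zeros.
#'
#' @param p_model,p_sample probability vectors (any of the distribution
#'   classes or plain numeric).
#' @export
squared_error <- function(p_model, p_sample) {
  p <- if (inherits(p_model, "experiment_data")) p_model$p else unclass(p_model)
  q <- if (inherits(p_sample, "experiment_data")) p_sample$p else unclass(p_sample)
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  sum((p - q)^2)
}

#' Monte-Carlo p-value for a sparse histogram against a model distribution
#'
#' The sparse experimental histograms defeat standard tests, so the model is
#' tested by resampling: draw `n_mc` histograms of `N_exp` samples from the
#' model distribution, compute their squared errors against the model, and
#' report the fraction with an error at least as large as the experimental
#' one. Ties are counted as "larger or equal" (conservative); the strict
#' "larger" count is also reported.
#'
#' @param p_model model [synapse_distribution] (or numeric probabilities).
#' @param experiment [experiment_data()].
#' @param n_mc number of resampling repetitions (reference value 1000).
#' @param seed optional RNG seed.
#' @return list with `p` (conservative, ties included), `p_strict`, `se_exp`,
#'   `n_mc`.
#' @export
mc_pvalue <- function(p_model, experiment, n_mc = 1000, seed = NULL) {
  stopifnot(inherits(experiment, "experiment_data"), n_mc >= 100)
  if (!is.null(seed)) set.seed(seed)
  pm <- unclass(p_model)
  n <- max(length(pm), length(experiment$p))
  pm <- c(pm, rep(0, n - length(pm)))
  pe <- c(experiment$p, rep(0, n - length(experiment$p)))
  se_exp <- sum((pm - pe)^2)
  draws <- stats::rmultinom(n_mc, experiment$N_exp, pm) / experiment$N_exp
  se_rand <- colSums((draws - pm)^2)
  list(p = mean(se_rand >= se_exp), p_strict = mean(se_rand > se_exp),
       se_exp = se_exp, n_mc = n_mc)
}

#' Confidence region over the activity plane
#'
#' Scans a grid of (presynaptic activity, postsynaptic stimulation) cells;
#' at each cell the equilibrium first-step distribution of the model is
#' computed and compared to the experimental histogram with [mc_pvalue()].
#' The 95% confidence region is the set of cells with p-value above 0.05 —
#' the activities at which the model can account for the data. The
#' postsynaptic axis is parameterised by the rate at zero synapses,
#' `v_i(S=0) = F(I)`.
#'
#' Cells where the self-consistent profile fails (domain errors of the rule,
#' non-monotone profiles are fine) get `NA` and are excluded from the
#' summaries; the evaluable fraction is reported.
#'
#' @param v_j_grid,v_i0_grid grid axes in (0,1).
#' @param sp,rule,io,fb model components.
#' @param experiment [experiment_data()].
#' @param n_mc Monte-Carlo repetitions per cell.
#' @param seed master seed; per-cell streams are derived deterministically
#'   from it so the scan is reproducible cell by cell.
#' @return object of class `confidence_region`: list with the grids, matrices
#'   `p` and `E_vi` (rows: `v_j`, cols: `v_i0`), logical `mask` (p > 0.05),
#'   and `summary` (area fraction, mean presynaptic activity and mean
#'   postsynaptic stimulation over the mask, coverage).
#' @export
scan_confidence_region <- function(v_j_grid, v_i0_grid, sp, rule, io,
                                   experiment, fb = feedforward(),
                                   n_mc = 1000, seed = 1) {
  np <- length(v_j_grid); nq <- length(v_i0_grid)
  pmat <- matrix(NA_real_, np, nq, dimnames = list(NULL, NULL))
  emat <- matrix(NA_real_, np, nq)
  for (i in seq_len(np)) for (j in seq_len(nq)) {
    cell_seed <- (seed * 7919L + i * 1009L + j) %% .Machine$integer.max
    res <- tryCatch({
      point <- system_point(v_j = v_j_grid[i], v_i_S0 = v_i0_grid[j], io = io)
      prof <- activity_profile(sp$P, point, rule, io, fb)
      dist <- first_step_distribution(sp, pdel_profile(sp, prof))
      list(p = mc_pvalue(dist, experiment, n_mc = n_mc, seed = cell_seed)$p,
           E = sum(unclass(dist) * prof$v_i_star))
    }, error = function(e) NULL)
    if (!is.null(res)) { pmat[i, j] <- res$p; emat[i, j] <- res$E }
  }
  mask <- !is.na(pmat) & pmat > 0.05
  vj_m <- matrix(v_j_grid, np, nq, byrow = FALSE)
  vi_m <- matrix(v_i0_grid, np, nq, byrow = TRUE)
  summ <- list(area = mean(mask),
               mean_pre = if (any(mask)) mean(vj_m[mask]) else NA_real_,
               mean_post = if (any(mask)) mean(vi_m[mask]) else NA_real_,
               coverage = mean(!is.na(pmat)))
  structure(list(v_j_grid = v_j_grid, v_i0_grid = v_i0_grid, p = pmat,
                 E_vi = emat, mask = mask, summary = summ,
                 experiment = experiment),
            class = "confidence_region")
}

#' @export
print.confidence_region <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<confidence_region> %dx%d grid; area %.3f, mean v_j %.3f,",
                     " mean v_i(S=0) %.3f (coverage %.0f%%)\n"),
              length(x$v_j_grid), length(x$v_i0_grid), s$area,
              s$mean_pre, s$mean_post, 100 * s$coverage))
  invisible(x)
}

#' Prior over the number of potential synapses
#'
#' @param P_values integer support (e.g. `1:20`).
#' @param probs probabilities (normalised).
#' @export
p_prior <- function(P_values, probs) {
  stopifnot(length(P_values) == length(probs), all(probs >= 0),
            all(P_values >= 1), all(P_values == round(P_values)))
  probs <- probs / sum(probs)
  structure(list(P = as.integer(P_values), prob = probs), class = "p_prior")
}

#' @rdname p_prior
#' @details `default_p_prior()` loads the synthetic prior shipped with the
#'   package (`inst/extdata/p_prior_synthetic.tsv`): a unimodal bump over
#'   `P = 1..20` with most mass below 12, emulating the shape of
#'   morphology-based estimates. It is a labelled stand-in, not ground truth.
#' @export
default_p_prior <- function() {
  path <- system.file("extdata", "p_prior_synthetic.tsv",
                      package = "structplast")
  df <- read_tsv_with_header(path)
  p_prior(df$P, df$prob)
}

#' Mixture of equilibrium distributions over potential-synapse counts
#'
#' When the number of potential synapses is itself distributed (as estimated
#' from reconstructed morphologies), the observable synapse-count
#' distribution is the prior-weighted sum of the per-`P` equilibria,
#' zero-padded to the largest support.
#'
#' @param prior a [p_prior()].
#' @param dists named or ordered list of [synapse_distribution]s, one per `P`
#'   in the prior's support.
#' @export
mixture_over_P <- function(prior, dists) {
  stopifnot(inherits(prior, "p_prior"))
  if (length(dists) != length(prior$P))
    stop("need one component distribution per P with prior mass")
  n <- max(vapply(dists, length, integer(1)))
  acc <- numeric(n)
  for (k in seq_along(dists)) {
    p <- unclass(dists[[k]])
    if (length(p) != prior$P[k] + 1)
      stop(sprintf("component %d has support 0..%d but P = %d", k,
                   length(p) - 1, prior$P[k]))
    acc[seq_along(p)] <- acc[seq_along(p)] + prior$prob[k] * p
  }
  synapse_distribution(acc, method = "mixture_over_P")
}

#' Activity estimates from a confidence region
#'
#' For intra-layer connections the pre- and postsynaptic rates should be
#' equal, so the physiological activity is estimated as the intersection of
#' the confidence region with the `v_i = v_j` cline. Two clines are used:
#' the baseline postsynaptic rate at zero synapses, and the expected
#' postsynaptic rate \eqn{E[v_i] = \sum_S p[S] v_i^*[S]} under the
#' equilibrium distribution (stored per cell during the scan).
#'
#' @param region a [scan_confidence_region()] result.
#' @return list with data.frames `baseline_cline` and `expected_cline`
#'   (cells of the region crossing each cline) and the mean activity on each
#'   intersection (`NA` when empty).
#' @export
cline_and_expectation <- function(region) {
  vj <- region$v_j_grid; vi0 <- region$v_i0_grid
  dv <- if (length(vi0) > 1) max(diff(vi0)) else 0.05
  cells <- which(region$mask, arr.ind = TRUE)
  if (!nrow(cells)) {
    empty <- data.frame(v_j = numeric(0), v_i0 = numeric(0))
    return(list(baseline_cline = empty, expected_cline = empty,
                baseline_activity = NA_real_, expected_activity = NA_real_))
  }
  df <- data.frame(v_j = vj[cells[, 1]], v_i0 = vi0[cells[, 2]],
                   E_vi = region$E_vi[region$mask])
  base <- df[abs(df$v_i0 - df$v_j) <= dv / 2 + 1e-12, c("v_j", "v_i0")]
  expd <- df[!is.na(df$E_vi) & abs(df$E_vi - df$v_j) <= dv / 2 + 1e-12,
             c("v_j", "v_i0")]
  list(baseline_cline = base, expected_cline = expd,
       baseline_activity = if (nrow(base)) mean(base$v_j) else NA_real_,
       expected_activity = if (nrow(expd)) mean(expd$v_j) else NA_real_)
}
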