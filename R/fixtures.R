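#' Synthetic experiment-like synapse-count histograms
#'
#' The published synapse-count histograms are figure-level data without
#' printed values; this generator emulates their common shape: a large point
#' mass at zero synapses (unconnected pairs, 0.75-0.99 of the probability)
#' plus a unimodal peak at 3-8 synapses, sampled at the small pair counts
#' (10-50) typical of paired recordings. Both the ground-truth distribution
#' and a finite sample are returned; anything built from this generator is
#' synthetic stand-in data, not a published dataset.
#'
#' @param zero_mass probability of zero synapses.
#' @param center,spread location (in synapses) and width of the connected
#'   peak, discretised from a Gaussian profile on `1..P_max`.
#' @param N_exp number of sampled pairs.
#' @param P_max largest representable synapse count.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(zero_mass = 0.9, center = 5, spread = 1.2,
                         N_exp = 30, P_max = 12) {
  stopifnot(zero_mass >= 0, zero_mass <= 1, center >= 1, center <= P_max,
            spread > 0, N_exp >= 1, P_max >= 1)
  structure(list(zero_mass = zero_mass, center = center, spread = spread,
                 N_exp = as.integer(N_exp), P_max = as.integer(P_max)),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @param spec a [fixture_spec()].
#' @param seed optional RNG seed for the sampling step.
#' @return for `generate_fixture()`: list with `truth` (the ground-truth
#'   [synapse_distribution]) and `sample` (an [experiment_data()] of `N_exp`
#'   draws from it).
#' @export
generate_fixture <- function(spec = fixture_spec(), seed = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(seed)) set.seed(seed)
  S <- 0:spec$P_max
  bump <- exp(-(1:spec$P_max - spec$center)^2 / (2 * spec$spread^2))
  p <- c(spec$zero_mass, (1 - spec$zero_mass) * bump / sum(bump))
  truth <- synapse_distribution(p, log_p = log(pmax(p, 1e-300)),
                                method = "fixture_truth")
  counts <- as.vector(stats::rmultinom(1, spec$N_exp, p))
  sample <- experiment_data(S, counts / spec$N_exp, N_exp = spec$N_exp)
  list(truth = truth, sample = sample)
}
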