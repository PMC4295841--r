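#' Neuronal input-output curves
#'
#' An IO curve maps the total input current of a neuron to its firing rate.
#' [logistic_io()] gives the dimensionless analytic curve
#' \eqn{F(x) = 1/(1+e^{-x})} with rates in (0,1); [empirical_io()] wraps a
#' sampled curve (e.g. a simulated f-I relation in pA / Hz) with piecewise
#' linear interpolation.
#'
#' @param x,y strictly increasing abscissa (current) and ordinate (rate)
#'   samples for the empirical curve.
#' @param units optional two-element character vector naming the input and
#'   output units, kept as metadata only.
#' @return an object of class `io_curve` with elements `forward` (current ->
#'   rate), `inverse` (rate -> current) and `domain`.
#' @examples
#' io <- logistic_io()
#' io$forward(0)            # 0.5
#' io$inverse(io$forward(1.7))
#' @export
logistic_io <- function() {
  structure(list(
    kind = "logistic",
    forward = function(x) stats::plogis(x),
    inverse = function(p) {
      if (any(p <= 0 | p >= 1)) stop("logistic inverse requires rates in (0,1)")
      stats::qlogis(p)
    },
    domain = c(-Inf, Inf),
    range = c(0, 1),
    units = c(input = "dimensionless", output = "dimensionless")
  ), class = "io_curve")
}

#' @rdname logistic_io
#' @export
empirical_io <- function(x, y, units = c(input = "pA", output = "Hz")) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (any(diff(x) <= 0)) stop("empirical IO curve abscissa must be strictly increasing")
  if (any(diff(y) <= 0)) stop("empirical IO curve must be strictly increasing (forward invertible)")
  fwd <- stats::approxfun(x, y, rule = 2)
  inv <- stats::approxfun(y, x, rule = 2)
  structure(list(
    kind = "empirical",
    forward = fwd,
    inverse = inv,
    domain = range(x),
    range = range(y),
    units = units
  ), class = "io_curve")
}

#' @export
print.io_curve <- function(x, ...) {
  cat("<io_curve>", x$kind, "\n")
  if (x$kind == "empirical")
    cat("  domain:", format(x$domain[1]), "-", format(x$domain[2]), x$units[["input"]],
        " range:", format(x$range[1]), "-", format(x$range[2]), x$units[["output"]], "\n")
  invisible(x)
}

#' Presynaptic feedback specification
#'
#' When the plastic connection is embedded in a recurrent circuit, the
#' presynaptic rate can be approximated as a linear function of the
#' postsynaptic rate, \eqn{v_j = r_0 + r_1 v_i}. The feed-forward system has
#' `r1 = 0` (the presynaptic rate is an external constant); the linear
#' feedback system has `r0 = 0, r1 = 1` so that \eqn{v_j = v_i}.
#'
#' @param r0 rate offset.
#' @param r1 slope of the presynaptic rate in the postsynaptic rate.
#' @return object of class `feedback_spec`.
#' @examples
#' feedforward()
#' linear_feedback()
#' @export
feedback_spec <- function(r0 = 0, r1 = 0) {
  stopifnot(is.numeric(r0), is.numeric(r1), length(r0) == 1, length(r1) == 1)
  # resulting v_j must stay a rate on the configured postsynaptic range [0,1]
  vj_ends <- r0 + r1 * c(0, 1)
  if (r1 != 0 && (min(vj_ends) < 0 || max(vj_ends) > 1))
    stop("feedback spec maps some v_i in [0,1] outside [0,1]")
  structure(list(r0 = r0, r1 = r1), class = "feedback_spec")
}

#' @rdname feedback_spec
#' @export
feedforward <- function() feedback_spec(r0 = 0, r1 = 0)

#' @rdname feedback_spec
#' @export
linear_feedback <- function() feedback_spec(r0 = 0, r1 = 1)

is_feedforward <- function(fb) fb$r1 == 0

# presynaptic rate seen by the connection; in the feed-forward system this is
# the externally supplied v_j from the system point, otherwise r0 + r1 * v_i
presyn_rate <- function(fb, v_i, v_j_external) {
  if (is_feedforward(fb)) rep(v_j_external, length.out = length(v_i))
  else fb$r0 + fb$r1 * v_i
}

#' External drive of the two-neuron system
#'
#' Bundles the presynaptic activity `v_j` and the postsynaptic external
#' influence `I` (leak, inhibition, input from other areas). `I` may be given
#' directly or implicitly as the postsynaptic rate at zero synapses,
#' `v_i_S0 = F(I)`, which is the parameterisation used for activity maps.
#'
#' @param v_j presynaptic rate in (0,1) (ignored by the self-consistency loop
#'   when a feedback system with `r1 != 0` is used).
#' @param I postsynaptic external influence (current). Give either `I` or
#'   `v_i_S0`.
#' @param v_i_S0 postsynaptic rate at `S = 0`, converted through `io$inverse`.
#' @param io the [io_curve] used for the conversion (default logistic).
#' @return object of class `system_point` with fields `v_j`, `I`, `v_i_S0`.
#' @export
system_point <- function(v_j, I = NULL, v_i_S0 = NULL, io = logistic_io()) {
  stopifnot(is.numeric(v_j), length(v_j) == 1, v_j >= 0, v_j <= 1)
  if (is.null(I) == is.null(v_i_S0))
    stop("give exactly one of I or v_i_S0")
  if (is.null(I)) {
    if (v_i_S0 <= 0 || v_i_S0 >= 1) stop("v_i_S0 must lie in (0,1)")
    I <- io$inverse(v_i_S0)
  } else {
    v_i_S0 <- io$forward(I)
  }
  structure(list(v_j = v_j, I = I, v_i_S0 = v_i_S0), class = "system_point")
}

#' @export
print.system_point <- function(x, ...) {
  cat(sprintf("<system_point> v_j = %.4g, I = %.4g (v_i at S=0: %.4g)\n",
              x$v_j, x$I, x$v_i_S0))
  invisible(x)
}
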