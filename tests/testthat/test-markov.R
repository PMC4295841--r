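test_that("deletion probability has the right limits and monotonicity", {
  sp <- ref_sp()
  expect_equal(deletion_prob(sp, 0), sp$p_build^sp$rho)
  expect_true(deletion_prob(sp, 1) < deletion_prob(sp, 0.5))
  expect_error(deletion_prob(sp, -0.1), "negative")
  # quadratic-exponent variant is a parameter, not a different model
  sp2 <- structural_params(q = 2)
  expect_equal(deletion_prob(sp2, 1.5), exp(0.125 * -16 - 4 * 1.5^2))
  # a = 0 removes the weight dependence entirely
  sp0 <- structural_params(a = 0)
  expect_equal(deletion_prob(sp0, 0.2), deletion_prob(sp0, 2))
})

test_that("first-step distribution: constant-pdel closed forms", {
  # pdel = p_build: detailed-balance ratio reduces to (P-S+1)/S -> Binomial(P, 1/2)
  sp <- structural_params(p_build = 0.2, rho = 1, a = 0, P = 2)
  d <- first_step_distribution(sp, rep(0.2, 3))
  expect_equal(pvec(d), c(0.25, 0.5, 0.25))
  # P = 1, p_build = 2 pdel -> (1/3, 2/3)
  sp1 <- structural_params(p_build = 0.4, rho = 1, a = 0, P = 1)
  d1 <- first_step_distribution(sp1, c(NA, 0.2))
  expect_equal(pvec(d1), c(1 / 3, 2 / 3))
})

test_that("weight-independent pdel gives the Binomial closed form exactly", {
  set.seed(5)
  for (rep in 1:10) {
    P <- sample(1:20, 1)
    pb <- runif(1, 0.01, 0.6)
    pd <- runif(1, 0.01, 0.6)
    sp <- structural_params(p_build = pb, rho = 1, a = 0, P = P)
    d <- first_step_distribution(sp, rep(pd, P + 1))
    expect_equal(pvec(d), dbinom(0:P, P, pb / (pb + pd)),
                 tolerance = 1e-12)
  }
})

test_that("first-step distribution satisfies detailed balance to 1e-12", {
  set.seed(17)
  for (rep in 1:200) {
    P <- sample(2:15, 1)
    sp <- structural_params(p_build = exp(runif(1, -18, -0.7)),
                            rho = runif(1, 0.05, 1.5), a = runif(1, 0, 3),
                            P = P)
    pdel <- exp(runif(P + 1, -17, -0.1))
    d <- first_step_distribution(sp, pdel)
    lp <- attr(d, "log_p")
    S <- 1:P
    lhs <- lp[S] + log(P - S + 1) + log(sp$p_build)
    rhs <- lp[S + 1] + log(S) + log(pdel[S + 1])
    expect_true(max(abs(lhs - rhs)) < 1e-12)
  }
})

test_that("delta_ln_p is the log-ratio of the first-step distribution", {
  sp <- ref_sp()
  pdel <- pdel_profile(sp, ref_profile())
  d <- first_step_distribution(sp, pdel)
  delta <- delta_ln_p(sp, pdel)
  expect_equal(unname(delta), unname(diff(attr(d, "log_p"))),
               tolerance = 1e-12)
  # reference sign pattern: (-, +, ..., -) = case 6
  expect_true(delta[1] < 0)
  expect_true(any(delta[2:5] > 0))
  expect_true(delta[12] < 0)
})

test_that("transition matrix: exhaustive enumeration at P = 1", {
  sp <- structural_params(p_build = 0.3, rho = 1, a = 0, P = 1)
  pd <- 0.2
  M <- build_transition_matrix(sp, c(NA, pd))
  # from 0 synapses: build or not
  expect_equal(M[, 1], c(S0 = 0.7, S1 = 0.3))
  # from 1 synapse: only deletion possible (no vacant site at step start)
  expect_equal(M[, 2], c(S0 = pd, S1 = 1 - pd))
})

test_that("transition matrix columns are stochastic; p_build = 0 builds nothing", {
  sp <- ref_sp()
  pdel <- pdel_profile(sp, ref_profile())
  M <- build_transition_matrix(sp, pdel)
  expect_true(max(abs(colSums(M) - 1)) < 1e-12)
  expect_true(all(M > 0))
  sp0 <- structural_params(p_build = 1e-300, rho = 1e-6, a = 0, P = 4)
  M0 <- build_transition_matrix(sp0, rep(0.3, 5))
  for (l in 0:3) expect_true(all(M0[(l + 2):5, l + 1] < 1e-250))
})

test_that("transition matrix matches a Monte-Carlo one-step oracle at P = 3", {
  set.seed(23)
  P <- 3
  pb <- 0.25
  pdel <- c(NA, 0.5, 0.3, 0.15)
  sp <- structural_params(p_build = pb, rho = 1, a = 0, P = P)
  M <- build_transition_matrix(sp, pdel)
  n <- 2e5
  for (l in 1:3) {
    # simulate the printed process directly: remove among l, build among P-l
    removed <- rbinom(n, l, pdel[l + 1])
    built <- rbinom(n, P - l, pb)
    k <- l - removed + built
    emp <- tabulate(k + 1, nbins = P + 1) / n
    se <- sqrt(M[, l + 1] * (1 - M[, l + 1]) / n)
    expect_true(all(abs(emp - M[, l + 1]) < 3.5 * se + 1e-4),
                label = paste("column l =", l))
  }
})

test_that("stationary distribution: fixed point, uniform 2-state, TV to first-step", {
  # symmetric 2-state chain -> uniform
  M2 <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  expect_equal(pvec(stationary_from_matrix(M2)), c(0.5, 0.5))
  # applying M returns the stationary vector
  sp <- ref_sp()
  pdel <- pdel_profile(sp, ref_profile())
  M <- build_transition_matrix(sp, pdel)
  st <- stationary_from_matrix(M)
  expect_true(max(abs(M %*% unclass(st) - unclass(st))) < 1e-10)
  expect_error(stationary_from_matrix(matrix(c(1, 1, 0, 1), 2, 2)),
               "stochastic")
})

test_that("matrix and first-step distributions agree near the reference point", {
  set.seed(31)
  io <- ref_io()
  for (rep in 1:12) {
    sp <- structural_params(p_build = exp(-16 + runif(1, -1, 1)),
                            rho = 0.125 * runif(1, 0.9, 1.1),
                            a = 2 * runif(1, 0.9, 1.1), P = 12)
    pt <- system_point(v_j = 0.656 + runif(1, -0.05, 0.05),
                       v_i_S0 = 0.2975 + runif(1, -0.05, 0.05), io = io)
    prof <- activity_profile(sp$P, pt, ref_rule(), io)
    pdel <- pdel_profile(sp, prof)
    tv <- tv_distance(stationary_from_matrix(build_transition_matrix(sp, pdel)),
                      first_step_distribution(sp, pdel))
    expect_true(tv < 0.05, label = sprintf("draw %d: TV = %.4g", rep, tv))
  }
})

test_that("classification covers the six cases and the tie rule", {
  expect_equal(classify_case(c(1, 2, 0.5))$case, 1L)
  expect_equal(classify_case(c(-1, -2))$case, 2L)
  expect_equal(classify_case(c(1, 1, -1, -1))$case, 3L)
  expect_equal(classify_case(c(1, 1, -1, -1))$maxima, 2L)
  expect_equal(classify_case(c(-1, 1))$case, 4L)
  expect_equal(classify_case(c(1, -1, 1))$case, 5L)
  res6 <- classify_case(c(-1, 1, 1, -1, -2))
  expect_equal(res6$case, 6L)
  expect_equal(res6$maxima, c(0L, 3L))
  # exact zero between sign changes is still two crossings
  expect_equal(classify_case(c(-1, 0, 1, -1))$case, 6L)
  expect_true(classify_case(rep(0, 5))$degenerate)
  expect_true(is.na(classify_case(c(1, -1, 1, -1))$case))
})

test_that("classification of delta agrees with the distribution's extrema", {
  set.seed(11)
  for (rep in 1:300) {
    P <- sample(3:12, 1)
    sp <- structural_params(p_build = exp(runif(1, -10, -0.8)),
                            rho = runif(1, 0.1, 1.5), a = 0, P = P)
    pdel <- exp(runif(P + 1, -10, -0.05))
    delta <- delta_ln_p(sp, pdel)
    if (any(delta == 0)) next
    res <- classify_case(delta)
    p <- unclass(first_step_distribution(sp, pdel))
    if (!is.na(res$case) && length(res$maxima)) {
      # every reported maximum is a local maximum of p (boundaries included)
      for (m in res$maxima) {
        lo <- if (m > 0) p[m] <= p[m + 1] else TRUE
        hi <- if (m < P) p[m + 2] <= p[m + 1] else TRUE
        expect_true(lo && hi, label = sprintf("rep %d max at %d", rep, m))
      }
    }
  }
})

test_that("p_cf / p_d curves: monotone p_cf, intersections match crossings", {
  sp <- ref_sp()
  prof <- ref_profile()
  curves <- pcf_pd_curves(sp, prof)
  v <- seq(curves$v_range[1], curves$v_range[2], length.out = 50)
  expect_true(all(diff(curves$p_cf(v)) > 0))
  expect_equal(length(curves$intersections), 2)
  # intersections sit where the discrete delta changes sign
  delta <- delta_ln_p(sp, pdel_profile(sp, prof))
  flips <- which(diff(sign(delta)) != 0)
  for (k in seq_along(curves$intersections)) {
    vi <- curves$intersections[k]
    Si <- curves$S_of_v(vi)
    expect_true(Si > flips[k] - 1 && Si < flips[k] + 2,
                label = sprintf("intersection %d at S = %.2f", k, Si))
  }
})

test_that("constant fixed weight caps the curves at one intersection", {
  sp <- ref_sp()
  rule <- rule_spec("hebb_hard", w_max = 2.2)
  pt <- system_point(v_j = 0.656, v_i_S0 = 0.2975)
  prof <- activity_profile(sp$P, pt, rule, ref_io())
  curves <- pcf_pd_curves(sp, prof)
  expect_true(length(curves$intersections) <= 1)
})

test_that("continuous fixed points: attractor structure across stimulation", {
  sp <- ref_sp(); rule <- ref_rule(); io <- ref_io()
  # very low stimulation: single attractor at (effectively) S = 0
  fp_low <- continuous_fixed_points(sp, rule, io,
                                    system_point(v_j = 0.656, v_i_S0 = 0.05, io = io))
  expect_false(attr(fp_low, "bistable"))
  expect_true(all(fp_low$S[fp_low$stable] < 1))
  # working point: stable / unstable / stable triple
  fp <- continuous_fixed_points(sp, rule, io, ref_point())
  expect_true(attr(fp, "bistable"))
  expect_equal(sum(fp$stable), 2)
  expect_equal(sum(!fp$stable), 1)
  st <- sort(fp$S[fp$stable])
  expect_true(st[1] < 1)             # effective S = 0 attractor
  expect_true(st[2] > 3 && st[2] < 8)
  # peak/attractor correspondence: distribution maxima within 1 synapse
  d <- first_step_distribution(sp, pdel_profile(sp, ref_profile()))
  cl <- classify_case(delta_ln_p(sp, pdel_profile(sp, ref_profile())))
  expect_true(abs(cl$maxima[2] - st[2]) <= 1)
})

test_that("fixed-point diagram finds a bistable band bounded by bifurcations", {
  sp <- ref_sp(); rule <- ref_rule(); io <- ref_io()
  lv <- seq(0.05, 0.7, by = 0.05)
  dg <- fixed_point_diagram(sp, rule, io, feedforward(), lv, vary = "post",
                            v_j = 0.656, n_grid = 101)
  expect_true(any(dg$bistable))
  # monostable below and above the band
  expect_false(dg$bistable[1])
  expect_false(dg$bistable[length(lv)])
  # the band is contiguous
  r <- range(which(dg$bistable))
  expect_true(all(dg$bistable[r[1]:r[2]]))
})
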