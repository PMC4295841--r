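test_that("squared error: identities and an independent recomputation", {
  expect_equal(squared_error(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(squared_error(c(1, 0), c(0, 1)), 2)
  # different support lengths are zero-padded
  expect_equal(squared_error(c(1, 0), c(0, 0.5, 0.5)), 1 + 0.25 + 0.25)
  set.seed(3)
  p <- runif(8); p <- p / sum(p)
  q <- runif(8); q <- q / sum(q)
  expect_equal(squared_error(p, q), sum((p - q)^2))
})

test_that("experiment data validates and normalises", {
  # integer counts are normalised silently; fractional non-normalised input warns
  ex <- experiment_data(c(0, 3), c(27, 3), N_exp = 30)
  expect_equal(ex$p[1], 0.9)
  expect_warning(experiment_data(c(0, 3), c(0.5, 0.3), N_exp = 30),
                 "normalising")
  expect_error(experiment_data(c(0, 3), c(0.8, 0.3), 30, normalize = FALSE),
               "strict")
  expect_error(experiment_data(c(0, 0), c(0.5, 0.5), 30), "duplicated")
  expect_error(experiment_data(c(0, 2), c(0.9, -0.1), 30), "negative")
  # integer counts normalise silently (counts sum to N)
  ex2 <- experiment_data(c(0, 4, 5), c(24, 4, 2), N_exp = 30)
  expect_equal(sum(ex2$p), 1)
})

test_that("mc_pvalue: self test ~ 1, far point mass ~ 0, zero-bin invariance", {
  d <- ref_first_step()
  ex_self <- experiment_data(0:12, unclass(d), N_exp = 30)
  pv <- mc_pvalue(d, ex_self, n_mc = 500, seed = 2)
  expect_true(pv$p > 0.95)
  ex_far <- experiment_data(12, 1, N_exp = 30)    # mass where model has ~1e-7
  pv_far <- mc_pvalue(d, ex_far, n_mc = 500, seed = 2)
  expect_true(pv_far$p < 0.01)
  # padding the model with zero-probability bins does not change p
  d_pad <- c(unclass(d), 0, 0)
  set.seed(9); ex <- experiment_data(0:12, as.vector(rmultinom(1, 30, unclass(d))) / 30, 30)
  p1 <- mc_pvalue(unclass(d), ex, n_mc = 400, seed = 5)$p
  p2 <- mc_pvalue(d_pad, ex, n_mc = 400, seed = 5)$p
  expect_equal(p1, p2)
})

test_that("mc p-values are calibrated and their noise shrinks with n_mc", {
  d <- ref_first_step()
  set.seed(61)
  pvals <- vapply(1:150, function(i) {
    cnt <- as.vector(rmultinom(1, 30, unclass(d)))
    ex <- experiment_data(0:12, cnt / 30, 30)
    mc_pvalue(d, ex, n_mc = 400)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_true(ks$p.value > 0.001)
  # Monte-Carlo error ~ 1/sqrt(n_mc): repeated p for one experiment
  cnt <- as.vector(rmultinom(1, 30, unclass(d)))
  ex <- experiment_data(0:12, cnt / 30, 30)
  spread <- function(n_mc) {
    sd(vapply(1:25, function(i) mc_pvalue(d, ex, n_mc = n_mc)$p, numeric(1)))
  }
  expect_true(spread(250) > spread(4000))
})

test_that("mixture over potential-synapse counts", {
  d5 <- synapse_distribution(dbinom(0:5, 5, 0.3))
  d8 <- synapse_distribution(dbinom(0:8, 8, 0.3))
  # point prior: identity
  m1 <- mixture_over_P(p_prior(5, 1), list(d5))
  expect_equal(pvec(m1), pvec(d5))
  # uniform two-component prior: padded arithmetic mean
  m2 <- mixture_over_P(p_prior(c(5, 8), c(0.5, 0.5)), list(d5, d8))
  expect_equal(length(m2), 9)
  expect_equal(pvec(m2), (c(pvec(d5), 0, 0, 0) + pvec(d8)) / 2)
  # concentrated prior stays TV-close to its dominant component
  m3 <- mixture_over_P(p_prior(c(5, 8), c(0.98, 0.02)), list(d5, d8))
  expect_true(tv_distance(m3, c(unclass(d5), 0, 0, 0)) < 0.03)
  expect_error(mixture_over_P(p_prior(c(5, 8), c(0.5, 0.5)), list(d5, d5)),
               "support")
})

test_that("shipped synthetic P-prior drives a mixture at the working point", {
  prior <- default_p_prior()
  expect_equal(prior$P, 1:20)
  expect_equal(sum(prior$prob), 1)
  expect_true(sum(prior$prob[prior$P < 12]) > 0.5)
  # v_i*[S] does not depend on P, so one long profile serves every component
  io <- ref_io(); rule <- ref_rule()
  prof20 <- activity_profile(20, ref_point(), rule, io)
  dists <- lapply(prior$P, function(P) {
    sp <- structural_params(P = P)
    prof <- structure(list(S = 0:P, v_i_star = prof20$v_i_star[1:(P + 1)],
                           w_star = prof20$w_star[1:(P + 1)],
                           monotone = TRUE), class = "activity_profile")
    first_step_distribution(sp, pdel_profile(sp, prof))
  })
  mix <- mixture_over_P(prior, dists)
  expect_equal(sum(mix), 1)
  expect_equal(length(mix), 21)
  # small-P components concentrate at S = 0, so the mixture has more zero
  # mass than the P = 12 component and stays inside the component envelope
  expect_true(mix[1] > pvec(dists[[12]])[1])
  expect_true(all(mix >= 0 & mix <= 1))
  expect_true(mix[1] <= max(vapply(dists, function(d) pvec(d)[1], numeric(1))))
})

test_that("confidence region: self-consistency, emptiness, overlap", {
  sp <- ref_sp(); rule <- ref_rule(); io <- ref_io()
  d <- ref_first_step()
  vj <- seq(0.45, 0.9, length.out = 8)
  vi0 <- seq(0.15, 0.5, length.out = 8)
  set.seed(71)
  cnt <- as.vector(rmultinom(1, 30, unclass(d)))
  ex <- experiment_data(0:12, cnt / 30, 30)
  reg <- scan_confidence_region(vj, vi0, sp, rule, io, ex, n_mc = 300,
                                seed = 5)
  # the generating cell (0.656, 0.2975) lies inside the region: nearest cell
  i <- which.min(abs(vj - 0.656)); j <- which.min(abs(vi0 - 0.2975))
  expect_true(reg$mask[i, j])
  expect_true(reg$summary$area > 0)
  expect_true(reg$summary$coverage > 0.9)
  # an experiment the model cannot produce anywhere: empty region
  ex0 <- experiment_data(c(0, 1), c(0.05, 0.95), 40)
  reg0 <- scan_confidence_region(vj, vi0, sp, rule, io, ex0, n_mc = 300,
                                 seed = 6)
  expect_equal(sum(reg0$mask), 0)
  # two samples from the same cell give overlapping regions
  cnt2 <- as.vector(rmultinom(1, 30, unclass(d)))
  reg2 <- scan_confidence_region(vj, vi0, sp, rule, io,
                                 experiment_data(0:12, cnt2 / 30, 30),
                                 n_mc = 300, seed = 7)
  expect_true(any(reg$mask & reg2$mask))
})

test_that("cline intersections and expected activity", {
  sp <- ref_sp(); rule <- ref_rule(); io <- ref_io()
  d <- ref_first_step()
  set.seed(83)
  ex <- experiment_data(0:12, as.vector(rmultinom(1, 30, unclass(d))) / 30, 30)
  grid <- seq(0.2, 0.9, length.out = 10)
  reg <- scan_confidence_region(grid, grid, sp, rule, io, ex, n_mc = 300,
                                seed = 8)
  ce <- cline_and_expectation(reg)
  # E[v_i] >= v_i(S=0) cells exist; the expected-activity cline intersects
  # the region even where the baseline cline misses it
  expect_true(nrow(ce$expected_cline) >= nrow(ce$baseline_cline) ||
              nrow(ce$expected_cline) > 0)
  if (nrow(ce$expected_cline)) expect_true(is.finite(ce$expected_activity))
  # empty region: empty intersections, no error
  empty_reg <- reg
  empty_reg$mask[] <- FALSE
  ce0 <- cline_and_expectation(empty_reg)
  expect_equal(nrow(ce0$baseline_cline), 0)
  expect_true(is.na(ce0$baseline_activity))
})
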