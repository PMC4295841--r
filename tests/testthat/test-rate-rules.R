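test_that("rule_rhs has the expected zeros and values", {
  bcm <- ref_rule()
  # at v_i = theta and w = 0 both terms vanish
  expect_equal(rule_rhs(bcm, 0, bcm$theta, 0.5), 0)
  # Oja rests at w = v_j / v_i
  oja <- rule_spec("oja")
  expect_equal(rule_rhs(oja, 0.5 / 0.4, 0.4, 0.5), 0)
  # independent substitution check for the scaling rule at (0.5, 0.5, 1)
  mu <- 0.2; theta <- 0.08; kappa <- 9; v_tss <- 0.1
  by_hand <- mu * (0.5 * 0.5 * (0.5 - theta) - (0.5 - v_tss) * 1^2 / kappa)
  expect_equal(rule_rhs(bcm, 1, 0.5, 0.5), by_hand)
  expect_error(rule_rhs(bcm, NaN, 0.5, 0.5))
})

test_that("fixed weights match their closed forms", {
  expect_equal(fixed_weight(rule_spec("hebb_hard", w_max = 0.95), 0.3, 0.5),
               0.95)
  # Oja under linear feedback rests at 1
  expect_equal(fixed_weight(rule_spec("oja"), 0.37, fb = linear_feedback()), 1)
  # BCM + scaling closed form
  r <- rule_spec("bcm_scaling", theta = 0.08, kappa = 9, v_tss = 0.1)
  expect_equal(fixed_weight(r, 0.5, 0.5), sqrt(9 * 0.5 * 0.5 * 0.42 / 0.4))
  # ... and by integrating the differential equation to rest
  w_int <- integrate_rule_to_fp(r, 0.3, 0.5, 0.5)
  expect_equal(w_int, sqrt(9 * 0.5 * 0.5 * 0.42 / 0.4), tolerance = 1e-6)
  # hard-threshold BCM picks the admissible bound by the sign of (v_i - theta)
  bh <- rule_spec("bcm_fixed_hard", theta = 0.1, w_min = 0.04, w_max = 0.95)
  expect_equal(fixed_weight(bh, 0.05, 0.5), 0.04)
  expect_equal(fixed_weight(bh, 0.5, 0.5), 0.95)
  # domain errors instead of silent clamping
  expect_error(fixed_weight(r, 0.05, 0.5), "v_tss")
  expect_error(fixed_weight(rule_spec("bcm_scaling", theta = 0.3), 0.2, 0.5),
               "negative Hebbian drive")
})

test_that("sliding-threshold BCM needs an invertible IO curve in range", {
  r <- rule_spec("bcm_sliding", theta_tilde = 2)
  io <- logistic_io()
  w <- fixed_weight(r, 0.4, 0.6, io = io, I = -1)
  expect_equal(w, (io$inverse(0.5) - (-1)) / 0.6)
  expect_error(fixed_weight(r, 0.4, 0.6), "needs io")
  r_bad <- rule_spec("bcm_sliding", theta_tilde = 0.5)  # target rate 2 > 1
  expect_error(fixed_weight(r_bad, 0.4, 0.6, io = io, I = -1),
               "not applicable")
})

test_that("integrating every rule from random weights reaches its fixed point", {
  set.seed(13)
  v_i <- 0.55; v_j <- 0.4
  kinds <- c("hebb_hard", "bcm_fixed_hard", "oja", "hebb_scaling", "bcm_scaling")
  for (kind in kinds) {
    rule <- switch(kind,
      hebb_hard = rule_spec("hebb_hard", w_min = 0.04, w_max = 0.95),
      bcm_fixed_hard = rule_spec("bcm_fixed_hard", theta = 0.1,
                                 w_min = 0.04, w_max = 0.95),
      oja = rule_spec("oja"),
      hebb_scaling = rule_spec("hebb_scaling", v_tss = 0.05, kappa = 1),
      bcm_scaling = rule_spec("bcm_scaling", theta = 0.1, v_tss = 0.05,
                              kappa = 1))
    target <- fixed_weight(rule, v_i, v_j)
    for (w0 in runif(4, 0.01, 3)) {
      w_end <- integrate_rule_to_fp(rule, w0, v_i, v_j)
      expect_equal(w_end, target, tolerance = 1e-6,
                   label = sprintf("%s from w0=%.3f", kind, w0))
    }
  }
})

test_that("necessary condition reproduces the rule-by-system pattern", {
  rules <- condition_table_rules()
  ff <- feedforward(); fbk <- linear_feedback()
  expected_true <- c("hebb_scaling.feedback", "bcm_scaling.feedforward",
                     "bcm_scaling.feedback")
  for (nm in names(rules)) {
    for (sys in c("feedforward", "feedback")) {
      fb <- if (sys == "feedforward") ff else fbk
      res <- necessary_condition(rules[[nm]], fb, v_range = c(0.15, 0.95),
                                 v_j = 0.08)
      expect_identical(isTRUE(res$ok),
                       paste(nm, sys, sep = ".") %in% expected_true,
                       label = paste(nm, sys))
    }
  }
})

test_that("necessary condition reports slope profiles and shrunken ranges", {
  r <- rule_spec("bcm_scaling", theta = 0.1, v_tss = 0.05, kappa = 1)
  res <- necessary_condition(r, feedforward(), v_range = c(0.01, 0.95),
                             v_j = 0.08)
  # below v_tss / theta the fixed weight does not exist -> NAs reported
  expect_true(res$evaluable_fraction < 1)
  expect_true(any(is.na(res$slope)))
})

test_that("mean inner curvature helper behaves on crafted sign patterns", {
  # concave hump between crossings: curvature negative
  d <- c(-1, 0.5, 1, 0.5, -1)
  expect_true(structplast:::delta_mean_curvature(d) < 0)
  # convex valley between crossings: positive
  expect_true(structplast:::delta_mean_curvature(-d) > 0)
  # fewer than two crossings: NA
  expect_true(is.na(structplast:::delta_mean_curvature(c(1, 2, 3))))
})

test_that("sufficient condition holds at the reference working point", {
  res <- sufficient_condition(ref_rule(), ref_io(), feedforward(), ref_sp(),
                              ref_point())
  expect_true(res$applicable)
  expect_true(res$ok)
  expect_equal(res$n_crossings, 2)
  expect_true(res$mean_curvature < 0)
})

test_that("sufficient condition: linear v-w relation with concave logistic IO", {
  # an empirical rule with linearly growing fixed weight; the logistic IO
  # supplies the (negative) curvature once the visited activities sit in its
  # concave region -> case 6_2 mechanism
  rule <- rule_spec("empirical", vw_fun = function(v_i, v_j) 1 + 1.6 * v_i)
  io <- logistic_io()
  pt <- system_point(v_j = 0.6, I = qlogis(0.25), io = io)
  res <- sufficient_condition(rule, io, feedforward(), ref_sp(), pt)
  expect_true(res$applicable)
  expect_true(res$ok)
})

test_that("sufficient condition is not applicable without two crossings", {
  # very low stimulation: deletion dominates everywhere, no crossings
  pt <- system_point(v_j = 0.3, v_i_S0 = 0.05)
  res <- sufficient_condition(ref_rule(), ref_io(), feedforward(), ref_sp(),
                              pt)
  expect_false(res$applicable)
  expect_true(is.na(res$ok))
})
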