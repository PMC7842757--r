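test_that("regions partition the mean-frequency range into terciles", {
  expect_equal(as.character(assign_region(c(-0.15, 0, 0.15))),
               c("I", "II", "III"))
  expect_equal(as.character(assign_region(c(-0.2 / 3 - 1e-9, 0.2 / 3 + 1e-9))),
               c("I", "III"))
  blk <- generate_block("control", 220, seed = 61)
  reg <- assign_region(blk)
  expect_s3_class(reg, "factor")
  expect_equal(levels(reg), c("I", "II", "III"))
})

test_that("psychometric curves are step-like for noiseless observers and track the model", {
  blk <- generate_block("control", 2000, seed = 62)
  noiseless <- simulate_static_observer(observer_spec("static", sigma = 0,
                                                      seed = 63), blk)
  cv <- psychometric_curve(noiseless)
  expect_equal(cv$prop[cv$bin_center < 0], rep(0, 4))
  expect_equal(cv$prop[cv$bin_center > 0], rep(1, 4))
  expect_false(attr(cv, "empty"))

  cohort <- simulate_cohort(cohort_spec(8, sigma_distribution =
                                          list(dist = "fixed", value = 0.1),
                                        n_trials = 220, master_seed = 64))
  cva <- psychometric_curve(cohort)
  p <- perceptron_params(1, 0, 0.1)
  pred <- response_probability(p, cva$bin_center / 2, -cva$bin_center / 2)
  se <- sqrt(pred * (1 - pred) / cva$n_trials)
  expect_true(all(abs(cva$prop - pred) < 3 * se + 0.02))
  expect_true(all(cva$n_observers == 8))
})

test_that("a choice-biased observer shifts the curve midpoint rightward", {
  blk <- generate_block("control", 5000, seed = 65)
  biased <- simulate_static_observer(observer_spec("static", a = 1, b = 0.03,
                                                   sigma = 0.1, seed = 66),
                                     blk)
  fit <- fit_sigmoid(biased)
  expect_gt(fit$midpoint, 0.015)
  expect_lt(fit$value_at_0, 0.5)
})

test_that("sigmoid fitting recovers known psychometric parameters", {
  set.seed(67)
  delta <- runif(5000, -0.181, 0.181)
  resp <- as.integer(runif(5000) < pnorm((delta - 0.03) / 0.1))
  fit <- fit_sigmoid(data.frame(delta = delta, response = resp))
  expect_false(fit$degenerate)
  expect_equal(fit$midpoint, 0.03, tolerance = 0.3)
  expect_equal(fit$slope, 0.1, tolerance = 0.3)

  # symmetric step data have midpoint ~0
  step <- data.frame(delta = delta, response = as.integer(delta > 0))
  fstep <- fit_sigmoid(step)
  expect_lt(abs(fstep$midpoint), 0.005)

  # degenerate data are flagged and report the empirical proportion
  fdeg <- fit_sigmoid(data.frame(delta = delta[1:50],
                                 response = rep(1L, 50)))
  expect_true(fdeg$degenerate)
  expect_equal(fdeg$value_at_0, 1)
})

test_that("contraction magnitude is null for a = 1 and positive for a < 1", {
  unbiased <- simulate_cohort(cohort_spec(10, a = 1,
                                          sigma_distribution =
                                            list(dist = "fixed", value = 0.1),
                                        n_trials = 1000, master_seed = 68))
  bs0 <- contraction_magnitude(unbiased)
  expect_lt(abs(bs0$contraction_magnitude), 0.075)
  expect_lt(abs(bs0$contraction_magnitude_impossible), 0.075)

  contracting <- simulate_cohort(cohort_spec(10, a = 0.75,
                                             sigma_distribution =
                                               list(dist = "fixed",
                                                    value = 0.1),
                                             n_trials = 220,
                                             master_seed = 69))
  bs <- contraction_magnitude(contracting, per_observer = TRUE)
  expect_gt(bs$contraction_magnitude, 0.1)
  expect_gt(bs$contraction_magnitude_impossible, 0.1)
  expect_length(bs$per_observer_impossible, 10L)

  # the two estimators of the contrast agree on a large cohort
  big <- simulate_cohort(cohort_spec(20, a = 0.75,
                                     sigma_distribution =
                                       list(dist = "fixed", value = 0.1),
                                     n_trials = 1000, master_seed = 70))
  bb <- contraction_magnitude(big, per_observer = TRUE)
  se_imp <- sd(bb$per_observer_impossible) /
    sqrt(length(bb$per_observer_impossible))
  expect_lt(abs(bb$contraction_magnitude -
                  bb$contraction_magnitude_impossible), 3 * se_imp + 0.02)
})

test_that("region-II curves are unshifted for unbiased static observers", {
  cohort <- simulate_cohort(cohort_spec(12, a = 1,
                                        sigma_distribution =
                                          list(dist = "fixed", value = 0.1),
                                        n_trials = 500, master_seed = 71))
  bs <- contraction_magnitude(cohort)
  expect_lt(abs(bs$choice_bias), 0.012)
})

test_that("the impossible-trial time course has the expected shape", {
  cohort <- simulate_cohort(cohort_spec(10, a = 1,
                                        sigma_distribution =
                                          list(dist = "fixed", value = 0.1),
                                        n_trials = 220, master_seed = 72))
  tc <- choice_bias_timecourse(cohort, window = 20)
  expect_equal(nrow(tc), 11L)
  expect_equal(tc$trial_lo, seq(1, 201, by = 20))
  # unbiased static observers stay at 0.5 throughout
  expect_true(all(abs(tc$mean_p_f1gt - 0.5) < 3 * tc$sem + 0.05))
  expect_error(choice_bias_timecourse(cohort, window = 21), "divide")
})

test_that("rank-sum p-values match full enumeration on small groups", {
  res <- group_difference_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 1 / 20)
  expect_true(res$exact)

  # identical groups offer no evidence of direction
  same <- group_difference_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p_value, 0.5)

  set.seed(73)
  for (i in 1:25) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- round(rnorm(na), 3); b <- round(rnorm(nb, 0.5), 3)
    if (any(duplicated(c(a, b)))) next
    expect_equal(group_difference_test(a, b)$p_value,
                 oracle_ranksum_less(a, b), tolerance = 1e-10,
                 info = sprintf("case %d", i))
  }
  expect_error(group_difference_test(1, c(1, 2)), "at least 2")
})
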