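test_that("the decision rule implements h = a*r1 - r2 - b with a step", {
  p <- perceptron_params(1, 0, 0)
  out <- decide(p, 0.1, 0.0)
  expect_equal(out$h, 0.1)
  expect_equal(out$A, 1L)

  expect_equal(decide(perceptron_params(1, 0.2, 0), 0.1, 0.0)$A, 0L)

  # a = 0: the first stimulus is ignored entirely
  p0 <- perceptron_params(0, 0, 0)
  expect_equal(decide(p0, c(-5, 0, 5), rep(-0.05, 3))$A, rep(1L, 3))
  expect_equal(decide(p0, c(-5, 0, 5), rep(0.05, 3))$A, rep(0L, 3))

  # tie h == 0 resolves to A = 0
  expect_equal(decide(p, 0.05, 0.05)$A, 0L)
  expect_error(decide(p, Inf, 0), "finite")
})

test_that("response probability is the normal upper tail of the decision variable", {
  p <- perceptron_params(1, 0, 0.1)
  expect_equal(response_probability(p, 0.05, 0.05), 0.5)
  expect_equal(response_probability(p, 0.05, -0.05), pnorm(1))
  expect_equal(response_probability(p, -0.05, 0.05), pnorm(-1))

  # deterministic limits
  expect_equal(response_probability(perceptron_params(0, 0, 0.3), 0.1, 0.05), 0)
  expect_equal(response_probability(perceptron_params(0, 0, 0.3), 0.1, -0.05), 1)
  expect_equal(response_probability(perceptron_params(1, 0, 0), 0.02, 0.01), 1)

  # complement identity and monotonicity (property, fixed seed)
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0.1, 1.5); b <- runif(1, -0.1, 0.1)
    sig <- runif(1, 0.01, 0.3)
    pp <- perceptron_params(a, b, sig)
    s1 <- sort(runif(50, -0.3, 0.3)); s2 <- runif(1, -0.2, 0.2)
    probs <- response_probability(pp, s1, s2)
    expect_true(all(diff(probs) >= 0))                      # increasing in s1
    expect_true(all(diff(response_probability(pp, s2, s1)) <= 0))
    expect_equal(probs + pnorm((s2 + b - a * s1) / (a * sig)), rep(1, 50))
  }
})

test_that("the posterior shrinks the noisy representation toward the prior mean", {
  pr <- prior_spec("gaussian", Sigma = 0.1)
  post <- posterior_s1(0.1, sigma = 0.1, prior = pr)
  expect_equal(post$mu, 0.05)          # equal precisions halve the estimate
  expect_equal(post$rho2, 1 / (1 / 0.01 + 1 / 0.01))

  post0 <- posterior_s1(0.07, sigma = 0, prior = pr)
  expect_equal(post0$mu, 0.07)
  expect_equal(post0$rho2, 0)

  post_inf <- posterior_s1(0.07, sigma = 1e6, prior = pr)
  expect_lt(abs(post_inf$mu), 1e-10)

  # rho2 never exceeds either variance; mu lies between 0 and r1
  for (sig in c(0.01, 0.05, 0.2, 1)) {
    po <- posterior_s1(0.08, sig, pr)
    expect_lte(po$rho2, min(sig^2, pr$Sigma^2) + 1e-15)
    expect_gte(po$mu, 0)
    expect_lte(po$mu, 0.08)
  }
})

test_that("the closed-form optimal weight follows 1/(1 + sigma^2/Sigma^2)", {
  pr <- prior_spec("gaussian", Sigma = 0.1)
  expect_equal(optimal_a_gaussian(0, pr), 1)
  expect_equal(optimal_a_gaussian(0.1, pr), 0.5)
  expect_equal(optimal_a_gaussian(0.2, pr), 0.2)
  sig <- seq(0, 1, by = 0.05)
  expect_true(all(diff(optimal_a_gaussian(sig, pr)) < 0))
  # the task-variance prior computes Sigma from the design ranges
  tu <- prior_spec("task_uniform")
  expect_equal(tu$Sigma^2, 0.2^2 / 3 + 0.0905^2 / 3)
})

test_that("expected reward matches hand-computable limits and symmetries", {
  expect_equal(expected_reward(1, 0, 0, "control"), 0.875)

  # control feedback is symmetric under (s1,s2,b) -> (-s1,-s2,-b)
  for (b in c(0.03, 0.1)) {
    for (sig in c(0.05, 0.15)) {
      expect_equal(expected_reward(0.8, b, sig, "control"),
                   expected_reward(0.8, -b, sig, "control"),
                   tolerance = 1e-10)
    }
  }

  # ignoring the first stimulus still beats chance
  for (sig in c(0, 0.1, 0.5)) {
    expect_gt(expected_reward(0, 0, sig, "control"), 0.5)
  }
})

test_that("quadrature expected reward agrees with Monte-Carlo", {
  cases <- list(c(1, 0, 0.1), c(0.7, 0.05, 0.2), c(0.5, -0.1, 0.05))
  for (proto in c("control", "enhance_contraction")) {
    for (cs in cases) {
      mc <- oracle_mc_expected_reward(cs[1], cs[2], cs[3], proto,
                                      n = 1e5, seed = round(100 * cs[1]))
      expect_lt(abs(expected_reward(cs[1], cs[2], cs[3], proto) - mc$mean),
                3 * mc$se)
    }
  }
})

test_that("parameter optimization recovers the unbiased optimum", {
  opt <- optimize_params(0, "control")
  expect_equal(opt$a, 1, tolerance = 1e-3)
  expect_equal(opt$b, 0, tolerance = 1e-3)
  expect_equal(opt$value, 0.875, tolerance = 1e-5)

  # a* in (0, 1] and approaching 1 as noise vanishes
  a_stars <- vapply(c(0.3, 0.1, 0.02, 0.005),
                    function(s) optimize_params(s, "control")$a, numeric(1))
  expect_true(all(a_stars > 0 & a_stars <= 1 + 1e-6))
  expect_true(all(diff(a_stars) > 0))
  expect_gt(a_stars[4], 0.99)
})

test_that("quadrant accuracies capture the a = 0 Perceptron's structure", {
  qa0 <- quadrant_accuracy(perceptron_params(0, 0, 0.1))
  expect_equal(unname(qa0["f1_high_f2_low"]), 1)
  expect_equal(unname(qa0["f1_low_f2_high"]), 1)
  expect_equal(unname(qa0["f1_low_f2_low"]), 0.5, tolerance = 0.01)
  expect_equal(unname(qa0["f1_high_f2_high"]), 0.5, tolerance = 0.01)

  qa1 <- quadrant_accuracy(perceptron_params(1, 0, 0))
  expect_true(all(qa1 == 1))
  expect_equal(sum(attr(qa0, "mass")), 1, tolerance = 1e-12)
})

test_that("the indifference line of the response surface has slope a", {
  # P = 0.5 exactly on the line a*s1 - s2 - b = 0
  for (cs in list(c(1, 0), c(0.75, 0), c(1, 0.05))) {
    p <- perceptron_params(cs[1], cs[2], 0.1)
    s1 <- seq(-0.15, 0.15, length.out = 7)
    s2 <- cs[1] * s1 - cs[2]
    expect_equal(response_probability(p, s1, s2), rep(0.5, 7))
  }
  surf <- response_surface(perceptron_params(1, 0, 0.08))
  expect_equal(dim(surf), c(41L, 41L))
  expect_equal(unname(diag(surf)), rep(0.5, 41))  # diagonal indifference
  expect_true(all(surf >= 0 & surf <= 1))
})
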