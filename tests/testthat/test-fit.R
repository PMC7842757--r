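test_that("the choice log-likelihood matches a hand-computed product", {
  # 10-trial toy log built by hand
  f1 <- 1000 * exp(c(0.05, -0.03, 0.1, 0.0, -0.08, 0.02, 0.06, -0.01, 0.04, -0.06))
  f2 <- 1000 * exp(c(-0.05, 0.03, 0.02, 0.0, -0.02, -0.04, 0.06, 0.05, -0.04, 0.02))
  df <- data.frame(trial_index = 1:10, f1_hz = f1, f2_hz = f2,
                   is_impossible = f1 == f2,
                   rewarded_response_draw = ifelse(f1 == f2, 1L, NA_integer_),
                   response = c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L),
                   feedback = NA_integer_)
  log <- perceptbias:::new_trial_log(df, "control")

  sigma <- 0.12
  p <- pnorm((log$s1 - log$s2) / sigma)
  ll_oracle <- sum(ifelse(log$response == 1, base::log(p), base::log(1 - p)))
  expect_equal(choice_loglik("psychometric", sigma, log), ll_oracle)

  # impossible trials contribute log(0.5) each under the psychometric model
  imp <- log[log$is_impossible, ]
  expect_equal(choice_loglik("psychometric", sigma, imp),
               nrow(imp) * base::log(0.5))

  # deterministic-looking data prefer a sharper curve
  det <- log[!log$is_impossible, ]
  det$response <- as.integer(det$s1 > det$s2)
  expect_gt(choice_loglik("psychometric", 0.02, det),
            choice_loglik("psychometric", 0.3, det))

  expect_error(choice_loglik("psychometric", 0.1,
                             generate_block("control", 8, seed = 1)),
               "responses")
})

test_that("the likelihood profile is finite and continuous in sigma", {
  blk <- generate_block("control", 220, seed = 41)
  obs <- simulate_static_observer(observer_spec("static", sigma = 0.1,
                                                seed = 42), blk)
  sig <- 10^seq(-3, 0, length.out = 120)
  ll <- vapply(sig, function(s) choice_loglik("psychometric", s, obs),
               numeric(1))
  expect_true(all(is.finite(ll)))
  # no jump larger than expected for a smooth profile on a log grid
  expect_lt(max(abs(diff(ll))), 50)
})

test_that("fit_sigma recovers the generating noise on a large block", {
  blk <- generate_block("control", 10000, seed = 43)
  obs <- simulate_static_observer(observer_spec("static", a = 1, b = 0,
                                                sigma = 0.1, seed = 44), blk)
  fit <- fit_sigma(obs, model = "psychometric")
  expect_true(fit$converged)
  expect_lt(abs(fit$sigma_hat - 0.1) / 0.1, 0.1)
  # grid stage peaks at or adjacent to the truth
  i_true <- which.min(abs(fit$profile$sigma - 0.1))
  i_peak <- which.max(fit$profile$loglik)
  expect_lte(abs(i_peak - i_true), 2L)
})

test_that("degenerate data drive the estimate to the boundary with a flag", {
  blk <- generate_block("control", 220, seed = 45)
  noiseless <- simulate_static_observer(observer_spec("static", sigma = 0,
                                                      seed = 46), blk)
  fit <- fit_sigma(noiseless, model = "psychometric")
  expect_false(fit$converged)
  expect_equal(fit$sigma_hat, min(fit$profile$sigma))

  all_one <- blk
  all_one$response <- 1L
  all_one$feedback <- assign_feedback("control", all_one, 1L)
  fit1 <- fit_sigma(all_one, model = "psychometric")
  expect_false(fit1$converged)
})

test_that("sigma_fit behaves like a standard model object", {
  blk <- generate_block("control", 220, seed = 47)
  obs <- simulate_static_observer(observer_spec("static", sigma = 0.12,
                                                seed = 48), blk)
  fit <- fit_sigma(obs, model = "psychometric")

  expect_named(coef(fit), c("sigma", "a", "b"))
  expect_equal(unname(coef(fit)[c("a", "b")]), c(1, 0))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "df"), 1L)
  expect_equal(attr(ll, "nobs"), 220L)

  pr <- predict(fit)
  expect_length(pr, 220L)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(predict(fit, type = "response"), as.integer(pr > 0.5))
  expect_equal(residuals(fit), obs$response - pr)
  newd <- data.frame(s1 = c(0.1, -0.1), s2 = c(-0.1, 0.1))
  expect_equal(predict(fit, newd),
               response_probability(perceptron_params(1, 0, fit$sigma_hat),
                                    newd$s1, newd$s2))

  s1 <- simulate(fit, nsim = 2, seed = 9)
  s2 <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(unlist(s1) %in% 0:1))

  expect_output(print(fit), "sigma_hat")
  expect_output(print(summary(fit)), "accuracy on possible trials")
  tf <- tempfile(fileext = ".png")
  png(tf); plot(fit); dev.off()
  expect_true(file.exists(tf))
})

test_that("the optimal-Perceptron fit uses the reward-optimal (a, b) mapping", {
  blk <- generate_block("control", 220, seed = 49)
  obs <- simulate_static_observer(observer_spec("static", a = 0.74, b = 0,
                                                sigma = 0.1, seed = 50), blk)
  fit <- fit_sigma(obs, model = "optimal_perceptron")
  opt <- optimize_params(fit$sigma_hat, "control")
  expect_equal(fit$a, opt$a, tolerance = 5e-3)
  expect_equal(fit$b, opt$b, tolerance = 5e-3)
  expect_lt(fit$a, 1)  # contraction predicted at positive noise
  # and the likelihood at the optimum mapping agrees with choice_loglik
  expect_equal(fit$loglik,
               choice_loglik("optimal_perceptron", fit$sigma_hat, obs),
               tolerance = 1e-4)
})

test_that("model comparison handles ties, pairs and mismatches", {
  blk <- generate_block("control", 220, seed = 51)
  obs <- simulate_static_observer(observer_spec("static", sigma = 0.1,
                                                seed = 52), blk)
  fit <- fit_sigma(obs, model = "psychometric")
  cmp <- compare_models(fit, fit)
  expect_equal(cmp$per_observer$dll_per_trial, 0)
  expect_true(cmp$all_tied)
  expect_equal(cmp$fraction_favoring_perceptron, 0.5)

  fit2 <- fit_sigma(obs[1:100, ], model = "psychometric")
  expect_error(compare_models(fit, fit2), "different trial counts")
})
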