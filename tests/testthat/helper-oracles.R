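# Independent oracles used across tests. These deliberately avoid the
# package's own quadrature/optimisation code paths.

# Discrimination accuracy of the rule "respond 1 iff a*r1 > s2" when
# s1 ~ N(0, Sigma^2), r1 = s1 + N(0, sigma^2), and s2 ~ U(-s2_range,
# s2_range) independent of s1. Quadrature: conditional on (s1, s2) the
# response probability is a normal tail, integrated on dense grids.
oracle_gaussian_accuracy <- function(a, sigma, Sigma, s2_range = 0.15,
                                     n_s1 = 201L, n_s2 = 201L) {
  s1 <- seq(-5 * Sigma, 5 * Sigma, length.out = n_s1)
  w1 <- dnorm(s1, 0, Sigma)
  w1 <- w1 / sum(w1)
  s2 <- seq(-s2_range, s2_range, length.out = n_s2)
  acc <- 0
  for (j in seq_along(s2)) {
    p1 <- pnorm((a * s1 - s2[j]) / (abs(a) * sigma))
    correct <- ifelse(s1 > s2[j], p1, 1 - p1)
    acc <- acc + sum(w1 * correct)
  }
  acc / n_s2
}

# Brute-force optimal weight under the Gaussian-prior setting above.
oracle_gaussian_opt_a <- function(sigma, Sigma, a_grid = seq(0.05, 1.2,
                                                             by = 0.005)) {
  accs <- vapply(a_grid, oracle_gaussian_accuracy, numeric(1),
                 sigma = sigma, Sigma = Sigma)
  a_grid[which.max(accs)]
}

# Monte-Carlo expected feedback rate of a perceptron under a protocol.
oracle_mc_expected_reward <- function(a, b, sigma, protocol, n = 1e5,
                                      seed = 99) {
  proto <- feedback_protocol(protocol)
  set.seed(seed)
  imp <- runif(n) < 0.25
  m <- runif(n, -0.2, 0.2)
  d <- ifelse(imp, 0, runif(n, -0.0905, 0.0905))
  s1 <- m + d; s2 <- m - d
  r1 <- s1 + rnorm(n, 0, sigma)
  A <- as.integer(a * r1 - s2 - b > 0)
  p_rew <- ifelse(m < 0, proto$p_reward_f1gt_low, proto$p_reward_f1gt_high)
  rr <- rbinom(n, 1, p_rew)
  fb <- ifelse(imp, as.integer(A == rr), as.integer(A == (d > 0)))
  list(mean = mean(fb), se = sd(fb) / sqrt(n))
}

# Exact two-sided binomial p-value by direct enumeration of the pmf
# (sum of P(X = j) over all j at most as probable as the observed count).
oracle_binom_two_sided <- function(k, n, p = 0.5) {
  pm <- dbinom(0:n, n, p)
  sum(pm[pm <= pm[k + 1] * (1 + 1e-7)])
}

# Exact one-sided rank-sum p-value by full enumeration of group-A rank
# assignments (P(W_A <= observed) for alternative A < B).
oracle_ranksum_less <- function(a, b) {
  v <- c(a, b)
  n <- length(v)
  ranks <- rank(v)
  w_obs <- sum(ranks[seq_along(a)])
  combos <- combn(n, length(a))
  w_all <- apply(combos, 2, function(idx) sum(rank(v)[idx]))
  mean(w_all <= w_obs)
}
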