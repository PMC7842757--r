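#' Perceptron parameters
#'
#' The observer model has three parameters: the weight `a` applied to the
#' (noisy) representation of the first stimulus, the decision criterion
#' `b`, and the standard deviation `sigma` of the Gaussian noise corrupting
#' the first stimulus' representation. All stimulus quantities are in
#' natural-log frequency units relative to 1 kHz.
#'
#' @param a First-stimulus weight (unitless). Values below 1 produce
#'   contraction bias; `a = 1` weights both stimuli equally.
#' @param b Decision criterion (log-frequency units). Nonzero values
#'   produce choice bias.
#' @param sigma Representation-noise SD (log-frequency units, >= 0).
#' @return An object of class `perceptron_params`.
#' @examples
#' perceptron_params(a = 0.8, b = 0, sigma = 0.1)
#' @export
perceptron_params <- function(a, b = 0, sigma = 0) {
  stopifnot(is.finite(a), is.finite(b), is.finite(sigma) || sigma == Inf,
            sigma >= 0)
  structure(list(a = a, b = b, sigma = sigma), class = "perceptron_params")
}

#' @export
print.perceptron_params <- function(x, ...) {
  cat(sprintf("Perceptron parameters: a = %.4g, b = %.4g, sigma = %.4g\n",
              x$a, x$b, x$sigma))
  invisible(x)
}

#' Perceptron decision rule
#'
#' Applies the linear discriminator `h = a * r1 - r2 - b` followed by a
#' step nonlinearity: the action is `A = 1` ("f1 > f2") when `h > 0` and
#' `A = 0` otherwise. The tie `h == 0` — measure-zero under noise — is
#' resolved to `A = 0` for determinism.
#'
#' @param params A [perceptron_params()] object.
#' @param r1,r2 Internal representations of the two stimuli (log-frequency
#'   units); `r2` equals the veridical `s2`, `r1` is typically `s1 + noise`.
#'   Vectorised.
#' @return A list with numeric `h` and integer `A`.
#' @export
decide <- function(params, r1, r2) {
  stopifnot(all(is.finite(r1)), all(is.finite(r2)))
  h <- params$a * r1 - r2 - params$b
  list(h = h, A = as.integer(h > 0))
}

#' Probability of responding "f1 > f2"
#'
#' The decision variable `h = a * (s1 + n) - s2 - b` with
#' `n ~ N(0, sigma^2)` is Gaussian with mean `a*s1 - s2 - b` and SD
#' `|a|*sigma`, so the response probability is the upper-tail normal
#' probability at zero. When `sigma == 0` or `a == 0` the decision is
#' deterministic and the probability is the step value in \{0, 1\} (with
#' the `h == 0` tie resolved to 0).
#'
#' @param params A [perceptron_params()] object.
#' @param s1,s2 True stimulus values (log-frequency units), vectorised.
#' @return Numeric vector of probabilities of reporting "f1 > f2".
#' @examples
#' p <- perceptron_params(1, 0, 0.1)
#' response_probability(p, s1 = 0.05, s2 = -0.05)  # pnorm(1)
#' @export
response_probability <- function(params, s1, s2) {
  z <- params$a * s1 - s2 - params$b
  sd <- abs(params$a) * params$sigma
  if (sd > 0) pnorm(z / sd) else as.numeric(z > 0)
}

#' Prior specification for the first stimulus
#'
#' The Bayesian account treats the remembered first stimulus as a draw from
#' a prior centred on the distribution median. `family = "gaussian"` uses a
#' normal prior with SD `Sigma`; `family = "task_uniform"` sets `Sigma^2`
#' to the variance of the task's actual `s1` marginal (the convolution of
#' the two uniform components, computed from the design ranges).
#'
#' @param family `"gaussian"` or `"task_uniform"`.
#' @param Sigma Prior SD (required for `"gaussian"`, ignored otherwise).
#' @return An object of class `prior_spec` with elements `family`, `Sigma`.
#' @export
prior_spec <- function(family = c("gaussian", "task_uniform"), Sigma = NULL) {
  family <- match.arg(family)
  if (family == "task_uniform") {
    Sigma <- sqrt(.M_RANGE^2 / 3 + .D_RANGE^2 / 3)
  } else {
    stopifnot(is.numeric(Sigma), length(Sigma) == 1L, Sigma > 0)
  }
  structure(list(family = family, Sigma = Sigma), class = "prior_spec")
}

#' Posterior over the first stimulus given its noisy representation
#'
#' With likelihood `r1 | s1 ~ N(s1, sigma^2)` and prior
#' `s1 ~ N(0, Sigma^2)`, the posterior is normal with mean
#' `mu = r1 / (1 + sigma^2/Sigma^2)` and variance
#' `rho^2 = 1 / (1/sigma^2 + 1/Sigma^2)`: the representation is shrunk
#' toward the prior mean by an amount that grows with the noise.
#'
#' @param r1 Noisy representation of the first stimulus (vectorised).
#' @param sigma Representation-noise SD (>= 0; `sigma = 0` returns
#'   `mu = r1`, `rho2 = 0`).
#' @param prior A [prior_spec()].
#' @return List with `mu` and `rho2`.
#' @export
posterior_s1 <- function(r1, sigma, prior) {
  stopifnot(inherits(prior, "prior_spec"), sigma >= 0)
  Sigma <- prior$Sigma
  if (sigma == 0) return(list(mu = r1, rho2 = 0))
  mu <- r1 / (1 + sigma^2 / Sigma^2)
  rho2 <- 1 / (1 / sigma^2 + 1 / Sigma^2)
  list(mu = mu, rho2 = rho2)
}

#' Closed-form optimal weight under a Gaussian prior
#'
#' Reporting "f1 > f2" exactly when the posterior mean of `s1` exceeds
#' `s2` is implemented by a Perceptron with weight
#' `a = 1 / (1 + sigma^2/Sigma^2)` and criterion `b = 0`. The weight is 1
#' only at `sigma = 0` and decreases toward 0 as the noise grows — the
#' normative account of contraction bias.
#'
#' @param sigma Representation-noise SD (vectorised, >= 0).
#' @param prior A [prior_spec()] (Gaussian family, or the task-variance
#'   matched `"task_uniform"` spec).
#' @return Optimal weight(s) in (0, 1].
#' @examples
#' optimal_a_gaussian(0, prior_spec("gaussian", Sigma = 0.1))      # 1
#' optimal_a_gaussian(0.2, prior_spec("gaussian", Sigma = 0.1))    # 0.2
#' @export
optimal_a_gaussian <- function(sigma, prior) {
  stopifnot(inherits(prior, "prior_spec"), all(sigma >= 0))
  1 / (1 + sigma^2 / prior$Sigma^2)
}

# ---------------------------------------------------------------------------
# Expected feedback rate ("expected reward") machinery
#
# Possible trials (75%): m ~ U(-M, M), d ~ U(-D, D); feedback is veridical,
# so the contribution is the probability that the response matches sign(d).
# Impossible trials (25%): m ~ U(-M, M), d = 0; feedback follows the
# protocol's contingency table.
#
# For sigma*|a| > 0 the integrand is smooth within each half-range and is
# integrated by tensor-product Gauss-Legendre quadrature, split at d = 0
# (where the "correct" response flips) and m = 0 (where the reward
# probability jumps). For sigma*|a| == 0 the response is deterministic and
# the expectation reduces to exact areas of half-planes clipped to the
# stimulus rectangle; quadrature of an indicator would be unreliable there.
# ---------------------------------------------------------------------------

.gl_cache <- new.env(parent = emptyenv())

gl_nodes <- function(n, lo, hi) {
  key <- sprintf("%d_%.17g_%.17g", n, lo, hi)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, lo, hi)
  }
  .gl_cache[[key]]
}

# Smooth path: expected reward for vectors a, b (equal length) at one sigma.
expected_reward_smooth <- function(a, b, sigma, proto, n_m = 48L, n_d = 24L) {
  M <- .M_RANGE; D <- .D_RANGE
  gm <- gl_nodes(n_m, -M, M)
  gdp <- gl_nodes(n_d, 0, D)       # d > 0 half; d < 0 by symmetry of nodes
  gdn <- gl_nodes(n_d, -D, 0)
  dd <- c(gdn$x, gdp$x)
  wd <- c(gdn$w, gdp$w)
  mm <- rep(gm$x, times = length(dd))
  d2 <- rep(dd, each = n_m)
  ww <- rep(gm$w, times = length(dd)) * rep(wd, each = n_m)

  K <- length(a)
  alpha <- a - 1; beta <- a + 1
  sd <- abs(a) * sigma
  # K x N matrices
  Z <- outer(alpha, mm) + outer(beta, d2) - b
  P <- pnorm(Z / sd)               # sd recycles down columns (K-vector)
  corr <- sweep(P, 2, as.numeric(d2 > 0), function(p, pos) {
    pos * p + (1 - pos) * (1 - p)
  })
  e_poss <- as.numeric(corr %*% ww) / (2 * M * 2 * D)

  gmn <- gl_nodes(n_m, -M, 0)
  gmp <- gl_nodes(n_m, 0, M)
  mi <- c(gmn$x, gmp$x)
  wi <- c(gmn$w, gmp$w)
  p_rew <- ifelse(mi < 0, proto$p_reward_f1gt_low, proto$p_reward_f1gt_high)
  Zi <- outer(alpha, mi) - b
  Pi <- pnorm(Zi / sd)
  Ri <- sweep(Pi, 2, p_rew, function(p, q) p * q + (1 - p) * (1 - q))
  e_imp <- as.numeric(Ri %*% wi) / (2 * M)

  list(poss = e_poss, imp = e_imp)
}

# Length of {m in (-M, M): response A(m) = 1} for the deterministic
# perceptron, as a function of d: the half-plane alpha*m + beta*d - b > 0
# clipped to the m-range (piecewise linear in d).
.len_respond1 <- function(alpha, beta, b, d, M) {
  if (alpha > 0) {
    pmin(pmax(M - (b - beta * d) / alpha, 0), 2 * M)
  } else if (alpha < 0) {
    pmin(pmax((b - beta * d) / alpha + M, 0), 2 * M)
  } else {
    2 * M * as.numeric(beta * d - b > 0)
  }
}

# Deterministic path (sigma == 0 or a == 0): exact-geometry expectation.
# The d-integrands are piecewise linear with clamps, so the midpoint rule
# on a dense grid is exact up to the handful of cells containing a kink.
expected_reward_det <- function(a, b, proto, n_grid = 8192L) {
  M <- .M_RANGE; D <- .D_RANGE
  alpha <- a - 1; beta <- a + 1
  h <- D / n_grid
  # possible trials: correct = respond 1 when d > 0, respond 0 when d < 0
  dp <- (seq_len(n_grid) - 0.5) * h
  int_pos <- h * sum(.len_respond1(alpha, beta, b, dp, M))
  int_neg <- h * sum(2 * M - .len_respond1(alpha, beta, b, -dp, M))
  e_poss <- (int_pos + int_neg) / (2 * M * 2 * D)

  # impossible trials: A = 1{alpha*m - b > 0}, reward prob jumps at m = 0;
  # piecewise constant in m, so the interval decomposition is exact
  cuts <- c(-M, 0, M)
  if (alpha != 0) {
    t0 <- b / alpha
    if (t0 > -M && t0 < M) cuts <- sort(c(cuts, t0))
  }
  e_imp <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    mid <- (cuts[i] + cuts[i + 1L]) / 2
    A <- as.numeric(alpha * mid - b > 0)
    q <- if (mid < 0) proto$p_reward_f1gt_low else proto$p_reward_f1gt_high
    e_imp <- e_imp + (cuts[i + 1L] - cuts[i]) * (A * q + (1 - A) * (1 - q))
  }
  e_imp <- e_imp / (2 * M)

  c(poss = e_poss, imp = e_imp)
}

expected_reward_parts <- function(a, b, sigma, proto) {
  det <- sigma == 0 | a == 0
  poss <- numeric(length(a)); imp <- numeric(length(a))
  if (any(!det)) {
    sm <- expected_reward_smooth(a[!det], b[!det], sigma, proto)
    poss[!det] <- sm$poss; imp[!det] <- sm$imp
  }
  if (any(det)) {
    dt <- mapply(expected_reward_det, a[det], b[det],
                 MoreArgs = list(proto = proto))
    poss[det] <- dt["poss", ]; imp[det] <- dt["imp", ]
  }
  list(poss = poss, imp = imp)
}

expected_reward_many <- function(a, b, sigma, proto) {
  parts <- expected_reward_parts(a, b, sigma, proto)
  0.75 * parts$poss + 0.25 * parts$imp
}

#' Expected accuracy on possible trials
#'
#' The probability that a Perceptron's response matches the veridical
#' ordering of the two frequencies, integrated over the possible-trial
#' stimulus distribution (`m ~ U(-0.2, 0.2)`, `d ~ U(-0.0905, 0.0905)`).
#' This is the component of [expected_reward()] that feedback protocols
#' cannot alter.
#'
#' @inheritParams expected_reward
#' @return Expected fraction correct on possible trials.
#' @examples
#' possible_accuracy(1, 0, 0)  # 1: noiseless veridical discriminator
#' @export
possible_accuracy <- function(a, b, sigma) {
  stopifnot(length(a) == 1L, length(b) == 1L, sigma >= 0)
  expected_reward_parts(a, b, sigma, feedback_protocol("control"))$poss
}

#' Expected feedback rate of a Perceptron under a protocol
#'
#' The probability, over stimuli, representation noise and reward draws,
#' that a response earns "correct" feedback:
#' `0.75 * E[correct | possible] + 0.25 * E[rewarded | impossible]`, with
#' possible-trial stimuli integrated over `m ~ U(-0.2, 0.2)`,
#' `d ~ U(-0.0905, 0.0905)` and impossible-trial reward probabilities taken
#' from the protocol's contingency table. Deterministic quadrature
#' (tensor-product Gauss-Legendre, split at the integrand's kinks) is used
#' throughout; the `sigma == 0` and `a == 0` cases use exact geometry of
#' the deterministic decision regions.
#'
#' @param a,b,sigma Perceptron parameters (scalars).
#' @param protocol Protocol name or [feedback_protocol()] object.
#' @return Expected feedback rate in (0, 1).
#' @examples
#' expected_reward(1, 0, 0, "control")  # 0.875: perfect on the 75% possible
#' @export
expected_reward <- function(a, b, sigma, protocol) {
  proto <- feedback_protocol(protocol)
  stopifnot(length(a) == 1L, length(b) == 1L, length(sigma) == 1L,
            is.finite(a), is.finite(b), sigma >= 0)
  expected_reward_many(a, b, sigma, proto)
}

#' Reward-optimal Perceptron parameters for a protocol
#'
#' Deterministic coarse-to-fine grid search for the `(a, b)` maximising
#' [expected_reward()] over the box `a` in [-0.5, 2], `b` in [-0.3, 0.3].
#' Each stage evaluates a 13 x 13 grid and shrinks the box to one grid cell
#' around the maximiser, until both box widths fall below `tol`. No
#' randomness is involved; repeated calls are identical.
#'
#' @param sigma Representation-noise SD (>= 0).
#' @param protocol Protocol name or object.
#' @param box_a,box_b Search intervals.
#' @param tol Terminal box width (default 1e-3).
#' @return List with `a`, `b`, `value` (the achieved expected reward),
#'   `sigma` and `protocol`.
#' @examples
#' \donttest{optimize_params(0, "control")  # a = 1, b = 0}
#' @export
optimize_params <- function(sigma, protocol, box_a = c(-0.5, 2),
                            box_b = c(-0.3, 0.3), tol = 1e-3) {
  proto <- feedback_protocol(protocol)
  stopifnot(sigma >= 0)
  lo_a <- box_a[1]; hi_a <- box_a[2]
  lo_b <- box_b[1]; hi_b <- box_b[2]
  n <- 13L
  repeat {
    ga <- seq(lo_a, hi_a, length.out = n)
    gb <- seq(lo_b, hi_b, length.out = n)
    aa <- rep(ga, times = n)
    bb <- rep(gb, each = n)
    val <- expected_reward_many(aa, bb, sigma, proto)
    best <- which.max(val)
    a_star <- aa[best]; b_star <- bb[best]
    if ((hi_a - lo_a) < tol && (hi_b - lo_b) < tol) {
      return(list(a = a_star, b = b_star, value = val[best],
                  sigma = sigma, protocol = proto$name))
    }
    step_a <- ga[2] - ga[1]; step_b <- gb[2] - gb[1]
    lo_a <- max(box_a[1], a_star - step_a); hi_a <- min(box_a[2], a_star + step_a)
    lo_b <- max(box_b[1], b_star - step_b); hi_b <- min(box_b[2], b_star + step_b)
  }
}

#' Accuracy of a Perceptron by quadrant of the f1 x f2 plane
#'
#' Splits the possible-trial stimulus distribution at 1 kHz on both axes
#' and reports the expected fraction of correct responses in each quadrant,
#' computed on a dense midpoint grid over `(m, d)`. Quadrants receiving no
#' stimulus mass are flagged with `NA`.
#'
#' @param params A [perceptron_params()] object.
#' @param n_grid Grid resolution per dimension (default 401).
#' @return Named numeric vector of accuracies for quadrants
#'   `f1_low_f2_low`, `f1_high_f2_low`, `f1_low_f2_high`,
#'   `f1_high_f2_high`, with an attribute `mass` giving each quadrant's
#'   probability mass.
#' @examples
#' quadrant_accuracy(perceptron_params(0, 0, 0.1))
#' @export
quadrant_accuracy <- function(params, n_grid = 401L) {
  M <- .M_RANGE; D <- .D_RANGE
  hm <- 2 * M / n_grid; hd <- 2 * D / n_grid
  m <- -M + (seq_len(n_grid) - 0.5) * hm
  d <- -D + (seq_len(n_grid) - 0.5) * hd
  mm <- rep(m, times = n_grid)
  dd <- rep(d, each = n_grid)
  s1 <- mm + dd; s2 <- mm - dd
  keep <- s1 != 0 & s2 != 0 & dd != 0
  s1 <- s1[keep]; s2 <- s2[keep]; dd <- dd[keep]
  p <- response_probability(params, s1, s2)
  correct <- ifelse(dd > 0, p, 1 - p)
  quad <- paste0(ifelse(s1 > 0, "f1_high", "f1_low"), "_",
                 ifelse(s2 > 0, "f2_high", "f2_low"))
  levels <- c("f1_low_f2_low", "f1_high_f2_low", "f1_low_f2_high",
              "f1_high_f2_high")
  quad <- factor(quad, levels = levels)
  acc <- tapply(correct, quad, mean)
  mass <- as.numeric(table(quad)) / length(correct)
  out <- as.numeric(acc)
  names(out) <- levels
  attr(out, "mass") <- stats::setNames(mass, levels)
  out
}

#' Response-probability surface over a stimulus grid
#'
#' Evaluates [response_probability()] on the tensor grid `f1 x f2`. The
#' level set at probability 0.5 (the line of indifference) has slope `a`
#' in (log f1, log f2) coordinates and intercept set by `b`; contraction
#' bias (`a < 1`) tilts it away from the diagonal, choice bias shifts it
#' in parallel.
#'
#' @param params A [perceptron_params()] object.
#' @param f1,f2 Frequency grids in Hz (default: 41 log-spaced points
#'   spanning the stimulus rectangle).
#' @return Matrix of probabilities with `f1` on rows (dimnames carry the
#'   frequencies).
#' @export
response_surface <- function(params,
                             f1 = 1000 * exp(seq(-0.2905, 0.2905,
                                                 length.out = 41L)),
                             f2 = f1) {
  s1 <- log(f1 / 1000)
  s2 <- log(f2 / 1000)
  out <- outer(s1, s2, function(x, y) response_probability(params, x, y))
  dimnames(out) <- list(f1 = sprintf("%.1f", f1), f2 = sprintf("%.1f", f2))
  out
}
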