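#' Observer specification
#'
#' Describes a synthetic observer. `kind = "static"` fixes `(a, b, sigma)`
#' for the whole block. `kind = "adaptive_b"` additionally updates the
#' decision criterion after each trial with a reward-following delta rule,
#' `b <- b - eta * (2*feedback - 1) * (2*response - 1)`, so that rewarded
#' responses become more likely and punished ones less likely; `a` and
#' `sigma` never change. With `learning_rate = 0` the adaptive observer
#' reduces exactly to the static one. The delta rule is deliberately
#' minimal plumbing for generating criterion-drift dynamics; it is not a
#' claim about the learning mechanism.
#'
#' @param kind `"static"` or `"adaptive_b"`.
#' @param a,b,sigma Perceptron parameters (initial values for adaptive
#'   observers).
#' @param learning_rate Criterion step size `eta >= 0` (adaptive only).
#' @param seed Integer seed for the observer's noise stream.
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(kind = c("static", "adaptive_b"), a = 1, b = 0,
                          sigma = 0.1, learning_rate = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.finite(a), is.finite(b), sigma >= 0, learning_rate >= 0)
  structure(list(kind = kind,
                 params = perceptron_params(a, b, sigma),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "observer_spec")
}

#' Simulate a static Perceptron observer on a trial block
#'
#' Per trial, draws representation noise `n ~ N(0, sigma^2)` for the first
#' stimulus, forms `r1 = s1 + n`, `r2 = s2`, applies the decision rule and
#' assigns feedback according to the block's protocol. Seeded and
#' bit-reproducible.
#'
#' @param spec An [observer_spec()] of kind `"static"`.
#' @param log A `trial_log` without responses (from [generate_block()]).
#' @return The `trial_log` with `response` and `feedback` filled in; the
#'   generating parameters are attached as attribute `"observer"`.
#' @export
simulate_static_observer <- function(spec, log) {
  stopifnot(inherits(spec, "observer_spec"), spec$kind == "static",
            inherits(log, "trial_log"))
  par <- spec$params
  noise <- with_seed(spec$seed, rnorm(nrow(log), 0, par$sigma))
  dec <- decide(par, log$s1 + noise, log$s2)
  log$response <- dec$A
  log$feedback <- assign_feedback(attr(log, "protocol"), log, dec$A)
  attr(log, "observer") <- list(kind = "static", a = par$a, b = par$b,
                                sigma = par$sigma, seed = spec$seed)
  log
}

#' Simulate a criterion-adaptive observer
#'
#' As [simulate_static_observer()], but after each trial the criterion is
#' updated with the reward-following delta rule described in
#' [observer_spec()]. Only `b` adapts; the contraction weight `a` and the
#' noise `sigma` stay fixed, mirroring the empirical dissociation between
#' the feedback sensitivity of the two biases.
#'
#' @param spec An [observer_spec()] of kind `"adaptive_b"` (or `"static"`,
#'   treated as `learning_rate = 0`).
#' @param protocol Protocol for the generated block (ignored if `log` is
#'   supplied).
#' @param n_trials Block length (ignored if `log` is supplied).
#' @param seed Seed for the noise stream; when no `log` is supplied, the
#'   block itself is generated with the derived seed `child_seed(seed, 1)`.
#' @param log Optionally, a pre-generated `trial_log` to respond to.
#' @return The `trial_log` with responses, feedback, and a `b_trajectory`
#'   attribute (criterion value before each trial, length `n_trials + 1`).
#' @export
simulate_adaptive_observer <- function(spec, protocol = "control",
                                       n_trials = 220L, seed = spec$seed,
                                       log = NULL) {
  stopifnot(inherits(spec, "observer_spec"))
  if (is.null(log)) {
    log <- generate_block(protocol, n_trials, seed = child_seed(seed, 1L))
  }
  par <- spec$params
  eta <- spec$learning_rate
  n <- nrow(log)
  noise <- with_seed(seed, rnorm(n, 0, par$sigma))
  b <- par$b
  b_traj <- numeric(n + 1L)
  response <- integer(n)
  feedback <- integer(n)
  s1 <- log$s1; s2 <- log$s2
  imp <- log$is_impossible; rr <- log$rewarded_response_draw
  for (t in seq_len(n)) {
    b_traj[t] <- b
    h <- par$a * (s1[t] + noise[t]) - s2[t] - b
    A <- as.integer(h > 0)
    fb <- if (imp[t]) as.integer(A == rr[t]) else as.integer(A == (s1[t] > s2[t]))
    b <- b - eta * (2 * fb - 1) * (2 * A - 1)
    response[t] <- A
    feedback[t] <- fb
  }
  b_traj[n + 1L] <- b
  log$response <- response
  log$feedback <- feedback
  attr(log, "observer") <- list(kind = "adaptive_b", a = par$a, b0 = par$b,
                                sigma = par$sigma, learning_rate = eta,
                                seed = seed)
  attr(log, "b_trajectory") <- b_traj
  log
}

#' Cohort specification
#'
#' @param n_observers Number of observers (>= 1).
#' @param protocol Feedback protocol administered to the cohort.
#' @param observer_kind `"static"` or `"adaptive_b"`.
#' @param sigma_distribution Named distribution for per-observer noise:
#'   `list(dist = "lognormal", meanlog = log(0.08), sdlog = 0.5)` (default,
#'   a stand-in population centred on a median of 0.08 log units),
#'   `list(dist = "fixed", value = sigma)`, or
#'   `list(dist = "uniform", min = , max = )` (min > 0).
#' @param a First-stimulus weight for every observer, or the string
#'   `"optimal"` to give each observer the reward-optimal `(a, b)` for its
#'   own `sigma` under the cohort's protocol.
#' @param b Initial criterion (ignored when `a = "optimal"`).
#' @param learning_rate Criterion step size (adaptive kind only).
#' @param n_trials Trials per block.
#' @param master_seed Seed from which all per-observer seeds are derived.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_observers, protocol = "control",
                        observer_kind = c("static", "adaptive_b"),
                        sigma_distribution = list(dist = "lognormal",
                                                  meanlog = log(0.08),
                                                  sdlog = 0.5),
                        a = 1, b = 0, learning_rate = 0,
                        n_trials = 220L, master_seed = 1L) {
  observer_kind <- match.arg(observer_kind)
  stopifnot(n_observers >= 1)
  if (is.null(sigma_distribution$dist) ||
      !sigma_distribution$dist %in% c("lognormal", "fixed", "uniform")) {
    stop("sigma_distribution$dist must be one of 'lognormal', 'fixed', ",
         "'uniform'", call. = FALSE)
  }
  if (sigma_distribution$dist == "fixed" &&
      (is.null(sigma_distribution$value) || sigma_distribution$value <= 0)) {
    stop("fixed sigma_distribution needs a positive 'value'", call. = FALSE)
  }
  if (sigma_distribution$dist == "uniform" &&
      (is.null(sigma_distribution$min) || sigma_distribution$min <= 0 ||
       sigma_distribution$max <= sigma_distribution$min)) {
    stop("uniform sigma_distribution needs 0 < min < max", call. = FALSE)
  }
  structure(list(n_observers = as.integer(n_observers),
                 protocol = feedback_protocol(protocol)$name,
                 observer_kind = observer_kind,
                 sigma_distribution = sigma_distribution,
                 a = a, b = b, learning_rate = learning_rate,
                 n_trials = as.integer(n_trials),
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

sample_sigmas <- function(dist, n, seed) {
  with_seed(seed, switch(dist$dist,
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
    fixed = rep(dist$value, n),
    uniform = runif(n, dist$min, dist$max)))
}

#' Simulate a cohort of observers
#'
#' Generates one trial block and one simulated observer per cohort member.
#' Per-observer seeds are derived deterministically from the master seed
#' (`child_seed(master_seed, 2*i)` for the block,
#' `child_seed(master_seed, 2*i + 1)` for the noise stream) and recorded in
#' the manifest, so the whole cohort is bit-reproducible.
#'
#' @param cohort A [cohort_spec()].
#' @return A list of class `observer_cohort` with `logs` (list of
#'   `trial_log`s with responses) and `manifest` (data frame of true
#'   parameters and seeds, for parameter-recovery studies).
#' @export
simulate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n <- cohort$n_observers
  sigmas <- sample_sigmas(cohort$sigma_distribution, n,
                          child_seed(cohort$master_seed, 0L))
  if (identical(cohort$a, "optimal")) {
    # one optimisation per distinct noise level
    uniq <- unique(sigmas)
    opts <- lapply(uniq, optimize_params, protocol = cohort$protocol)
    names(opts) <- sprintf("%.15g", uniq)
  }
  logs <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    block_seed <- child_seed(cohort$master_seed, 2L * i)
    noise_seed <- child_seed(cohort$master_seed, 2L * i + 1L)
    obs_id <- sprintf("obs%03d", i)
    if (identical(cohort$a, "optimal")) {
      opt <- opts[[sprintf("%.15g", sigmas[i])]]
      a_i <- opt$a; b_i <- opt$b
    } else {
      a_i <- cohort$a; b_i <- cohort$b
    }
    blk <- generate_block(cohort$protocol, cohort$n_trials,
                          seed = block_seed, observer_id = obs_id)
    spec <- observer_spec(cohort$observer_kind, a = a_i, b = b_i,
                          sigma = sigmas[i],
                          learning_rate = cohort$learning_rate,
                          seed = noise_seed)
    logs[[i]] <- if (cohort$observer_kind == "static") {
      simulate_static_observer(spec, blk)
    } else {
      simulate_adaptive_observer(spec, log = blk, seed = noise_seed)
    }
    rows[[i]] <- data.frame(observer_id = obs_id,
                            kind = cohort$observer_kind,
                            protocol = cohort$protocol,
                            true_a = a_i, true_b0 = b_i,
                            true_sigma = sigmas[i],
                            learning_rate = cohort$learning_rate,
                            seed = noise_seed, block_seed = block_seed)
  }
  structure(list(logs = logs, manifest = do.call(rbind, rows),
                 spec = cohort),
            class = "observer_cohort")
}

#' @export
print.observer_cohort <- function(x, ...) {
  cat(sprintf("Observer cohort: %d %s observers, protocol '%s', %d trials each\n",
              length(x$logs), x$spec$observer_kind, x$spec$protocol,
              x$spec$n_trials))
  cat(sprintf("  sigma: median %.3f (range %.3f-%.3f)\n",
              stats::median(x$manifest$true_sigma),
              min(x$manifest$true_sigma), max(x$manifest$true_sigma)))
  invisible(x)
}
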