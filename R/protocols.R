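#' Feedback protocols for impossible trials
#'
#' The experiment manipulates feedback only on "impossible" trials
#' (`f1 == f2`), where no veridical answer exists. A protocol is defined by
#' the probability that the response "f1 > f2" is declared correct when the
#' common frequency lies below, respectively above, the 1 kHz median of the
#' stimulus distribution. Possible trials always receive veridical feedback.
#'
#' Five named protocols are available:
#' \describe{
#'   \item{control}{(0.5, 0.5) — unbiased random feedback.}
#'   \item{enhance_f1gt}{(0.9, 0.9) — rewards "f1 > f2" regardless of range.}
#'   \item{suppress_f1gt}{(0.1, 0.1) — rewards "f1 < f2" regardless of range.}
#'   \item{enhance_contraction}{(0.9, 0.1) — rewards responses congruent with
#'     contraction bias ("f1 > f2" below the median, "f1 < f2" above it).}
#'   \item{suppress_contraction}{(0.1, 0.9) — rewards anti-contraction
#'     responses.}
#' }
#'
#' @param name Protocol name (one of the five above), or an existing
#'   `feedback_protocol` object, which is returned unchanged.
#' @return An object of class `feedback_protocol`: a list with elements
#'   `name`, `p_reward_f1gt_low` and `p_reward_f1gt_high`.
#' @examples
#' feedback_protocol("enhance_contraction")
#' @export
feedback_protocol <- function(name) {
  if (inherits(name, "feedback_protocol")) return(name)
  table <- list(
    control              = c(0.5, 0.5),
    enhance_f1gt         = c(0.9, 0.9),
    suppress_f1gt        = c(0.1, 0.1),
    enhance_contraction  = c(0.9, 0.1),
    suppress_contraction = c(0.1, 0.9)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(table)) {
    stop("unknown feedback protocol ", deparse(substitute(name)), "; valid names: ",
         paste(names(table), collapse = ", "), call. = FALSE)
  }
  p <- table[[name]]
  structure(list(name = name,
                 p_reward_f1gt_low = p[1],
                 p_reward_f1gt_high = p[2]),
            class = "feedback_protocol")
}

#' @export
print.feedback_protocol <- function(x, ...) {
  cat("Feedback protocol:", x$name, "\n")
  cat(sprintf("  P(reward 'f1>f2' | impossible, f < 1 kHz) = %.2f\n",
              x$p_reward_f1gt_low))
  cat(sprintf("  P(reward 'f1>f2' | impossible, f > 1 kHz) = %.2f\n",
              x$p_reward_f1gt_high))
  invisible(x)
}

#' Names of the available feedback protocols
#' @return Character vector of the five protocol names.
#' @export
protocol_names <- function() {
  c("control", "enhance_f1gt", "suppress_f1gt",
    "enhance_contraction", "suppress_contraction")
}

# Canonical log-unit derivation from frequencies in Hz. Re-symmetrises via
# (m, d) so that s1 == m + d and s2 == m - d hold bit-exactly, and so that
# f1 == f2 implies d == 0 exactly.
derive_log_units <- function(f1_hz, f2_hz) {
  s1 <- log(f1_hz / 1000)
  s2 <- log(f2_hz / 1000)
  m <- (s1 + s2) / 2
  d <- (s1 - s2) / 2
  data.frame(s1 = m + d, s2 = m - d, m = m, d = d)
}

new_trial_log <- function(df, protocol, observer_id = "obs1", seed = NA_integer_) {
  units <- derive_log_units(df$f1_hz, df$f2_hz)
  df$s1 <- units$s1; df$s2 <- units$s2; df$m <- units$m; df$d <- units$d
  structure(df,
            protocol = protocol,
            observer_id = observer_id,
            seed = seed,
            class = c("trial_log", "data.frame"))
}

#' @export
print.trial_log <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Trial log: %d trials (%d impossible), protocol '%s', observer '%s'\n",
              n, sum(x$is_impossible), attr(x, "protocol"), attr(x, "observer_id")))
  if (all(is.na(x$response))) {
    cat("  responses: absent (stimuli only)\n")
  } else {
    poss <- !x$is_impossible & !is.na(x$response)
    acc <- mean(x$response[poss] == as.integer(x$s1[poss] > x$s2[poss]))
    cat(sprintf("  accuracy on possible trials: %.3f\n", acc))
  }
  invisible(x)
}

#' Generate a block of delayed-comparison trials
#'
#' Draws a block with the task's stimulus statistics: the mean log frequency
#' `m = (log f1 + log f2)/2 - log 1000` is uniform on (-0.2, 0.2); on
#' possible trials (75%) the half-difference `d = (log f1 - log f2)/2` is
#' uniform on (-0.0905, 0.0905); on the remaining 25% of trials ("impossible"
#' trials) `f1 == f2` exactly. The count of impossible trials is exactly
#' `round(0.25 * n_trials)` and their positions are uniformly shuffled. For
#' each impossible trial the response that will be rewarded is pre-drawn
#' according to the protocol's contingency and the side of the 1 kHz median.
#'
#' @param protocol Protocol name or [feedback_protocol()] object.
#' @param n_trials Number of trials; must be a positive multiple of 4 so the
#'   75/25 split is exact. Default 220.
#' @param seed Integer seed; identical inputs produce bit-identical blocks.
#' @param observer_id Identifier stored in the log.
#' @return A `trial_log` data frame (one row per trial) with columns
#'   `trial_index`, `f1_hz`, `f2_hz`, `is_impossible`,
#'   `rewarded_response_draw`, `response`, `feedback` (the latter two `NA`
#'   until an observer is simulated) and derived log-unit columns `s1`,
#'   `s2`, `m`, `d`.
#' @examples
#' blk <- generate_block("control", n_trials = 20, seed = 1)
#' sum(blk$is_impossible)  # exactly 5
#' @export
generate_block <- function(protocol, n_trials = 220L, seed,
                           observer_id = "obs1") {
  proto <- feedback_protocol(protocol)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials <= 0 ||
      n_trials != as.integer(n_trials)) {
    stop("n_trials must be a positive integer", call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  if (n_trials %% 4L != 0L) {
    stop("n_trials must be divisible by 4 so that the 75/25 ",
         "possible/impossible split is exact", call. = FALSE)
  }
  if (missing(seed)) stop("seed must be supplied", call. = FALSE)
  n_imp <- as.integer(round(0.25 * n_trials))

  with_seed(seed, {
    flags <- rep(FALSE, n_trials)
    flags[sample.int(n_trials, n_imp)] <- TRUE
    m <- runif(n_trials, -.M_RANGE, .M_RANGE)
    # keep "below/above 1 kHz" defined on impossible trials: exclude a
    # 1e-6-wide sliver around the median
    bad <- flags & abs(m) < 5e-7
    while (any(bad)) {
      m[bad] <- runif(sum(bad), -.M_RANGE, .M_RANGE)
      bad <- flags & abs(m) < 5e-7
    }
    d <- numeric(n_trials)
    d[!flags] <- runif(sum(!flags), -.D_RANGE, .D_RANGE)
    zero <- !flags & d == 0
    while (any(zero)) {
      d[zero] <- runif(sum(zero), -.D_RANGE, .D_RANGE)
      zero <- !flags & d == 0
    }
    rr <- rep(NA_integer_, n_trials)
    p_rew <- ifelse(m < 0, proto$p_reward_f1gt_low, proto$p_reward_f1gt_high)
    rr[flags] <- rbinom(n_imp, 1L, p_rew[flags])
  })

  f1 <- 1000 * exp(m + d)
  f2 <- 1000 * exp(m - d)
  df <- data.frame(trial_index = seq_len(n_trials),
                   f1_hz = f1, f2_hz = f2,
                   is_impossible = flags,
                   rewarded_response_draw = rr,
                   response = NA_integer_,
                   feedback = NA_integer_)
  new_trial_log(df, protocol = proto$name, observer_id = observer_id,
                seed = as.integer(seed))
}

#' Assign feedback to responses
#'
#' On possible trials feedback is veridical: the response is "correct" iff
#' it matches the sign of `s1 - s2`. On impossible trials the response is
#' "correct" iff it equals the pre-drawn rewarded response, which was
#' sampled with probability `p_reward_f1gt_low` (stimulus below 1 kHz) or
#' `p_reward_f1gt_high` (above) of rewarding "f1 > f2".
#'
#' @param protocol Protocol name or object (used only for validation; the
#'   reward draw itself is stored in the trial).
#' @param trial A `trial_log` (any number of rows) or a one-row data frame
#'   with columns `s1`, `s2`, `m`, `is_impossible`, `rewarded_response_draw`.
#' @param response Integer vector in \{0, 1\} (1 = "f1 > f2"), recycled to
#'   the number of trials.
#' @return Integer vector of feedback values (1 = "correct" face shown).
#' @export
assign_feedback <- function(protocol, trial, response) {
  feedback_protocol(protocol)  # validates the name
  if (!all(response %in% c(0L, 1L))) {
    stop("response must be 0 or 1", call. = FALSE)
  }
  response <- as.integer(response)
  if (length(response) == 1L) response <- rep(response, nrow(trial))
  stopifnot(length(response) == nrow(trial))
  imp <- trial$is_impossible
  if (any(imp & trial$m == 0)) {
    stop("impossible trial with m = 0 exactly: side of the 1 kHz median is ",
         "undefined", call. = FALSE)
  }
  if (any(imp & is.na(trial$rewarded_response_draw))) {
    stop("impossible trial without a pre-drawn rewarded response", call. = FALSE)
  }
  fb <- integer(nrow(trial))
  fb[!imp] <- as.integer(response[!imp] ==
                           as.integer(trial$s1[!imp] > trial$s2[!imp]))
  fb[imp] <- as.integer(response[imp] == trial$rewarded_response_draw[imp])
  fb
}

#' Participant-exclusion test
#'
#' A block is kept only if performance on the possible trials differs
#' significantly from chance in both halves of the block (first and second
#' `n/2` trials), by an exact two-sided binomial test against success
#' probability 0.5. With 82 possible trials per half this reproduces the
#' conventional "at least 62% correct" screening threshold.
#'
#' @param log A `trial_log` with responses for all trials.
#' @param alpha Significance level (default 0.05).
#' @return A list with `decision` ("keep" or "exclude"), `p_first`,
#'   `p_second`, and the per-half possible-trial counts and accuracies.
#' @export
exclusion_test <- function(log, alpha = 0.05) {
  if (any(is.na(log$response))) {
    stop("exclusion_test requires responses for all trials", call. = FALSE)
  }
  n <- nrow(log)
  half <- n %/% 2L
  halves <- list(seq_len(half), seq.int(half + 1L, n))
  res <- lapply(halves, function(idx) {
    sub <- log[idx, , drop = FALSE]
    poss <- !sub$is_impossible
    np <- sum(poss)
    if (np == 0L) {
      stop("a half-block contains no possible trials; the exclusion test ",
           "is undefined", call. = FALSE)
    }
    k <- sum(sub$response[poss] == as.integer(sub$s1[poss] > sub$s2[poss]))
    list(p = binom.test(k, np, p = 0.5,
                        alternative = "two.sided")$p.value,
         n_possible = np, n_correct = k)
  })
  keep <- res[[1]]$p < alpha && res[[2]]$p < alpha
  list(decision = if (keep) "keep" else "exclude",
       p_first = res[[1]]$p, p_second = res[[2]]$p,
       n_possible = c(res[[1]]$n_possible, res[[2]]$n_possible),
       n_correct = c(res[[1]]$n_correct, res[[2]]$n_correct),
       alpha = alpha)
}

#' Minimal fraction correct that passes the exclusion screen
#'
#' For a half-block with `n` possible trials, the smallest number of correct
#' responses `k > n/2` whose exact two-sided binomial p-value is below
#' `alpha`, returned with the corresponding fraction.
#'
#' @param n Number of possible trials in the half-block.
#' @param alpha Significance level (default 0.05).
#' @return List with `k_min` and `fraction` (`k_min / n`).
#' @export
min_passing_fraction <- function(n, alpha = 0.05) {
  ks <- seq.int(ceiling(n / 2), n)
  p <- vapply(ks, function(k) binom.test(k, n, 0.5)$p.value, numeric(1))
  k_min <- ks[which(p < alpha)[1]]
  list(k_min = k_min, fraction = k_min / n)
}
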