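#' Assign stimulus-range regions
#'
#' Partitions trials into low (I), intermediate (II) and high (III)
#' frequency ranges by the mean log frequency `m`, using terciles of the
#' design range by default: I for `m < -0.2/3`, III for `m > 0.2/3`, II in
#' between. The low range is where contraction bias favours "f1 > f2", the
#' high range the opposite.
#'
#' @param x A `trial_log`, a data frame with an `m` column, or a numeric
#'   vector of `m` values.
#' @param boundaries Length-2 numeric vector of region boundaries.
#' @return Factor with levels `I`, `II`, `III`.
#' @export
assign_region <- function(x, boundaries = c(-.M_RANGE / 3, .M_RANGE / 3)) {
  m <- if (is.numeric(x)) x else x$m
  stopifnot(length(boundaries) == 2L, boundaries[1] < boundaries[2])
  factor(ifelse(m < boundaries[1], "I",
                ifelse(m > boundaries[2], "III", "II")),
         levels = c("I", "II", "III"))
}

as_log_list <- function(logs) {
  if (inherits(logs, "observer_cohort")) return(logs$logs)
  if (inherits(logs, "trial_log")) return(list(logs))
  stopifnot(is.list(logs), all(vapply(logs, inherits, logical(1), "trial_log")))
  logs
}

#' Binned psychometric curve
#'
#' Proportion of "f1 > f2" responses as a function of the log-frequency
#' difference `delta = s1 - s2`, built from possible trials only, binned
#' into `n_bins` equal-width bins spanning the design range of `delta`.
#' Cross-observer aggregation averages per-observer proportions (never
#' pools trials) and reports the cross-observer SEM.
#'
#' @param logs A `trial_log`, list of them, or an `observer_cohort`.
#' @param region `"all"` or one of `"I"`, `"II"`, `"III"`.
#' @param n_bins Number of bins (default 9).
#' @param boundaries Region boundaries passed to [assign_region()].
#' @return An object of class `psychometric_curve`: data frame with
#'   `bin_center`, `prop`, `sem`, `n_trials`, `n_observers`; attribute
#'   `empty` flags a region with no trials.
#' @export
psychometric_curve <- function(logs, region = "all", n_bins = 9L,
                               boundaries = c(-.M_RANGE / 3, .M_RANGE / 3)) {
  logs <- as_log_list(logs)
  stopifnot(region %in% c("all", "I", "II", "III"))
  br <- seq(-2 * .D_RANGE, 2 * .D_RANGE, length.out = n_bins + 1L)
  centers <- (head(br, -1) + tail(br, -1)) / 2
  per_obs <- lapply(logs, function(log) {
    if (any(is.na(log$response))) {
      stop("psychometric_curve requires responses", call. = FALSE)
    }
    poss <- log[!log$is_impossible, ]
    if (region != "all") {
      poss <- poss[assign_region(poss, boundaries) == region, ]
    }
    if (nrow(poss) == 0L) return(NULL)
    bin <- cut(poss$s1 - poss$s2, br, include.lowest = TRUE)
    list(prop = tapply(poss$response, bin, mean),
         n = as.numeric(table(bin)))
  })
  per_obs <- per_obs[!vapply(per_obs, is.null, logical(1))]
  if (length(per_obs) == 0L) {
    out <- data.frame(bin_center = centers, prop = NA_real_, sem = NA_real_,
                      n_trials = 0, n_observers = 0)
    class(out) <- c("psychometric_curve", "data.frame")
    attr(out, "empty") <- TRUE
    attr(out, "region") <- region
    return(out)
  }
  props <- do.call(cbind, lapply(per_obs, `[[`, "prop"))
  ns <- do.call(cbind, lapply(per_obs, `[[`, "n"))
  n_obs <- rowSums(!is.na(props))
  mean_prop <- rowMeans(props, na.rm = TRUE)
  sem <- apply(props, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  })
  out <- data.frame(bin_center = centers, prop = mean_prop, sem = sem,
                    n_trials = rowSums(ns), n_observers = n_obs)
  class(out) <- c("psychometric_curve", "data.frame")
  attr(out, "empty") <- FALSE
  attr(out, "region") <- region
  out
}

#' Fit a cumulative-normal sigmoid to choice data
#'
#' Maximum-likelihood fit of the two-parameter psychometric function
#' `P("f1>f2") = Phi((delta - midpoint) / slope)`, by a deterministic
#' coarse grid over (midpoint, log slope) followed by Nelder-Mead
#' refinement from the grid optimum. Accepts either raw Bernoulli trials
#' or a binned [psychometric_curve()] (fitted by count-weighted binomial
#' likelihood of the bin proportions).
#'
#' @param x A `psychometric_curve`, or a data frame with columns `delta`
#'   and `response` (0/1), or a `trial_log` (possible trials are used).
#' @return An object of class `sigmoid_fit`: list with `midpoint`, `slope`,
#'   `value_at_0` (fitted probability at `delta = 0`), `loglik` and
#'   `degenerate` (TRUE when all responses are identical, in which case
#'   `value_at_0` is the empirical proportion and the curve parameters are
#'   `NA`).
#' @export
fit_sigmoid <- function(x) {
  if (inherits(x, "psychometric_curve")) {
    keep <- !is.na(x$prop) & x$n_trials > 0
    delta <- x$bin_center[keep]
    succ <- x$prop[keep] * x$n_trials[keep]
    n <- x$n_trials[keep]
  } else {
    if (inherits(x, "trial_log")) {
      poss <- x[!x$is_impossible, ]
      x <- data.frame(delta = poss$s1 - poss$s2, response = poss$response)
    }
    stopifnot(all(c("delta", "response") %in% names(x)))
    delta <- x$delta
    succ <- as.numeric(x$response)
    n <- rep(1, length(delta))
  }
  if (length(delta) == 0L) stop("no data to fit", call. = FALSE)
  phat <- sum(succ) / sum(n)
  if (phat == 0 || phat == 1) {
    return(structure(list(midpoint = NA_real_, slope = NA_real_,
                          value_at_0 = phat, loglik = 0, degenerate = TRUE),
                     class = "sigmoid_fit"))
  }
  eps <- 1e-9
  nll <- function(par) {
    p <- pnorm((delta - par[1]) / exp(par[2]))
    p <- pmin(pmax(p, eps), 1 - eps)
    -sum(succ * base::log(p) + (n - succ) * base::log(1 - p))
  }
  mids <- seq(-0.2, 0.2, length.out = 41L)
  lslopes <- seq(base::log(0.002), base::log(0.5), length.out = 41L)
  grid <- expand.grid(mid = mids, lslope = lslopes)
  vals <- mapply(function(m, s) nll(c(m, s)), grid$mid, grid$lslope)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  midpoint <- opt$par[1]; slope <- exp(opt$par[2])
  structure(list(midpoint = midpoint, slope = slope,
                 value_at_0 = pnorm(-midpoint / slope),
                 loglik = -opt$value, degenerate = FALSE),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Sigmoid fit: degenerate (all responses identical); P(0) = %.3f\n",
                x$value_at_0))
  } else {
    cat(sprintf("Sigmoid fit: midpoint %.4f, slope %.4f, P(0) = %.3f\n",
                x$midpoint, x$slope, x$value_at_0))
  }
  invisible(x)
}

#' Contraction-bias magnitude
#'
#' Quantifies contraction bias as the vertical distance, at `delta = 0`
#' (i.e. `f1 = f2`), between the psychometric curves of the low (I) and
#' high (III) frequency ranges: sigmoids are fitted to pooled possible
#' trials of each region and evaluated at zero. The same contrast computed
#' directly from impossible-trial response fractions (per observer, then
#' averaged) is reported alongside as a cross-validation, and the
#' region-II midpoint is reported as the choice-bias summary.
#'
#' @param logs A `trial_log`, list, or `observer_cohort`.
#' @param boundaries Region boundaries, as in [assign_region()].
#' @param per_observer If `TRUE`, additionally return each observer's
#'   impossible-trial contrast (used for group comparisons).
#' @return An object of class `bias_summary`: list with
#'   `contraction_magnitude` (fitted-curve contrast, in [-1, 1]),
#'   `contraction_magnitude_impossible`, `choice_bias` (region-II
#'   midpoint), fit flags and observer counts; with `per_observer = TRUE`
#'   also `per_observer_impossible`.
#' @export
contraction_magnitude <- function(logs,
                                  boundaries = c(-.M_RANGE / 3, .M_RANGE / 3),
                                  per_observer = FALSE) {
  logs <- as_log_list(logs)
  pooled <- do.call(rbind, lapply(logs, function(l) {
    data.frame(m = l$m, delta = l$s1 - l$s2, response = l$response,
               is_impossible = l$is_impossible)
  }))
  if (any(is.na(pooled$response))) {
    stop("contraction_magnitude requires responses", call. = FALSE)
  }
  pooled$region <- assign_region(pooled$m, boundaries)
  poss <- pooled[!pooled$is_impossible, ]
  if (!any(poss$region == "I") || !any(poss$region == "III")) {
    stop("regions I and III must both contain possible trials", call. = FALSE)
  }
  fit_region <- function(reg) {
    fit_sigmoid(poss[poss$region == reg, c("delta", "response")])
  }
  f1 <- fit_region("I"); f3 <- fit_region("III"); f2 <- fit_region("II")

  imp_contrast_obs <- vapply(logs, function(l) {
    imp <- l[l$is_impossible, ]
    reg <- assign_region(imp$m, boundaries)
    p1 <- mean(imp$response[reg == "I"])
    p3 <- mean(imp$response[reg == "III"])
    p1 - p3
  }, numeric(1))
  ok <- is.finite(imp_contrast_obs)

  out <- list(contraction_magnitude = f1$value_at_0 - f3$value_at_0,
              contraction_magnitude_impossible = mean(imp_contrast_obs[ok]),
              choice_bias = f2$midpoint,
              fit_I = f1, fit_III = f3, fit_II = f2,
              degenerate = f1$degenerate || f3$degenerate,
              n_observers = length(logs),
              n_observers_impossible = sum(ok))
  if (per_observer) out$per_observer_impossible <- imp_contrast_obs
  class(out) <- "bias_summary"
  out
}

#' @export
print.bias_summary <- function(x, ...) {
  cat("Bias summary\n")
  cat(sprintf("  contraction magnitude (fitted curves at f1 = f2): %.3f\n",
              x$contraction_magnitude))
  cat(sprintf("  contraction magnitude (impossible-trial fractions): %.3f (%d observers)\n",
              x$contraction_magnitude_impossible, x$n_observers_impossible))
  cat(sprintf("  choice bias (region-II midpoint): %.4f\n", x$choice_bias))
  if (x$degenerate) cat("  NOTE: a region fit was degenerate\n")
  invisible(x)
}

#' Time course of choice bias on impossible trials
#'
#' Splits each block into consecutive windows of `window` trials
#' (a 220-trial block with the default 20-trial window yields 11 points:
#' roughly five impossible trials each), computes each observer's mean
#' "f1 > f2" rate on the impossible trials of the window, and averages
#' across observers with a cross-observer SEM. Observers with no
#' impossible trial in a window are omitted from that point and counted.
#'
#' @param logs A `trial_log`, list, or `observer_cohort`.
#' @param window Window length in trials; must divide the block length.
#' @return Data frame with `window`, `trial_lo`, `trial_hi`, `mean_p_f1gt`,
#'   `sem`, `n_observers`.
#' @export
choice_bias_timecourse <- function(logs, window = 20L) {
  logs <- as_log_list(logs)
  n <- nrow(logs[[1]])
  if (n %% window != 0L) {
    stop("window (", window, ") must divide the block length (", n, ")",
         call. = FALSE)
  }
  k <- n %/% window
  per_obs <- vapply(logs, function(log) {
    stopifnot(nrow(log) == n)
    w <- (log$trial_index - 1L) %/% window + 1L
    vapply(seq_len(k), function(j) {
      sel <- log$is_impossible & w == j
      if (!any(sel)) NA_real_ else mean(log$response[sel])
    }, numeric(1))
  }, numeric(k))
  per_obs <- matrix(per_obs, nrow = k)
  data.frame(window = seq_len(k),
             trial_lo = (seq_len(k) - 1L) * window + 1L,
             trial_hi = seq_len(k) * window,
             mean_p_f1gt = rowMeans(per_obs, na.rm = TRUE),
             sem = apply(per_obs, 1, function(x) {
               x <- x[!is.na(x)]
               if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
             }),
             n_observers = rowSums(!is.na(per_obs)))
}

#' One-sided Wilcoxon rank-sum test between observer groups
#'
#' Thin wrapper around [stats::wilcox.test()] configured the way the bias
#' analyses use it: one-sided, exact when both groups are small (n <= 10)
#' and untied, normal approximation with tie correction otherwise.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @param alternative `"less"` (default; tests A < B), `"greater"` or
#'   `"two.sided"`.
#' @return List with `p_value`, `statistic`, `exact`.
#' @examples
#' group_difference_test(c(1, 2, 3), c(4, 5, 6))  # p = 1/20
#' @export
group_difference_test <- function(values_a, values_b,
                                  alternative = c("less", "greater",
                                                  "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  ties <- any(duplicated(c(values_a, values_b)))
  exact <- !ties && length(values_a) <= 10L && length(values_b) <= 10L
  res <- suppressWarnings(
    wilcox.test(values_a, values_b, alternative = alternative,
                exact = exact, correct = TRUE))
  list(p_value = res$p.value, statistic = unname(res$statistic),
       exact = exact)
}
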