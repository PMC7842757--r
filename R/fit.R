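#' Table of reward-optimal parameters over a noise grid
#'
#' Runs [optimize_params()] for each `sigma` in a grid and returns the
#' resulting `(a*, b*)` table. Results are cached per protocol within the
#' session, because the table is reused heavily during maximum-likelihood
#' fitting of the optimal-Perceptron model.
#'
#' @param protocol Protocol name or object.
#' @param sigmas Noise grid (default: the fitting grid, 201 log-spaced
#'   values on [1e-3, 1]).
#' @return Data frame with columns `sigma`, `a`, `b`, `value`.
#' @export
optimal_param_table <- function(protocol, sigmas = fit_sigma_grid()) {
  proto <- feedback_protocol(protocol)
  key <- paste0(proto$name, "_", config_hash(sprintf("%.12g", sigmas)))
  if (!is.null(.pb_cache[[key]])) return(.pb_cache[[key]])
  rows <- lapply(sigmas, function(s) {
    opt <- optimize_params(s, proto)
    data.frame(sigma = s, a = opt$a, b = opt$b, value = opt$value)
  })
  tab <- do.call(rbind, rows)
  .pb_cache[[key]] <- tab
  tab
}

#' The default noise grid used by [fit_sigma()]
#' @return 201 log-spaced values spanning [1e-3, 1].
#' @export
fit_sigma_grid <- function() {
  10^seq(log10(1e-3), 0, length.out = 201L)
}

# (a, b) for the optimal-Perceptron likelihood at arbitrary sigma, linearly
# interpolated on log(sigma) from the cached optimum table.
interp_optimal_ab <- function(sigma, protocol) {
  tab <- optimal_param_table(protocol)
  ls <- log(tab$sigma)
  x <- log(pmin(pmax(sigma, min(tab$sigma)), max(tab$sigma)))
  list(a = approx(ls, tab$a, xout = x, rule = 2)$y,
       b = approx(ls, tab$b, xout = x, rule = 2)$y)
}

#' Bernoulli log-likelihood of observed choices
#'
#' Sums, over trials, the log probability of the observed response under a
#' one-parameter choice model. `model = "psychometric"` predicts choices
#' from the stimulus difference alone (`a = 1, b = 0`), so impossible
#' trials contribute `log(0.5)` each. `model = "optimal_perceptron"` uses
#' the reward-optimal `(a, b)` for the given `sigma` (computed with
#' [optimize_params()] under `protocol`, by default the unbiased control
#' protocol), and therefore predicts the contraction bias that makes
#' impossible-trial responses informative. Probabilities are clipped to
#' `[eps, 1 - eps]` before logging.
#'
#' @param model `"optimal_perceptron"` or `"psychometric"`.
#' @param sigma Internal-noise SD (> 0).
#' @param log A `trial_log` with responses.
#' @param protocol Protocol whose optimum defines the perceptron-model
#'   `(a, b)`; default `"control"`.
#' @param possible_only If `TRUE`, restrict the likelihood to possible
#'   trials.
#' @param eps Clipping bound (default 1e-9).
#' @return The log-likelihood (a negative number).
#' @export
choice_loglik <- function(model = c("optimal_perceptron", "psychometric"),
                          sigma, log, protocol = "control",
                          possible_only = FALSE, eps = 1e-9) {
  model <- match.arg(model)
  stopifnot(sigma > 0)
  if (any(is.na(log$response))) {
    stop("choice_loglik requires responses for all trials", call. = FALSE)
  }
  if (model == "optimal_perceptron") {
    opt <- optimize_params(sigma, protocol)
    par <- perceptron_params(opt$a, opt$b, sigma)
  } else {
    par <- perceptron_params(1, 0, sigma)
  }
  loglik_for_params(par, log, possible_only, eps)
}

loglik_for_params <- function(par, log, possible_only = FALSE, eps = 1e-9) {
  keep <- if (possible_only) !log$is_impossible else rep(TRUE, nrow(log))
  p <- response_probability(par, log$s1[keep], log$s2[keep])
  p <- pmin(pmax(p, eps), 1 - eps)
  r <- log$response[keep]
  sum(r * base::log(p) + (1 - r) * base::log(1 - p))
}

#' Maximum-likelihood fit of the internal-noise parameter
#'
#' The package's central fitting function. Both candidate models are
#' one-parameter families indexed by the internal noise `sigma`: the
#' psychometric-curve model (`a = 1, b = 0`; choice depends only on the
#' log-frequency difference) and the optimal-Perceptron model, in which
#' `(a, b)` are the reward-optimal values for that `sigma` so that larger
#' noise implies larger contraction bias. The likelihood is maximised over
#' `sigma` in [1e-3, 1] on a 201-point log-spaced grid followed by
#' golden-section refinement of the bracketing interval; for the
#' optimal-Perceptron model, `(a, b)(sigma)` is precomputed on the grid and
#' interpolated during refinement. The procedure is deterministic.
#'
#' @param log A `trial_log` with responses (ideally one that passes
#'   [exclusion_test()]; the fit does not check).
#' @param model `"optimal_perceptron"` or `"psychometric"`.
#' @param protocol Protocol whose optimum defines the perceptron mapping
#'   `sigma -> (a, b)`; default `"control"`.
#' @param possible_only Restrict the likelihood to possible trials.
#' @return An object of class `sigma_fit` with components `model`,
#'   `sigma_hat`, `a`, `b`, `loglik`, `n_trials_used`, `converged` (FALSE
#'   when the maximiser sits on the search boundary, e.g. for noiseless or
#'   degenerate data), and the grid profile. Supports `print()`,
#'   `summary()`, `coef()`, `logLik()`, `predict()`, `residuals()`,
#'   `simulate()` and `plot()`.
#' @examples
#' blk <- generate_block("control", 220, seed = 3)
#' obs <- simulate_static_observer(observer_spec("static", sigma = 0.1,
#'                                               seed = 4), blk)
#' fit <- fit_sigma(obs, model = "psychometric")
#' coef(fit)
#' @export
fit_sigma <- function(log, model = c("optimal_perceptron", "psychometric"),
                      protocol = "control", possible_only = FALSE) {
  model <- match.arg(model)
  if (any(is.na(log$response))) {
    stop("fit_sigma requires responses for all trials", call. = FALSE)
  }
  grid <- fit_sigma_grid()
  keep <- if (possible_only) !log$is_impossible else rep(TRUE, nrow(log))
  n_used <- sum(keep)
  degenerate <- length(unique(log$response[keep])) < 2L

  params_at <- function(sigma) {
    if (model == "optimal_perceptron") {
      ab <- interp_optimal_ab(sigma, protocol)
      perceptron_params(ab$a, ab$b, sigma)
    } else {
      perceptron_params(1, 0, sigma)
    }
  }
  ll_at <- function(sigma) loglik_for_params(params_at(sigma), log,
                                             possible_only)
  ll_grid <- vapply(grid, ll_at, numeric(1))
  i <- which.max(ll_grid)
  at_boundary <- i == 1L || i == length(grid)

  if (!at_boundary) {
    # golden-section refinement on log(sigma) in the bracketing interval
    gr <- (sqrt(5) - 1) / 2
    lo <- base::log(grid[i - 1L]); hi <- base::log(grid[i + 1L])
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- ll_at(exp(x1)); f2 <- ll_at(exp(x2))
    while (hi - lo > 1e-6) {
      if (f1 < f2) {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo); f2 <- ll_at(exp(x2))
      } else {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo); f1 <- ll_at(exp(x1))
      }
    }
    sigma_hat <- exp((lo + hi) / 2)
    loglik <- ll_at(sigma_hat)
  } else {
    sigma_hat <- grid[i]
    loglik <- ll_grid[i]
  }
  par_hat <- params_at(sigma_hat)
  structure(list(model = model,
                 protocol = feedback_protocol(protocol)$name,
                 sigma_hat = sigma_hat,
                 a = par_hat$a, b = par_hat$b,
                 loglik = loglik,
                 n_trials_used = n_used,
                 converged = !at_boundary && !degenerate,
                 possible_only = possible_only,
                 profile = data.frame(sigma = grid, loglik = ll_grid),
                 data = log),
            class = "sigma_fit")
}

#' @export
print.sigma_fit <- function(x, ...) {
  cat(sprintf("Choice-model fit (%s)\n", x$model))
  cat(sprintf("  sigma_hat = %.4f  (a = %.4f, b = %.4f)\n", x$sigma_hat,
              x$a, x$b))
  cat(sprintf("  log-likelihood = %.2f over %d trials (%.4f per trial)\n",
              x$loglik, x$n_trials_used, x$loglik / x$n_trials_used))
  if (!x$converged) cat("  NOTE: estimate on the search boundary or data degenerate\n")
  invisible(x)
}

#' @export
coef.sigma_fit <- function(object, ...) {
  c(sigma = object$sigma_hat, a = object$a, b = object$b)
}

#' @export
logLik.sigma_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = object$n_trials_used,
            class = "logLik")
}

#' @export
summary.sigma_fit <- function(object, ...) {
  log <- object$data
  poss <- !log$is_impossible
  par <- perceptron_params(object$a, object$b, object$sigma_hat)
  pred <- response_probability(par, log$s1, log$s2)
  obs_acc <- mean(log$response[poss] ==
                    as.integer(log$s1[poss] > log$s2[poss]))
  pred_acc <- mean(ifelse(log$d[poss] > 0, pred[poss], 1 - pred[poss]))
  out <- list(fit = object, observed_accuracy = obs_acc,
              predicted_accuracy = pred_acc,
              impossible_choice_rate = mean(log$response[!poss]))
  class(out) <- "summary.sigma_fit"
  out
}

#' @export
print.summary.sigma_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  accuracy on possible trials: observed %.3f, predicted %.3f\n",
              x$observed_accuracy, x$predicted_accuracy))
  cat(sprintf("  P('f1>f2') on impossible trials: %.3f\n",
              x$impossible_choice_rate))
  invisible(x)
}

#' @export
predict.sigma_fit <- function(object, newdata = NULL,
                              type = c("prob", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  if (!all(c("s1", "s2") %in% names(newdata))) {
    if (all(c("f1_hz", "f2_hz") %in% names(newdata))) {
      u <- derive_log_units(newdata$f1_hz, newdata$f2_hz)
      newdata$s1 <- u$s1; newdata$s2 <- u$s2
    } else {
      stop("newdata needs columns s1/s2 or f1_hz/f2_hz", call. = FALSE)
    }
  }
  par <- perceptron_params(object$a, object$b, object$sigma_hat)
  p <- response_probability(par, newdata$s1, newdata$s2)
  if (type == "prob") p else as.integer(p > 0.5)
}

#' @export
residuals.sigma_fit <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
simulate.sigma_fit <- function(object, nsim = 1, seed = NULL, ...) {
  log <- object$data
  par <- perceptron_params(object$a, object$b, object$sigma_hat)
  draw <- function(k) {
    noise <- rnorm(nrow(log), 0, par$sigma)
    decide(par, log$s1 + noise, log$s2)$A
  }
  sims <- if (is.null(seed)) {
    lapply(seq_len(nsim), draw)
  } else {
    with_seed(seed, lapply(seq_len(nsim), draw))
  }
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' @export
plot.sigma_fit <- function(x, n_bins = 9L, ...) {
  log <- x$data
  poss <- log[!log$is_impossible, ]
  delta <- poss$s1 - poss$s2
  br <- seq(-2 * .D_RANGE, 2 * .D_RANGE, length.out = n_bins + 1L)
  bin <- cut(delta, br, include.lowest = TRUE)
  prop <- tapply(poss$response, bin, mean)
  centers <- (head(br, -1) + tail(br, -1)) / 2
  par_hat <- perceptron_params(x$a, x$b, x$sigma_hat)
  dd <- seq(min(br), max(br), length.out = 201L)
  # curve drawn along m = 0 slice (s1 = delta/2, s2 = -delta/2)
  pp <- response_probability(par_hat, dd / 2, -dd / 2)
  plot(centers, prop, ylim = c(0, 1), pch = 19,
       xlab = expression(Delta == log * f[1] - log * f[2]),
       ylab = "P(respond 'f1 > f2')",
       main = sprintf("%s fit: sigma = %.3f", x$model, x$sigma_hat), ...)
  lines(dd, pp, col = "steelblue", lwd = 2)
  abline(h = 0.5, v = 0, lty = 3, col = "grey60")
  invisible(x)
}

#' Per-observer model comparison
#'
#' Compares paired fits of the optimal-Perceptron and psychometric models
#' on identical trial sets: reports each observer's log-likelihood
#' difference per trial (Perceptron minus psychometric), the fraction of
#' observers favouring the Perceptron, and a two-sided exact sign
#' (binomial) test on the count of positive differences. Exact ties are
#' excluded from the sign test; if all observers tie, the fraction is
#' reported as 0.5 with a flag.
#'
#' @param fits_perceptron,fits_psychometric Lists of `sigma_fit` objects
#'   (or single fits), paired by position.
#' @return An object of class `model_comparison`: data frame `per_observer`
#'   plus `fraction_favoring_perceptron`, `p_value`, `all_tied`.
#' @export
compare_models <- function(fits_perceptron, fits_psychometric) {
  if (inherits(fits_perceptron, "sigma_fit")) fits_perceptron <- list(fits_perceptron)
  if (inherits(fits_psychometric, "sigma_fit")) fits_psychometric <- list(fits_psychometric)
  stopifnot(length(fits_perceptron) == length(fits_psychometric))
  rows <- mapply(function(fp, fq) {
    if (fp$n_trials_used != fq$n_trials_used) {
      stop("paired fits use different trial counts (", fp$n_trials_used,
           " vs ", fq$n_trials_used, ")", call. = FALSE)
    }
    data.frame(n_trials = fp$n_trials_used,
               sigma_perceptron = fp$sigma_hat,
               sigma_psychometric = fq$sigma_hat,
               dll_per_trial = (fp$loglik - fq$loglik) / fp$n_trials_used)
  }, fits_perceptron, fits_psychometric, SIMPLIFY = FALSE)
  tab <- do.call(rbind, rows)
  nonzero <- tab$dll_per_trial != 0
  all_tied <- !any(nonzero)
  if (all_tied) {
    frac <- 0.5
    p <- 1
  } else {
    npos <- sum(tab$dll_per_trial > 0)
    frac <- npos / sum(nonzero)
    p <- binom.test(npos, sum(nonzero), 0.5,
                    alternative = "two.sided")$p.value
  }
  structure(list(per_observer = tab,
                 fraction_favoring_perceptron = frac,
                 p_value = p, all_tied = all_tied),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  n <- nrow(x$per_observer)
  cat(sprintf("Model comparison over %d observers\n", n))
  cat(sprintf("  mean dLL/trial (Perceptron - psychometric): %.5f\n",
              mean(x$per_observer$dll_per_trial)))
  cat(sprintf("  fraction favoring the Perceptron: %.2f (sign test p = %.3g)\n",
              x$fraction_favoring_perceptron, x$p_value))
  if (x$all_tied) cat("  NOTE: all observers tied exactly\n")
  invisible(x)
}
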