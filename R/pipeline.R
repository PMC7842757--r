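#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], with the
#' study's design defaults: 220-trial blocks, 36 observers per protocol,
#' lognormal noise population (median 0.08 log units), static observers
#' with the reward-optimal parameters for their own noise, 9-bin curves,
#' 20-trial time-course windows. Any element can be overridden via `...`.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    protocols = protocol_names(),
    n_observers = 36L,
    n_trials = 220L,
    observer = list(kind = "static", a = "optimal", b = 0,
                    learning_rate = 0),
    sigma_distribution = list(dist = "lognormal", meanlog = log(0.08),
                              sdlog = 0.5),
    analysis = list(n_bins = 9L, window = 20L,
                    region_boundaries = c(-.M_RANGE / 3, .M_RANGE / 3)),
    optimize_sigmas = c(0.05, 0.1, 0.2),
    master_seed = 1L,
    figures = TRUE
  )
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "run_config")) {
    config <- do.call(run_config, config)
  }
  config
}

validate_config <- function(cfg) {
  bad <- setdiff(cfg$protocols, protocol_names())
  if (length(bad)) {
    stop("unknown protocol(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(protocol_names(), collapse = ", "),
         call. = FALSE)
  }
  if (cfg$n_trials %% 4L != 0L) {
    stop("n_trials must be divisible by 4 (exact 75/25 ",
         "possible/impossible split)", call. = FALSE)
  }
  if (cfg$n_trials %% cfg$analysis$window != 0L) {
    stop("analysis window must divide n_trials", call. = FALSE)
  }
  invisible(cfg)
}

write_csv <- function(df, path) {
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full simulate -> fit -> analyse -> report pipeline
#'
#' For each configured protocol: simulates a cohort, writes the trial logs
#' and manifest, applies the exclusion screen, fits both choice models to
#' every kept observer (under the unbiased-protocol optimum, the
#' convention used for model comparison), and computes the bias analyses
#' (region psychometric curves, contraction magnitudes, impossible-trial
#' time courses). Also tabulates the protocol-specific reward-optimal
#' `(a*, b*)` at the configured noise levels. All outputs are CSV/JSON
#' under `out_dir`; a machine-readable `summary.json` carries the headline
#' quantities and the config hash. Given the same config and seed the
#' summary is byte-identical across runs.
#'
#' @param config A `run_config` list, a plain named list of overrides, or
#'   the path to a YAML file of them.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`cohorts`,
#'   `fits`, `analyses`, `summary`, `out_dir`).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  cfg <- validate_config(load_config(config))
  if (missing(out_dir)) stop("out_dir must be supplied", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    stop("output directory ", out_dir, " is not writable", call. = FALSE)
  }
  hash <- config_hash(deparse(cfg[setdiff(names(cfg), "figures")]))
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                      line))
  }
  note("pipeline start: seed %d, config %s", cfg$master_seed, hash)

  cohorts <- list(); analyses <- list(); fits <- list()
  excl_rows <- list(); fit_rows <- list(); bias_rows <- list()
  tc_rows <- list(); curve_rows <- list(); opt_rows <- list()

  for (pi in seq_along(cfg$protocols)) {
    proto <- cfg$protocols[pi]
    note("simulating cohort: %s", proto)
    cohort <- simulate_cohort(cohort_spec(
      n_observers = cfg$n_observers, protocol = proto,
      observer_kind = cfg$observer$kind,
      sigma_distribution = cfg$sigma_distribution,
      a = cfg$observer$a, b = cfg$observer$b,
      learning_rate = cfg$observer$learning_rate,
      n_trials = cfg$n_trials,
      master_seed = child_seed(cfg$master_seed, 1000L + pi)))
    cohorts[[proto]] <- cohort

    combined <- do.call(rbind, lapply(cohort$logs, function(l) {
      data.frame(observer_id = attr(l, "observer_id"), protocol = proto,
                 l[, c("trial_index", "f1_hz", "f2_hz", "is_impossible",
                       "rewarded_response_draw", "response", "feedback")])
    }))
    write_csv(combined, file.path(out_dir,
                                  sprintf("trials_%s.csv", proto)))
    write_csv(cohort$manifest, file.path(out_dir,
                                         sprintf("manifest_%s.csv", proto)))

    excl <- lapply(cohort$logs, exclusion_test)
    excl_rows[[proto]] <- data.frame(
      observer_id = cohort$manifest$observer_id, protocol = proto,
      decision = vapply(excl, `[[`, character(1), "decision"),
      p_first = vapply(excl, `[[`, numeric(1), "p_first"),
      p_second = vapply(excl, `[[`, numeric(1), "p_second"))
    kept <- which(excl_rows[[proto]]$decision == "keep")
    note("%s: %d/%d observers kept", proto, length(kept), cfg$n_observers)

    if (proto == "control" && length(kept) > 0) {
      fp <- lapply(cohort$logs[kept], fit_sigma, model = "optimal_perceptron")
      fq <- lapply(cohort$logs[kept], fit_sigma, model = "psychometric")
      cmp <- compare_models(fp, fq)
      fits$control <- list(perceptron = fp, psychometric = fq,
                           comparison = cmp)
      fit_rows[[proto]] <- do.call(rbind, lapply(seq_along(kept), function(j) {
        data.frame(observer_id = cohort$manifest$observer_id[kept[j]],
                   protocol = proto,
                   model = c("optimal_perceptron", "psychometric"),
                   sigma_hat = c(fp[[j]]$sigma_hat, fq[[j]]$sigma_hat),
                   loglik = c(fp[[j]]$loglik, fq[[j]]$loglik),
                   n_trials_used = c(fp[[j]]$n_trials_used,
                                     fq[[j]]$n_trials_used),
                   converged = c(fp[[j]]$converged, fq[[j]]$converged))
      }))
    }

    logs_kept <- cohort$logs[kept]
    if (length(logs_kept) > 0) {
      bias <- contraction_magnitude(logs_kept,
                                    boundaries = cfg$analysis$region_boundaries,
                                    per_observer = TRUE)
      bias_rows[[proto]] <- data.frame(
        protocol = proto,
        contraction_fitted = bias$contraction_magnitude,
        contraction_impossible = bias$contraction_magnitude_impossible,
        choice_bias_midpoint = bias$choice_bias,
        n_observers = bias$n_observers)
      tc <- choice_bias_timecourse(logs_kept, window = cfg$analysis$window)
      tc$protocol <- proto
      tc_rows[[proto]] <- tc
      for (reg in c("all", "I", "II", "III")) {
        cv <- psychometric_curve(logs_kept, region = reg,
                                 n_bins = cfg$analysis$n_bins,
                                 boundaries = cfg$analysis$region_boundaries)
        cv$protocol <- proto; cv$region <- reg
        curve_rows[[paste(proto, reg)]] <- as.data.frame(cv)
      }
      analyses[[proto]] <- list(bias = bias, timecourse = tc)
    }

    opt_rows[[proto]] <- do.call(rbind, lapply(cfg$optimize_sigmas,
      function(s) {
        o <- optimize_params(s, proto)
        data.frame(protocol = proto, sigma = s, a_star = o$a, b_star = o$b,
                   expected_reward = o$value)
      }))
  }

  excl_tab <- do.call(rbind, excl_rows)
  bias_tab <- do.call(rbind, bias_rows)
  tc_tab <- do.call(rbind, tc_rows)
  curve_tab <- do.call(rbind, curve_rows)
  opt_tab <- do.call(rbind, opt_rows)
  write_csv(excl_tab, file.path(out_dir, "exclusion.csv"))
  if (length(fit_rows)) {
    write_csv(do.call(rbind, fit_rows), file.path(out_dir, "fits.csv"))
  }
  write_csv(bias_tab, file.path(out_dir, "bias_summary.csv"))
  write_csv(tc_tab, file.path(out_dir, "timecourse.csv"))
  write_csv(curve_tab, file.path(out_dir, "curves.csv"))
  write_csv(opt_tab, file.path(out_dir, "optimal_params.csv"))

  summary <- list(
    config_hash = hash,
    master_seed = cfg$master_seed,
    n_observers = cfg$n_observers,
    protocols = cfg$protocols,
    kept_per_protocol = as.list(tapply(excl_tab$decision == "keep",
                                       excl_tab$protocol, sum)),
    optimal_params = opt_tab,
    contraction_by_protocol = bias_tab,
    model_comparison = if (!is.null(fits$control)) list(
      fraction_favoring_perceptron =
        fits$control$comparison$fraction_favoring_perceptron,
      mean_dll_per_trial =
        mean(fits$control$comparison$per_observer$dll_per_trial),
      sign_test_p = fits$control$comparison$p_value) else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("pipeline done")
  writeLines(log_lines, file.path(out_dir, "run.log"))

  if (isTRUE(cfg$figures)) replicate_figures(out_dir)

  invisible(list(cohorts = cohorts, fits = fits, analyses = analyses,
                 summary = summary, out_dir = out_dir))
}

#' Regenerate the package's standard figures from pipeline outputs
#'
#' Draws, from the CSV tables written by [run_pipeline()] (plus a short
#' deterministic optimisation sweep), the package's synthetic analogues of
#' the study's figure panels: the impossible-trial choice-rate time course
#' by protocol, the contraction magnitude by protocol, the optimal weight
#' `a*` as a function of noise, the quadrant accuracies of the `a = b = 0`
#' Perceptron, the distribution of per-observer log-likelihood differences,
#' and the region-split psychometric curves. Each figure is a PNG written
#' next to the table it was drawn from.
#'
#' @param out_dir Directory containing pipeline outputs.
#' @return Character vector of figure paths, invisibly.
#' @export
replicate_figures <- function(out_dir) {
  need <- c("timecourse.csv", "bias_summary.csv", "curves.csv")
  for (f in need) {
    if (!file.exists(file.path(out_dir, f))) {
      stop("missing pipeline table ", f, " in ", out_dir, call. = FALSE)
    }
  }
  paths <- character(0)
  fig <- function(name, w = 900, h = 600, code) {
    p <- file.path(out_dir, name)
    png(p, width = w, height = h, res = 120)
    on.exit(dev.off(), add = TRUE)
    force(code)
    paths <<- c(paths, p)
  }

  tc <- read.csv(file.path(out_dir, "timecourse.csv"))
  fig("fig_choice_timecourse.png", code = {
    protos <- unique(tc$protocol)
    cols <- seq_along(protos)
    plot(NULL, xlim = range(tc$trial_hi), ylim = c(0, 1),
         xlab = "trial", ylab = "P('f1>f2') on impossible trials",
         main = "Choice-bias time course")
    for (i in seq_along(protos)) {
      sub <- tc[tc$protocol == protos[i], ]
      lines(sub$trial_hi - 10, sub$mean_p_f1gt, col = cols[i], lwd = 2)
      points(sub$trial_hi - 10, sub$mean_p_f1gt, col = cols[i], pch = 19)
    }
    abline(h = 0.5, lty = 3)
    legend("topleft", legend = protos, col = cols, lwd = 2, cex = 0.7)
  })

  bias <- read.csv(file.path(out_dir, "bias_summary.csv"))
  fig("fig_contraction_by_protocol.png", code = {
    barplot(bias$contraction_impossible, names.arg = bias$protocol,
            ylab = "contraction magnitude (impossible-trial contrast)",
            main = "Contraction bias by feedback protocol", las = 2,
            cex.names = 0.7)
    abline(h = 0)
  })

  fig("fig_optimal_a_vs_sigma.png", code = {
    sig <- c(0.001, 0.02, 0.05, 0.08, 0.12, 0.2, 0.3, 0.5)
    astar <- vapply(sig, function(s) optimize_params(s, "control")$a,
                    numeric(1))
    plot(sig, astar, type = "b", pch = 19, ylim = c(0, 1.05),
         xlab = expression(sigma), ylab = "optimal weight a*",
         main = "Optimal first-stimulus weight vs noise")
    abline(h = 1, lty = 3)
  })

  fig("fig_quadrant_accuracy.png", code = {
    qa <- quadrant_accuracy(perceptron_params(0, 0, 0.1))
    qa <- stats::setNames(as.numeric(qa), names(qa))
    barplot(qa, ylim = c(0, 1), las = 2, cex.names = 0.7,
            ylab = "fraction correct",
            main = "Accuracy of the a = 0 Perceptron by quadrant")
    abline(h = 0.5, lty = 3)
  })

  fits_path <- file.path(out_dir, "fits.csv")
  if (file.exists(fits_path)) {
    ft <- read.csv(fits_path)
    wide <- merge(ft[ft$model == "optimal_perceptron",
                     c("observer_id", "loglik", "n_trials_used")],
                  ft[ft$model == "psychometric", c("observer_id", "loglik")],
                  by = "observer_id", suffixes = c("_perc", "_psy"))
    dll <- (wide$loglik_perc - wide$loglik_psy) / wide$n_trials_used
    fig("fig_delta_ll.png", code = {
      hist(dll, breaks = 12, col = "grey80",
           xlab = expression(Delta * "LL per trial (Perceptron - psychometric)"),
           main = "Per-observer model comparison")
      abline(v = 0, lty = 2)
    })
  }

  curves <- read.csv(file.path(out_dir, "curves.csv"))
  for (proto in unique(curves$protocol)) {
    local({
      p <- proto
      fig(sprintf("fig_region_curves_%s.png", p), code = {
        sub <- curves[curves$protocol == p & curves$region != "all", ]
        cols <- c(I = "firebrick", II = "black", III = "steelblue")
        plot(NULL, xlim = range(sub$bin_center), ylim = c(0, 1),
             xlab = expression(Delta == log * f[1] - log * f[2]),
             ylab = "P('f1>f2')",
             main = sprintf("Region psychometric curves: %s", p))
        for (reg in c("I", "II", "III")) {
          rs <- sub[sub$region == reg & !is.na(sub$prop), ]
          lines(rs$bin_center, rs$prop, col = cols[[reg]], lwd = 2)
          points(rs$bin_center, rs$prop, col = cols[[reg]], pch = 19)
        }
        abline(h = 0.5, v = 0, lty = 3)
        legend("topleft", legend = c("I (low)", "II (mid)", "III (high)"),
               col = cols, lwd = 2, cex = 0.8)
      })
    })
  }
  invisible(paths)
}
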