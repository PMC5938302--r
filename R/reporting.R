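# Output statistics: monthly per-100,000 incidence series, replicate summary
# statistics (mean, SD, 95% margin of error using the t distribution),
# baseline-versus-scenario percent reductions with Welch-propagated margins,
# and the calibration harness used to fit the packaged default
# parameterisation.

#' Monthly per-100k incidence series
#'
#' Counts qualifying events per calendar month and divides by the month's
#' adult population denominator, scaled to 100,000. The ED and
#' hospitalisation series count acute events carrying the respective flag;
#' the chronic series counts chronic onsets and chronic annual events.
#'
#' @param event_log Event log data.frame (columns `month`, `kind`, `ed`,
#'   `hospital`).
#' @param population_series Data.frame with `month` and `denominator`
#'   (persons 18+ alive).
#' @return A data.frame of class `alco_monthly`: `month`, `denominator`,
#'   `acute_per100k`, `ed_per100k`, `hosp_per100k`, `chronic_per100k`.
#' @export
#' @examples
#' log <- data.frame(month = c(1, 1), kind = "acute",
#'                   ed = c(TRUE, FALSE), hospital = FALSE)
#' pops <- data.frame(month = 1, denominator = 20000)
#' monthly_per100k(log, pops)$acute_per100k  # 10
monthly_per100k <- function(event_log, population_series) {
  if (any(population_series$denominator <= 0))
    stop("population denominator must be positive")
  m <- population_series$month
  count_in <- function(sel) {
    if (!nrow(event_log) || !any(sel)) return(numeric(length(m)))
    tab <- table(factor(event_log$month[sel], levels = m))
    as.numeric(tab)
  }
  acute <- event_log$kind == "acute"
  out <- data.frame(
    month = m,
    denominator = population_series$denominator,
    acute_per100k = count_in(acute) / population_series$denominator * 1e5,
    ed_per100k = count_in(acute & event_log$ed) /
      population_series$denominator * 1e5,
    hosp_per100k = count_in(acute & event_log$hospital) /
      population_series$denominator * 1e5,
    chronic_per100k = count_in(!acute) / population_series$denominator * 1e5)
  class(out) <- c("alco_monthly", "data.frame")
  out
}

#' Monthly series for every replicate of a run
#'
#' @param run An `alco_run`.
#' @param window_only Restrict to the scenario/reporting window months.
#' @return A list of `alco_monthly` data.frames, one per replicate.
#' @export
run_series <- function(run, window_only = TRUE) {
  keep <- if (window_only) run$months$month[run$months$in_window] else
    run$months$month
  lapply(run$replicates, function(r) {
    s <- monthly_per100k(r$event_log, r$pop_series)
    s[s$month %in% keep, , drop = FALSE]
  })
}

#' Replicate summary statistics
#'
#' The unit of analysis is the replicate's mean monthly value over the
#' reporting window; across `n` replicates the summary is the mean of those
#' means, their standard deviation, and the 95% margin of error
#' `t(n-1, 0.975) * sd / sqrt(n)`.
#'
#' @param series_list List of monthly series (one per replicate) or an
#'   `alco_run`.
#' @param outcome Column name, e.g. `"acute_per100k"`.
#' @return A list with `mean`, `sd`, `margin_of_error`, `n`.
#' @export
#' @examples
#' # margin printed for a 12-run summary with sd 1.8:
#' qt(0.975, 11) * 1.8 / sqrt(12)  # ~1.14
summarize_replicates <- function(series_list, outcome) {
  if (inherits(series_list, "alco_run")) series_list <- run_series(series_list)
  n <- length(series_list)
  if (n < 2) stop("need at least 2 replicates to summarise")
  means <- vapply(series_list, function(s) mean(s[[outcome]]), numeric(1))
  mu <- mean(means); s <- sd(means)
  list(mean = mu, sd = s,
       margin_of_error = qt(0.975, n - 1) * s / sqrt(n), n = n)
}

#' Compare a scenario against baseline
#'
#' Percent reduction in the mean of the per-replicate monthly means,
#' `100 * (baseline - scenario) / baseline`, with a 95% margin of error
#' propagated from the two replicate sets' variances: Welch standard error
#' of the difference of means, t critical value at Welch-Satterthwaite
#' degrees of freedom, expressed as a percentage of the baseline mean.
#'
#' @param baseline Baseline replicate series list or `alco_run`.
#' @param scenario Scenario replicate series list or `alco_run`.
#' @param outcome Column name, e.g. `"acute_per100k"`.
#' @return A list of class `alco_comparison`: `outcome`, `baseline_mean`,
#'   `scenario_mean`, `percent_reduction`, `margin_of_error`, `n`.
#' @export
compare_scenarios <- function(baseline, scenario, outcome = "acute_per100k") {
  if (inherits(baseline, "alco_run")) baseline <- run_series(baseline)
  if (inherits(scenario, "alco_run")) scenario <- run_series(scenario)
  if (!length(baseline) || !length(scenario))
    stop("both replicate sets must be non-empty")
  mb <- vapply(baseline, function(s) mean(s[[outcome]]), numeric(1))
  ms <- vapply(scenario, function(s) mean(s[[outcome]]), numeric(1))
  if (mean(mb) == 0) stop("baseline mean is zero")
  n1 <- length(mb); n2 <- length(ms)
  se2 <- var(mb) / n1 + var(ms) / n2
  df <- se2^2 / ((var(mb) / n1)^2 / (n1 - 1) + (var(ms) / n2)^2 / (n2 - 1))
  if (!is.finite(df) || df <= 0) df <- min(n1, n2) - 1
  crit <- qt(0.975, df)
  structure(list(
    outcome = outcome, baseline_mean = mean(mb), scenario_mean = mean(ms),
    percent_reduction = 100 * (mean(mb) - mean(ms)) / mean(mb),
    margin_of_error = 100 * crit * sqrt(se2) / mean(mb),
    n = c(baseline = n1, scenario = n2)
  ), class = "alco_comparison")
}

#' @export
print.alco_comparison <- function(x, ...) {
  cat(sprintf("<alco_comparison> %s: %.1f%% reduction (+/- %.1f%%), baseline %.1f vs scenario %.1f per 100k/month\n",
              x$outcome, x$percent_reduction, x$margin_of_error,
              x$baseline_mean, x$scenario_mean))
  invisible(x)
}

#' Headline outcome set for a run battery
#'
#' Computes the statistics the model is calibrated and evaluated against:
#' mean monthly acute incidence, ED and hospitalisation rates per 100k over
#' the reporting window; the acute share of all harms; the ED and
#' hospitalisation shares of acute harms (pooled events); and the annualised
#' population decline.
#'
#' @param baseline_run An `alco_run` under baseline.
#' @return Named list of outcomes.
#' @export
baseline_outcomes <- function(baseline_run) {
  ser <- run_series(baseline_run)
  keep <- baseline_run$months$month[baseline_run$months$in_window]
  pool <- do.call(rbind, lapply(baseline_run$replicates, function(r)
    r$event_log[r$event_log$month %in% keep,
                c("kind", "ed", "hospital"), drop = FALSE]))
  acute <- pool$kind == "acute"
  n_acute <- sum(acute); n_chronic <- sum(!acute)
  decline <- vapply(baseline_run$replicates, function(r) {
    d <- r$pop_series$denominator[r$pop_series$month %in% keep]
    yrs <- length(d) / 12
    100 * (1 - (d[length(d)] / d[1])^(1 / yrs))
  }, numeric(1))
  rate_mean <- function(outc)
    mean(vapply(ser, function(s) mean(s[[outc]]), numeric(1)))
  list(
    acute_rate = rate_mean("acute_per100k"),
    ed_rate = rate_mean("ed_per100k"),
    hosp_rate = rate_mean("hosp_per100k"),
    acute_share = 100 * n_acute / max(1, n_acute + n_chronic),
    ed_share = 100 * sum(pool$ed[acute]) / max(1, n_acute),
    hosp_share = 100 * sum(pool$hospital[acute]) / max(1, n_acute),
    population_decline = mean(decline)
  )
}

# ---- calibration harness --------------------------------------------------

config_get <- function(config, path) {
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) config <- config[[k]]
  config
}

config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, keys) {
    if (length(keys) == 1) x[[keys]] <- value
    else x[[keys[1]]] <- rec(x[[keys[1]]], keys[-1])
    x
  }
  rec(config, keys)
}

#' Calibrate free parameters to target statistics
#'
#' Searches a box of free parameters (configuration paths with bounds) to
#' minimise the weighted squared relative error between measured outcomes
#' and targets. The search is Latin-hypercube screening followed by
#' coordinate descent (per-coordinate bracketed refinement with shrinking
#' step), which suits the small, noisy, monotone-in-most-parameters
#' objectives that arise here. Runs are seeded, so a repeated call with the
#' same seed returns the identical fitted configuration.
#'
#' @param free_parameters Data.frame with columns `path` (configuration path
#'   such as `"acute_hazards.scale"`), `lower`, `upper`.
#' @param target_set Data.frame with columns `outcome`, `value`, and
#'   optionally `tolerance` (same units as value) and `weight`.
#' @param budget Maximum number of objective evaluations.
#' @param seed Integer seed.
#' @param evaluate Function(config) returning a named list/vector of
#'   measured outcomes covering `target_set$outcome`.
#' @param config Starting configuration.
#' @param n_screen Latin-hypercube screening points.
#' @return A list of class `alco_calibration`: `config` (best found),
#'   `achieved`, `report` (achieved vs target per outcome), `objective`,
#'   `n_eval`, `met` (all targets within tolerance?).
#' @export
calibrate <- function(free_parameters, target_set, budget, seed, evaluate,
                      config = default_config(),
                      n_screen = min(10, max(4, budget %/% 4))) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  fp <- free_parameters
  tg <- target_set
  if (is.null(tg$weight)) tg$weight <- 1
  if (is.null(tg$tolerance)) tg$tolerance <- abs(tg$value) * 0.05
  n_eval <- 0L
  score <- function(meas) {
    got <- unlist(meas)[tg$outcome]
    sum(tg$weight * ((got - tg$value) / ifelse(tg$value != 0, tg$value, 1))^2)
  }
  eval_at <- function(x) {
    cfg <- config
    for (j in seq_len(nrow(fp)))
      cfg <- config_set(cfg, fp$path[j], unname(x[j]))
    meas <- evaluate(cfg)
    n_eval <<- n_eval + 1L
    list(obj = score(meas), meas = meas, cfg = cfg)
  }
  x0 <- vapply(fp$path, function(p) config_get(config, p), numeric(1))
  best <- eval_at(x0); best_x <- x0
  targets_met <- function(meas) {
    got <- unlist(meas)[tg$outcome]
    all(abs(got - tg$value) <= tg$tolerance)
  }
  if (!targets_met(best$meas) && n_eval < budget) {
    # Latin hypercube screening
    if (n_screen > 0 && nrow(fp) >= 1) {
      grid <- lhs::randomLHS(n_screen, nrow(fp))
      for (i in seq_len(n_screen)) {
        if (n_eval >= budget) break
        x <- fp$lower + grid[i, ] * (fp$upper - fp$lower)
        cand <- eval_at(x)
        if (cand$obj < best$obj) { best <- cand; best_x <- x }
      }
    }
    # coordinate descent with shrinking relative step
    step <- 0.25
    while (n_eval < budget && !targets_met(best$meas) && step > 1e-4) {
      improved <- FALSE
      for (j in seq_len(nrow(fp))) {
        if (n_eval >= budget) break
        span <- fp$upper[j] - fp$lower[j]
        for (dirn in c(-1, 1)) {
          if (n_eval >= budget) break
          x <- best_x
          x[j] <- min(max(x[j] + dirn * step * span, fp$lower[j]),
                      fp$upper[j])
          if (x[j] == best_x[j]) next
          cand <- eval_at(x)
          if (cand$obj < best$obj) {
            best <- cand; best_x <- x; improved <- TRUE
            break
          }
        }
      }
      if (!improved) step <- step / 2
    }
  }
  got <- unlist(best$meas)[tg$outcome]
  report <- data.frame(outcome = tg$outcome, target = tg$value,
                       achieved = as.numeric(got),
                       tolerance = tg$tolerance,
                       met = abs(got - tg$value) <= tg$tolerance)
  structure(list(config = best$cfg, achieved = best$meas, report = report,
                 objective = best$obj, n_eval = n_eval,
                 parameters = setNames(best_x, fp$path),
                 met = all(report$met)),
            class = "alco_calibration")
}

#' @export
print.alco_calibration <- function(x, ...) {
  cat("<alco_calibration>", x$n_eval, "evaluations, objective",
      signif(x$objective, 4), if (x$met) "(targets met)" else
        "(targets NOT met; best found returned)", "\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Write monthly series / comparison reports
#'
#' @param series An `alco_monthly` data.frame.
#' @param path CSV path.
#' @export
write_monthly_series <- function(series, path) {
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_monthly_series
#' @param comparison An `alco_comparison`.
#' @export
write_comparison <- function(comparison, path) {
  jsonlite::write_json(unclass(comparison), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Plot monthly per-100k series
#'
#' Simple line plot of an outcome across replicates (thin lines) with the
#' replicate mean (thick line).
#'
#' @param series_list List of monthly series or an `alco_run`.
#' @param outcome Column to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_monthly <- function(series_list, outcome = "acute_per100k", ...) {
  if (inherits(series_list, "alco_run")) series_list <- run_series(series_list)
  m <- series_list[[1]]$month
  vals <- sapply(series_list, function(s) s[[outcome]])
  graphics::matplot(m, vals, type = "l", lty = 1,
                    col = grDevices::grey(0.7), xlab = "month",
                    ylab = paste(outcome, "(per 100k)"), ...)
  graphics::lines(m, rowMeans(vals), lwd = 2)
  invisible(NULL)
}
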