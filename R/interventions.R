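# Policy scenarios as configuration overlays. Environmental levers (venue
# closing time, lockout, bottle shop hours, RSA threshold) override the
# environment section of the baseline configuration from the scenario start
# date; treatment expansion is an agent-side mechanism applied annually to
# heavy drinkers. Overlays are pure: the baseline configuration object is
# never mutated.

SCENARIO_KEYS <- c("venue_closing_hour", "lockout_hour",
                   "bottle_shop_closing_hour", "rsa_refusal_bac",
                   "treatment_coverage")

#' Define a policy scenario
#'
#' @param name Scenario name.
#' @param start_date Date (or `"YYYY-MM-DD"`) from which overrides apply.
#' @param venue_closing_hour Clock hour; hours at or before the venue
#'   opening hour are interpreted as next-day (e.g. 3 means 3 a.m.).
#' @param lockout_hour Clock hour after which no new patrons are admitted
#'   (`NA` = no lockout).
#' @param bottle_shop_closing_hour Clock hour.
#' @param rsa_refusal_bac BAC threshold for responsible-service refusal.
#' @param treatment_coverage Fraction of heavy drinkers reached per year by
#'   treatment services, in \[0, 1\].
#' @return A list of class `alco_scenario`.
#' @export
#' @examples
#' scenario_closing_lockout()   # 3 a.m. closing + 1 a.m. lockout
scenario <- function(name, start_date = "2017-01-01",
                     venue_closing_hour = NULL, lockout_hour = NULL,
                     bottle_shop_closing_hour = NULL, rsa_refusal_bac = NULL,
                     treatment_coverage = NULL) {
  ov <- list(venue_closing_hour = venue_closing_hour,
             lockout_hour = lockout_hour,
             bottle_shop_closing_hour = bottle_shop_closing_hour,
             rsa_refusal_bac = rsa_refusal_bac,
             treatment_coverage = treatment_coverage)
  ov <- ov[!vapply(ov, is.null, logical(1))]
  if (!is.null(ov$treatment_coverage) &&
      (ov$treatment_coverage < 0 || ov$treatment_coverage > 1))
    stop("treatment coverage must lie in [0,1]")
  structure(list(name = name, start_date = as.Date(start_date),
                 overrides = ov), class = "alco_scenario")
}

#' The four packaged policy scenarios (plus baseline)
#'
#' Baseline ("business as usual") keeps 5 a.m. venue closing and 10 p.m.
#' bottle shop closing with no lockout. The experiments are: 3 a.m. venue
#' closing with a 1 a.m. lockout; 3 a.m. closing alone; treatment expansion
#' to 20% annual coverage of heavy drinkers; and the combination of the
#' closing/lockout and treatment levers.
#'
#' @param start_date Date the levers take effect.
#' @return An `alco_scenario`.
#' @export
scenario_baseline <- function(start_date = "2017-01-01")
  scenario("baseline", start_date)

#' @rdname scenario_baseline
#' @export
scenario_closing_lockout <- function(start_date = "2017-01-01")
  scenario("closing3am_lockout1am", start_date,
           venue_closing_hour = 3, lockout_hour = 1,
           bottle_shop_closing_hour = 22)

#' @rdname scenario_baseline
#' @export
scenario_closing_only <- function(start_date = "2017-01-01")
  scenario("closing3am", start_date, venue_closing_hour = 3)

#' @rdname scenario_baseline
#' @export
scenario_treatment <- function(start_date = "2017-01-01")
  scenario("treatment20", start_date, treatment_coverage = 0.2)

#' @rdname scenario_baseline
#' @export
scenario_combined <- function(start_date = "2017-01-01")
  scenario("closing_lockout_treatment", start_date,
           venue_closing_hour = 3, lockout_hour = 1,
           bottle_shop_closing_hour = 22, treatment_coverage = 0.2)

#' Apply a scenario overlay to a baseline configuration
#'
#' Before the scenario's start date the effective configuration equals the
#' baseline; from the start date onwards the scenario's overrides replace
#' the corresponding baseline values, leaving everything else untouched.
#' The baseline object is never modified.
#'
#' @param baseline_config An `alco_config`.
#' @param scenario An `alco_scenario` (or `NULL` for pure baseline).
#' @param clock_date The current simulation date (`Date` or string).
#' @return The effective `alco_config`.
#' @export
apply_scenario <- function(baseline_config, scenario, clock_date) {
  if (is.null(scenario)) return(baseline_config)
  stopifnot(inherits(scenario, "alco_scenario"))
  unknown <- setdiff(names(scenario$overrides), SCENARIO_KEYS)
  if (length(unknown))
    stop(errorCondition(paste("unknown scenario override key:",
                              paste(unknown, collapse = ", ")),
                        class = c("alco_config_error", "error")))
  if (as.Date(clock_date) < scenario$start_date) return(baseline_config)
  cfg <- baseline_config
  ov <- scenario$overrides
  if (!is.null(ov$venue_closing_hour)) {
    cfg$environment$venues$closing_hour <- ov$venue_closing_hour
    cfg$environment$venues$closing_wraps <-
      ov$venue_closing_hour <= cfg$environment$venues$opening_hour
  }
  if (!is.null(ov$lockout_hour))
    cfg$environment$venues$lockout_hour <- ov$lockout_hour
  if (!is.null(ov$bottle_shop_closing_hour))
    cfg$environment$bottle_shops$closing_hour <- ov$bottle_shop_closing_hour
  if (!is.null(ov$rsa_refusal_bac))
    cfg$environment$venues$rsa_refusal_bac <- ov$rsa_refusal_bac
  if (!is.null(ov$treatment_coverage))
    cfg$treatment$coverage <- ov$treatment_coverage
  cfg
}

# Fraction of baseline late-night venue entry hours (past 1 a.m., up to the
# baseline 5 a.m. close) removed by the effective configuration. 0 under
# baseline conditions, 0.5 under a 3 a.m. close alone, 1 under a 3 a.m.
# close with 1 a.m. lockout. Drives the environmental suppression of
# relapse among treated agents.
late_restriction_index <- function(effective_cfg, baseline_cfg) {
  entry_hours <- function(cfg) {
    v <- cfg$environment$venues
    open <- v$opening_hour
    close_s <- if (isTRUE(v$closing_wraps) || v$closing_hour <= open)
      v$closing_hour + 24 else v$closing_hour
    last_entry <- if (!is.na(v$lockout_hour))
      min(session_hour(v$lockout_hour, open), close_s) else close_s
    max(0, last_entry - 25)                       # hours past 1 a.m.
  }
  base <- entry_hours(baseline_cfg)
  if (base <= 0) return(0)
  max(0, min(1, 1 - entry_hours(effective_cfg) / base))
}

#' Annual treatment-expansion step
#'
#' Enrols a fraction `coverage` of currently heavy drinkers into treatment;
#' enrolled agents transition to the moderate category with the configured
#' annual probability, and previously treated agents relapse to heavy at a
#' relapse rate that is suppressed when late-night venue availability is
#' restricted (the environmental coupling through which combined
#' environment + treatment scenarios reinforce each other).
#'
#' @param population An `alco_population`.
#' @param scenario_cfg Effective configuration (after [apply_scenario()]);
#'   its `treatment$coverage` drives enrolment (0 or absent = no-op).
#' @param year Simulation year (bookkeeping only).
#' @param seed Integer seed.
#' @param baseline_cfg Baseline configuration used to compute the
#'   late-night restriction index (defaults to `scenario_cfg`, i.e. no
#'   restriction).
#' @return The updated population. `attr(pop, "treatment")` records counts
#'   of enrolled, transitioned and relapsed agents.
#' @export
treatment_step <- function(population, scenario_cfg, year, seed,
                           baseline_cfg = scenario_cfg) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  pop <- population
  tr <- scenario_cfg$treatment
  coverage <- tr$coverage %||% 0
  # relapse of previously treated agents now in moderate category
  idx_treated <- which(pop$enrolled & pop$category == 2L)
  restriction <- late_restriction_index(scenario_cfg, baseline_cfg)
  relapse_p <- tr$relapse_rate * (1 - tr$relapse_env_coupling * restriction)
  relapsed <- idx_treated[runif(length(idx_treated)) < relapse_p]
  pop$category[relapsed] <- 3L
  pop$enrolled[relapsed] <- FALSE
  n_trans <- 0L; n_enrol <- 0L
  if (coverage > 0) {
    heavy <- which(pop$category == 3L & pop$role == 1L)
    # coverage applies to heavy drinkers; representatives carry behaviour,
    # synthetic persons mirror their representative's category annually.
    # Service capacity is sized to the heavy-drinker population at rollout
    # (capacity does not shrink as prevalence falls), so the reach is
    # coverage x the reference count, capped at the current pool.
    ref <- attr(pop, "treatment_ref")
    if (is.null(ref)) {
      ref <- length(heavy)
      attr(pop, "treatment_ref") <- ref
    }
    n_enrol <- min(rbinom(1, ref, coverage), length(heavy))
    enrol <- if (n_enrol > 0) sample(heavy, n_enrol) else integer(0)
    pop$enrolled[enrol] <- TRUE
    trans <- enrol[runif(length(enrol)) < tr$effect_heavy_to_moderate]
    pop$category[trans] <- 2L
    n_trans <- length(trans)
    # non-transitioned enrolees leave the programme
    pop$enrolled[setdiff(enrol, trans)] <- FALSE
  }
  attr(pop, "treatment") <- list(enrolled = n_enrol, transitioned = n_trans,
                                 relapsed = length(relapsed),
                                 relapse_p = relapse_p)
  pop
}

#' Scenario file IO
#'
#' Scenarios round-trip through YAML overlay files; the packaged scenario
#' files live under `system.file("extdata", "scenarios", package =
#' "alcosim")`.
#'
#' @param scn An `alco_scenario`.
#' @param path YAML file path.
#' @export
write_scenario <- function(scn, path) {
  yaml::write_yaml(list(name = scn$name,
                        start_date = format(scn$start_date),
                        overrides = scn$overrides), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(scenario, c(list(name = raw$name, start_date = raw$start_date),
                      raw$overrides))
}

#' @export
print.alco_scenario <- function(x, ...) {
  cat("<alco_scenario>", x$name, "from", format(x$start_date), "\n")
  if (length(x$overrides)) {
    for (k in names(x$overrides))
      cat("  ", k, "=", x$overrides[[k]], "\n")
  } else cat("   (no overrides: baseline)\n")
  invisible(x)
}
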