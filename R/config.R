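#' @importFrom stats rbinom rpois rnbinom rnorm runif rexp qt sd var quantile setNames aggregate pnorm qnorm
#' @importFrom utils read.csv write.csv modifyList head tail
NULL

# Categories are coded as integers throughout the engine:
#   0 = abstainer, 1 = low, 2 = moderate, 3 = heavy
CATEGORY_LEVELS <- c("abstainer", "low", "moderate", "heavy")

# Acute harm types
HARM_TYPES <- c("unintentional_injury", "alcohol_poisoning",
                "road_traffic_accident", "violence_assault",
                "chronic_exacerbation")

# Physical contexts in which acute hazards apply
CONTEXT_LEVELS <- c("home", "venue", "peer_event", "transit")

#' Default model configuration
#'
#' Returns the packaged parameterisation of the simulator: demographic
#' distributions, the drinking environment, behaviour rules, Widmark
#' pharmacokinetics, acute hazard and severity-routing tables, the chronic
#' disease model and the treatment mechanism. The published description of
#' the original model does not include its full parameter tables, so the
#' values here are a structurally faithful stand-in parameterisation whose
#' free scales were fitted by the package's own calibration harness
#' (\code{\link{calibrate}}) against the baseline target statistics
#' (mean monthly acute incidence, acute/chronic split, ED and
#' hospitalisation shares, scenario reductions and net population decline).
#'
#' Clock convention: simulation time is continuous in hours from the run
#' origin; within a day, drinking-session hours may exceed 24 (e.g. 27 means
#' 3 a.m. on the following calendar day). Venue hours are stored as clock
#' hours with a wrap flag (a closing hour at or before the opening hour
#' closes on the following day).
#'
#' @return A nested list of class \code{alco_config}.
#' @export
#' @examples
#' cfg <- default_config()
#' names(cfg)
default_config <- function() {
  cfg <- list(
    population = list(
      legal_age = 18,
      max_age = 110,
      # lower bounds of age bands (upper bound of last band = max_age)
      age_band_lower = c(18, 25, 35, 45, 55, 65, 75),
      age_band_probs = c(0.125, 0.180, 0.180, 0.175, 0.145, 0.100, 0.095),
      male_fraction = 0.49,
      weight = list(male_mean = 85, male_sd = 15,
                    female_mean = 71, female_sd = 14,
                    min = 40, max = 180),
      # P(category | age band); rows = age band, cols = abstainer/low/mod/heavy
      category_prevalence = rbind(
        c(0.18, 0.46, 0.24, 0.12),   # 18-24
        c(0.17, 0.48, 0.24, 0.11),   # 25-34
        c(0.18, 0.50, 0.23, 0.09),   # 35-44
        c(0.20, 0.51, 0.21, 0.08),   # 45-54
        c(0.22, 0.52, 0.20, 0.06),   # 55-64
        c(0.26, 0.52, 0.18, 0.04),   # 65-74
        c(0.34, 0.50, 0.13, 0.03)),  # 75+
      # Gompertz-Makeham annual hazard: a + b * exp(g * age)
      background_mortality = list(makeham_a = 3e-4,
                                  gompertz_b = 2.55e-5,
                                  gompertz_g = 0.095),
      # new legal-age (18-year-old) entrants per year per 100k alive persons
      entry_rate_per100k = 1117,
      # consumption band cut points (standard drinks/day); bands are
      # half-open: [0, low_upper) -> low, [low_upper, mod_upper) -> moderate,
      # [mod_upper, Inf) -> heavy; 0 with no episodes -> abstainer
      category_bands = list(low_upper = 2.5, moderate_upper = 6.5),
      history_years = 20
    ),
    environment = list(
      precincts = list(
        density_class = c("low", "medium", "high"),
        n_precincts   = c(4, 2, 1),
        venues_each   = c(2, 4, 8),
        travel_time_meanlog = c(log(35), log(22), log(12)),
        travel_time_sdlog   = c(0.45, 0.40, 0.35)
      ),
      venues = list(opening_hour = 12, closing_hour = 5, closing_wraps = TRUE,
                    lockout_hour = NA_real_, rsa_refusal_bac = 0.15),
      bottle_shops = list(n = 10, opening_hour = 9, closing_hour = 22,
                          travel_time_meanlog = log(12), travel_time_sdlog = 0.4),
      network = list(mean_degree = 6, rewiring = 0.1),
      peer_events = list(rate_per_year = 6, mean_duration_hours = 4),
      n_workplaces = 200
    ),
    behaviour = list(
      standard_drink_g = 10,
      # P(any drinking episode today | category), weekday
      drink_day_prob = c(abstainer = 0, low = 0.40, moderate = 0.65,
                         heavy = 0.85),
      weekend_drink_mult = 1.20,           # Fri/Sat uplift, capped at 1
      # negative-binomial intended drinks per episode
      intended_drinks_mean = c(low = 3.2, moderate = 6.5, heavy = 10.5),
      intended_drinks_size = 8,
      venue_intent_mult = 1.35,
      pace_min = c(home = 45, venue = 30, peer_event = 40),
      # P(episode located at a venue | category), weekday
      venue_prob = c(low = 0.07, moderate = 0.16, heavy = 0.32),
      venue_weekend_mult = 1.9,
      young_venue_mult = 1.5,              # ages 18-29
      # venue arrival-slot weights over session hours 18/20/22/24/26
      slot_hours = c(18, 20, 22, 24, 26),
      slot_weights = rbind(
        low      = c(0.36, 0.34, 0.20, 0.08, 0.02),
        moderate = c(0.20, 0.28, 0.29, 0.16, 0.07),
        heavy    = c(0.08, 0.15, 0.26, 0.22, 0.29)),
      young_late_tilt = 1.8,               # multiplies 24/26 slots, ages 18-29
      late_tilt = 0.87,                    # calibrated global late-slot tilt
      # home/peer episode start hours (session frame) and weights
      home_start_hours = c(17, 19, 21),
      home_start_weights = c(0.25, 0.5, 0.25),
      preload_prob = c(low = 0.05, moderate = 0.15, heavy = 0.30),
      preload_young_mult = 1.5,
      preload_drinks = 2,
      # probability an agent blocked by lockout/closing simply goes home
      # (no compensatory episode); remainder drink at home only if they
      # already hold takeaway alcohol (preloaders)
      blocked_abandon_prob = 1.0,
      habit_drift_prob = 0.028,
      severe_intoxication_bac = 0.25       # capacity gate: too drunk to start
    ),
    pharmacokinetics = list(
      widmark_r_male = 0.68,
      widmark_r_female = 0.55,
      beta = 0.015                          # g/100mL eliminated per hour
    ),
    acute_hazards = list(
      scale = 2.70e-07,                     # calibrated global scale, events/h
      base = c(unintentional_injury = 1.00, alcohol_poisoning = 0.28,
               road_traffic_accident = 6.0, violence_assault = 0.95,
               chronic_exacerbation = 6.2),
      bac_slope = c(unintentional_injury = 17, alcohol_poisoning = 20,
                    road_traffic_accident = 22, violence_assault = 19,
                    chronic_exacerbation = 10),
      # multiplier by sex (male, female) per type
      sex_mult = rbind(
        unintentional_injury  = c(male = 1.3, female = 1.0),
        alcohol_poisoning     = c(male = 1.0, female = 1.0),
        road_traffic_accident = c(male = 1.4, female = 1.0),
        violence_assault      = c(male = 2.5, female = 1.0),
        chronic_exacerbation  = c(male = 1.2, female = 1.0)),
      # multiplier by age band (same bands as population$age_band_lower)
      age_mult = c(2.0, 1.5, 1.1, 0.9, 0.7, 0.5, 0.4),
      # multiplier by context per type; road traffic only in transit
      context_mult = rbind(
        unintentional_injury  = c(home = 0.7, venue = 2.0, peer_event = 1.1, transit = 0.4),
        alcohol_poisoning     = c(home = 1.0, venue = 1.2, peer_event = 1.0, transit = 0.0),
        road_traffic_accident = c(home = 0.0, venue = 0.0, peer_event = 0.0, transit = 1.0),
        violence_assault      = c(home = 0.2, venue = 4.0, peer_event = 1.0, transit = 1.2),
        chronic_exacerbation  = c(home = 0.8, venue = 0.6, peer_event = 0.7, transit = 0.2)),
      exacerbation_heavy_only = TRUE
    ),
    severity_routing = list(
      ed       = c(unintentional_injury = 0.80, alcohol_poisoning = 0.85,
                   road_traffic_accident = 0.90, violence_assault = 0.25,
                   chronic_exacerbation = 0.50),
      hospital = c(unintentional_injury = 0.70, alcohol_poisoning = 0.30,
                   road_traffic_accident = 0.60, violence_assault = 0.05,
                   chronic_exacerbation = 0.95),
      death    = c(unintentional_injury = 0.004, alcohol_poisoning = 0.010,
                   road_traffic_accident = 0.015, violence_assault = 0.002,
                   chronic_exacerbation = 0.008),
      ed_scale = 1.10,                      # calibration knobs
      hosp_scale = 0.955
    ),
    chronic_model = list(
      scale = 0.271,                        # calibrated incidence scale
      conditions = chronic_condition_table()
    ),
    treatment = list(
      effect_heavy_to_moderate = 0.95,      # P(transition | enrolled), annual
      relapse_rate = 0.88,                  # P(return to heavy)/yr, permissive env
      # relapse falls as late-night venue availability is restricted:
      # relapse' = relapse_rate * (1 - coupling * restriction_index)
      relapse_env_coupling = 0.97,
      # habit formation: annual drift into the heavy category is suppressed
      # in proportion to the restriction of late-night venue entry
      habit_env_coupling = 0.95
    )
  )
  class(cfg) <- c("alco_config", "list")
  cfg
}

#' Chronic condition parameter table
#'
#' The alcohol-related chronic conditions carried by the model, with relative
#' risks by drinking category, baseline annual incidence by age band
#' (per 100,000/year, scaled by \code{chronic_model$scale}), mean illness
#' duration, annual emergency-department and hospitalisation probabilities
#' while ill, and annual case fatality. Conditions marked wholly attributable
#' (alcoholic liver cirrhosis, alcohol use disorder) have attributable
#' fraction 1 and their \code{rr_*} columns act as category incidence
#' weights rather than relative risks.
#'
#' @return A data.frame with one row per condition.
#' @export
chronic_condition_table <- function() {
  inc <- function(...) I(list(c(...)))
  d <- data.frame(
    condition = c("lip_oral_pharyngeal_cancer", "oesophageal_cancer",
                  "liver_cancer", "female_breast_cancer", "colorectal_cancer",
                  "hypertensive_diseases", "ischaemic_heart_disease",
                  "haemorrhagic_stroke", "alcoholic_liver_cirrhosis",
                  "alcohol_use_disorder"),
    female_only = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE),
    wholly_attributable = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                            FALSE, TRUE, TRUE),
    rr_low      = c(1.20, 1.10, 1.10, 1.05, 1.05, 1.10, 1.00, 1.10, 0.02, 0.01),
    rr_moderate = c(1.80, 1.50, 1.50, 1.15, 1.20, 1.40, 1.10, 1.30, 0.30, 0.20),
    rr_heavy    = c(3.00, 2.50, 2.50, 1.40, 1.50, 2.00, 1.30, 1.80, 3.00, 4.00),
    duration_years = c(6, 5, 5, 8, 6, 20, 15, 8, 10, 12),
    ed_annual   = c(0.25, 0.30, 0.30, 0.20, 0.25, 0.15, 0.30, 0.35, 0.40, 0.45),
    hosp_annual = c(0.40, 0.45, 0.45, 0.35, 0.40, 0.15, 0.35, 0.40, 0.45, 0.30),
    case_fatality_annual = c(0.08, 0.12, 0.12, 0.04, 0.06, 0.01, 0.05, 0.10,
                             0.06, 0.01),
    stringsAsFactors = FALSE
  )
  # baseline incidence per 100k/yr at age bands 18-24/25-34/35-44/45-54/55-64/65-74/75+
  d$incidence_per100k <- I(list(
    c(0.5, 1, 3, 8, 15, 20, 20),       # lip/oral/pharyngeal cancer
    c(0.2, 0.5, 1.5, 5, 12, 20, 25),   # oesophageal cancer
    c(0.2, 0.5, 1.5, 5, 12, 18, 20),   # liver cancer
    c(5, 15, 40, 80, 100, 110, 100),   # female breast cancer
    c(1, 3, 10, 30, 70, 120, 150),     # colorectal cancer
    c(10, 30, 80, 150, 250, 350, 400), # hypertensive diseases
    c(2, 10, 40, 120, 250, 400, 500),  # ischaemic heart disease
    c(1, 3, 8, 20, 50, 100, 180),      # haemorrhagic stroke
    c(1, 5, 15, 25, 30, 25, 15),       # alcoholic liver cirrhosis
    c(40, 35, 25, 15, 8, 4, 2)         # alcohol use disorder
  ))
  d
}

#' Validate a model configuration
#'
#' Checks structural and probabilistic invariants of a configuration:
#' probability tables normalise, hazards and rates are non-negative,
#' background mortality is non-decreasing above age 30, venue hours are
#' consistent, and routing probabilities lie in \[0, 1\].
#'
#' @param config A configuration list as produced by [default_config()].
#' @return The config, invisibly, if valid; otherwise an error of class
#'   \code{alco_config_error}.
#' @export
validate_config <- function(config) {
  fail <- function(msg) stop(errorCondition(msg,
    class = c("alco_config_error", "error")))
  p <- config$population
  if (abs(sum(p$age_band_probs) - 1) > 1e-9)
    fail("age band probabilities must sum to 1")
  if (any(p$age_band_probs < 0)) fail("negative age band probability")
  if (!is.matrix(p$category_prevalence) ||
      nrow(p$category_prevalence) != length(p$age_band_lower))
    fail("category_prevalence must have one row per age band")
  if (any(abs(rowSums(p$category_prevalence) - 1) > 1e-9))
    fail("category prevalence rows must sum to 1")
  if (any(p$category_prevalence < 0)) fail("negative category prevalence")
  if (p$male_fraction < 0 || p$male_fraction > 1)
    fail("male_fraction outside [0,1]")
  bm <- p$background_mortality
  ages <- seq(30, p$max_age, by = 1)
  haz <- bm$makeham_a + bm$gompertz_b * exp(bm$gompertz_g * ages)
  if (any(diff(haz) < 0))
    fail("background mortality must be non-decreasing above age 30")
  ph <- config$pharmacokinetics
  if (ph$widmark_r_male <= 0 || ph$widmark_r_male >= 1 ||
      ph$widmark_r_female <= 0 || ph$widmark_r_female >= 1)
    fail("Widmark r must lie in (0,1)")
  if (ph$beta <= 0) fail("elimination rate beta must be positive")
  v <- config$environment$venues
  if (!isTRUE(v$closing_wraps) && v$closing_hour <= v$opening_hour)
    fail("venue open interval is empty")
  if (!is.na(v$lockout_hour)) {
    lh <- session_hour(v$lockout_hour, v$opening_hour)
    ch <- session_hour(v$closing_hour, v$opening_hour)
    if (lh > ch) fail("lockout_hour must lie within venue open hours")
  }
  bs <- config$environment$bottle_shops
  if (bs$closing_hour < 0 || bs$closing_hour >= 24)
    fail("bottle shop closing_hour must lie in [0,24)")
  ah <- config$acute_hazards
  if (any(ah$base < 0) || ah$scale < 0) fail("acute hazards must be >= 0")
  if (any(ah$bac_slope < 0)) fail("BAC multiplier must be non-decreasing")
  r <- config$severity_routing
  for (nm in c("ed", "hospital", "death"))
    if (any(r[[nm]] < 0 | r[[nm]] > 1))
      fail(sprintf("severity routing '%s' outside [0,1]", nm))
  cm <- config$chronic_model$conditions
  if (any(!cm$wholly_attributable &
          (cm$rr_low < 1 | cm$rr_moderate < 1 | cm$rr_heavy < 1)))
    fail("relative risks below 1 are out of scope for harmful exposure")
  if (any(cm$duration_years <= 0)) fail("chronic durations must be positive")
  tr <- config$treatment
  if (tr$relapse_rate < 0 || tr$relapse_rate > 1 ||
      tr$effect_heavy_to_moderate < 0 || tr$effect_heavy_to_moderate > 1)
    fail("treatment probabilities outside [0,1]")
  b <- config$behaviour
  m <- b$intended_drinks_mean
  if (!(m[["heavy"]] > m[["moderate"]] && m[["moderate"]] > m[["low"]]))
    fail("intended drinks must order heavy > moderate > low")
  invisible(config)
}

# Convert a clock hour to the drinking-session frame anchored at the venue
# opening hour: hours at or before `anchor` are interpreted as next-day.
session_hour <- function(clock_hour, anchor) {
  ifelse(clock_hour <= anchor, clock_hour + 24, clock_hour)
}

#' Read / write configurations as YAML
#'
#' The configuration tree is YAML-compatible; matrices are stored as lists of
#' named rows and restored on read.
#'
#' @param config A configuration list.
#' @param path File path.
#' @return `read_config` returns an \code{alco_config}; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  serialize <- function(x) {
    if (is.data.frame(x)) {
      c(list(.conditions = TRUE), list(rows = serialize_conditions(x)))
    } else if (is.matrix(x)) {
      rows <- lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
      names(rows) <- rownames(x) %||% paste0("row", seq_len(nrow(x)))
      c(list(.matrix = TRUE), rows)
    } else if (is.atomic(x) && !is.null(names(x))) {
      # named vectors would be indistinguishable from sub-sections
      c(list(.vector = TRUE), as.list(x))
    } else if (is.list(x)) {
      lapply(x, serialize)
    } else x
  }
  yaml::write_yaml(serialize(unclass(config)), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  restore <- function(x) {
    if (!is.list(x)) return(x)
    if (isTRUE(x$.conditions)) return(deserialize_conditions(x$rows))
    if (isTRUE(x$.matrix)) {
      rows <- x[setdiff(names(x), ".matrix")]
      m <- do.call(rbind, lapply(rows, function(r) unlist(r)))
      rownames(m) <- names(rows)
      return(m)
    }
    if (isTRUE(x$.vector))
      return(unlist(x[setdiff(names(x), ".vector")]))
    lapply(x, restore)
  }
  cfg <- restore(raw)
  class(cfg) <- c("alco_config", "list")
  cfg
}

serialize_conditions <- function(d) {
  lapply(seq_len(nrow(d)), function(i) {
    row <- as.list(d[i, setdiff(names(d), "incidence_per100k")])
    row <- lapply(row, function(v) if (inherits(v, "AsIs")) unclass(v)[[1]] else v)
    row$incidence_per100k <- as.numeric(d$incidence_per100k[[i]])
    row
  })
}

deserialize_conditions <- function(rows) {
  base <- do.call(rbind, lapply(rows, function(r) {
    data.frame(r[setdiff(names(r), "incidence_per100k")],
               stringsAsFactors = FALSE)
  }))
  base$incidence_per100k <- I(lapply(rows, function(r)
    as.numeric(unlist(r$incidence_per100k))))
  rownames(base) <- NULL
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.alco_config <- function(x, ...) {
  cat("<alco_config>\n")
  cat("  age bands:", length(x$population$age_band_lower),
      "| venues:", sum(x$environment$precincts$n_precincts *
                       x$environment$precincts$venues_each),
      "in", sum(x$environment$precincts$n_precincts), "precincts",
      "| bottle shops:", x$environment$bottle_shops$n, "\n")
  v <- x$environment$venues
  cat(sprintf("  venue hours: %02d:00-%02d:00%s, lockout %s, RSA at BAC %.2f\n",
              v$opening_hour, v$closing_hour,
              if (isTRUE(v$closing_wraps)) " (+1d)" else "",
              if (is.na(v$lockout_hour)) "none" else
                sprintf("%02d:00", v$lockout_hour),
              v$rsa_refusal_bac))
  cat("  acute hazard scale:", x$acute_hazards$scale,
      "| chronic scale:", x$chronic_model$scale, "\n")
  invisible(x)
}
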