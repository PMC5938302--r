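# The capability / opportunity / motivation (COM-B) rules engine. At each
# daily decision epoch a representative agent may start a consumption
# episode: capacity rules decide whether drinking is possible at all,
# opportunity weights decide where (home, licensed venue, peer event), and
# motivation distributions decide how much and how fast. Long-run average
# consumption per category is emergent from these rules and is calibrated to
# fall inside the category's definitional band.

#' Context state
#'
#' @param physical One of `"home"`, `"work"`, `"venue"`, `"bottle_shop"`,
#'   `"peer_event"`, `"transit"`.
#' @param social One of `"alone"`, `"with_friends"`, `"with_coworkers"`.
#' @param timestamp Hours since run origin.
#' @return A list of class `alco_context`.
#' @export
context_state <- function(physical = "home", social = "alone",
                          timestamp = 0) {
  stopifnot(physical %in% c("home", "work", "venue", "bottle_shop",
                            "peer_event", "transit"),
            social %in% c("alone", "with_friends", "with_coworkers"))
  if (social == "with_coworkers" && !physical %in% c("work", "venue"))
    stop("with_coworkers requires a work or venue physical context")
  structure(list(physical = physical, social = social,
                 timestamp = timestamp), class = "alco_context")
}

#' COM-B rule set
#'
#' Packages the behaviour section of a configuration into the three rule
#' groups: capacity predicates (can the agent drink now), opportunity
#' weights (where), and motivation parameters (how much, how fast).
#'
#' @param behaviour_cfg The `behaviour` section of a configuration.
#' @return A list of class `alco_comb_rules`.
#' @export
comb_rules <- function(behaviour_cfg) {
  b <- behaviour_cfg
  m <- b$intended_drinks_mean
  stopifnot(m[["heavy"]] > m[["moderate"]], m[["moderate"]] > m[["low"]])
  structure(list(
    capacity = list(severe_intoxication_bac = b$severe_intoxication_bac,
                    non_drinking_contexts = c("work", "transit",
                                              "bottle_shop")),
    opportunity = list(
      drink_day_prob = b$drink_day_prob,
      weekend_drink_mult = b$weekend_drink_mult,
      venue_prob = b$venue_prob,
      venue_weekend_mult = b$venue_weekend_mult,
      young_venue_mult = b$young_venue_mult,
      slot_hours = b$slot_hours,
      slot_weights = b$slot_weights,
      young_late_tilt = b$young_late_tilt,
      late_tilt = b$late_tilt,
      home_start_hours = b$home_start_hours,
      home_start_weights = b$home_start_weights,
      travel_time_ref = 20, travel_time_scale = 120),
    motivation = list(
      intended_drinks_mean = m,
      intended_drinks_size = b$intended_drinks_size,
      venue_intent_mult = b$venue_intent_mult,
      pace_min = b$pace_min,
      standard_drink_g = b$standard_drink_g),
    preload = list(prob = b$preload_prob,
                   young_mult = b$preload_young_mult,
                   drinks = b$preload_drinks),
    blocked_abandon_prob = b$blocked_abandon_prob,
    habit_drift_prob = b$habit_drift_prob
  ), class = "alco_comb_rules")
}

#' Capacity check
#'
#' An agent lacks capacity to start an episode if they are an abstainer,
#' dead, hospitalised, severely intoxicated, or in a non-drinking physical
#' context (work, transit, bottle shop).
#'
#' @param person List with `category` (code or label) and optional
#'   `hospitalised`, `alive`.
#' @param context An [context_state()].
#' @param rules An [comb_rules()].
#' @param bac Current BAC.
#' @return Logical.
#' @export
capacity_ok <- function(person, context, rules, bac = 0) {
  cat_code <- if (is.character(person$category))
    match(person$category, CATEGORY_LEVELS) - 1L else person$category
  if (cat_code == 0L) return(FALSE)
  if (isTRUE(person$hospitalised)) return(FALSE)
  if (identical(person$alive, FALSE)) return(FALSE)
  if (bac >= rules$capacity$severe_intoxication_bac) return(FALSE)
  if (context$physical %in% rules$capacity$non_drinking_contexts) return(FALSE)
  TRUE
}

#' Opportunity weights over feasible drinking locations
#'
#' Relative weights for `home`, `venue` and `peer_event` given category,
#' day of week, age, and the agent's venue travel time (a lognormal proxy
#' which penalises remote agents; there is no geographic routing).
#'
#' @param person List with `category` and `age`.
#' @param rules An [comb_rules()].
#' @param weekend Logical: Friday/Saturday uplift applies.
#' @param travel_time_venue Minutes to the agent's precinct.
#' @param venues_exist Logical; no venue weight when the world has none.
#' @param peer_invite Logical; a peer event is only available when invited
#'   (or hosting).
#' @return Named numeric weights (non-negative, not normalised).
#' @export
opportunity_weights <- function(person, rules, weekend = FALSE,
                                travel_time_venue = 20,
                                venues_exist = TRUE, peer_invite = FALSE) {
  o <- rules$opportunity
  cat_lab <- if (is.character(person$category)) person$category else
    CATEGORY_LEVELS[person$category + 1L]
  if (cat_lab == "abstainer")
    return(c(home = 0, venue = 0, peer_event = 0))
  pv <- o$venue_prob[[cat_lab]]
  if (weekend) pv <- pv * o$venue_weekend_mult
  if (person$age < 30) pv <- pv * o$young_venue_mult
  pv <- pv * exp(-(travel_time_venue - o$travel_time_ref) / o$travel_time_scale)
  pv <- min(pv, 0.9)
  if (!venues_exist) pv <- 0
  c(home = 1 - pv, venue = pv, peer_event = if (peer_invite) 0.5 else 0)
}

#' Decide a consumption episode for one agent-day
#'
#' Runs the COM-B cascade for a representative agent at a daily decision
#' epoch: capacity gate, drink-today draw, location draw over opportunity
#' weights (venue admissibility enforced through [venue_admission()]),
#' intended drinks from the motivation distribution, and materialisation of
#' a drink schedule at the location's pace. Venue episodes are truncated at
#' closing time and by responsible-service refusal (service stops, and the
#' patron is ejected, once BAC reaches the RSA threshold).
#'
#' @param person A list with `person_id`, `age`, `sex`, `weight`,
#'   `category`; see [get_person()].
#' @param context An [context_state()].
#' @param rules An [comb_rules()].
#' @param environment An `alco_environment` (or `NULL` for a world without
#'   venues).
#' @param clock_time Decision epoch in session hours (hours since midnight
#'   of the current day; evening decisions default to 17).
#' @param seed Integer seed.
#' @param config Full configuration (for pharmacokinetics and venue policy);
#'   defaults to [default_config()].
#' @param weekend Logical.
#' @param bac Current BAC at decision time.
#' @param peer_invite Logical.
#' @return An episode (class `alco_episode`: person_id, location, start,
#'   end, drink_times, grams, preloaded) or `NULL`.
#' @export
decide_episode <- function(person, context, rules, environment, clock_time,
                           seed, config = default_config(), weekend = FALSE,
                           bac = 0, peer_invite = FALSE) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  if (!capacity_ok(person, context, rules, bac)) return(NULL)
  cat_lab <- if (is.character(person$category)) person$category else
    CATEGORY_LEVELS[person$category + 1L]
  o <- rules$opportunity
  p_today <- o$drink_day_prob[[cat_lab]] *
    (if (weekend) o$weekend_drink_mult else 1)
  if (runif(1) >= min(p_today, 1)) return(NULL)
  venues_exist <- !is.null(environment) && nrow(environment$venues) > 0
  tt <- if (!is.null(environment)) {
    i <- match(person$person_id, environment$person_precinct, nomatch = 1)
    environment$travel_time_venue[min(i, length(environment$travel_time_venue))]
  } else 20
  w <- opportunity_weights(person, rules, weekend, tt, venues_exist,
                           peer_invite)
  if (sum(w) <= 0) return(NULL)
  location <- sample(names(w), 1, prob = w)

  preloaded <- FALSE
  start_bac <- bac
  if (location == "venue") {
    slot_w <- o$slot_weights[cat_lab, ]
    tilt <- o$late_tilt * (if (person$age < 30) o$young_late_tilt else 1)
    slot_w[o$slot_hours >= 24] <- slot_w[o$slot_hours >= 24] * tilt
    start <- sample(o$slot_hours, 1, prob = slot_w)
    # pre-loading before the venue visit
    pp <- preload_and_purchase(person, list(slot = start), rules, environment,
                               seed = seed + 1, config = config)
    if (!is.null(pp$home_episode)) {
      preloaded <- TRUE
      start_bac <- bac + attr(pp$home_episode, "end_bac")
    }
    venue <- as.list(environment$venues[1, ])
    adm <- venue_admission(person, start_bac, venue, clock_time = start %% 24)
    if (adm != "admitted") {
      if (runif(1) < rules$blocked_abandon_prob || !preloaded) return(NULL)
      location <- "home"            # drink the takeaway at home instead
      start <- max(clock_time, 19)
    }
  } else if (location == "peer_event") {
    start <- 19 + 2 * runif(1)
  } else {
    start <- sample(o$home_start_hours, 1, prob = o$home_start_weights)
  }

  m <- rules$motivation
  mu <- m$intended_drinks_mean[[cat_lab]] *
    (if (location == "venue") m$venue_intent_mult else 1)
  intended <- 1 + rnbinom(1, size = m$intended_drinks_size,
                          mu = max(mu - 1, 0.1))
  pace_h <- m$pace_min[[if (location == "venue") "venue" else
    if (location == "peer_event") "peer_event" else "home"]] / 60

  sexlab <- if (is.numeric(person$sex))
    c("male", "female")[person$sex] else person$sex
  body <- body_params(person$weight, sexlab,
    widmark_r = if (sexlab == "male") config$pharmacokinetics$widmark_r_male
                else config$pharmacokinetics$widmark_r_female,
    beta = config$pharmacokinetics$beta)
  c_inc <- widmark_increment(m$standard_drink_g, body$widmark_r, body$weight)

  n_eff <- intended
  # the severe-intoxication capacity gate stops drinking in any context
  step_all <- c_inc - body$beta * pace_h
  if (step_all > 0)
    n_eff <- min(n_eff, max(1L, ceiling(
      (rules$capacity$severe_intoxication_bac - start_bac) / step_all)))
  if (location == "venue") {
    venue <- as.list(environment$venues[1, ])
    close_s <- session_hour(venue$closing_hour, venue$opening_hour)
    n_close <- max(0L, floor((close_s - start) / pace_h) + 1L)
    n_rsa <- rsa_drink_cap(start_bac, c_inc, pace_h, body$beta,
                           venue$rsa_refusal_bac)
    n_eff <- min(intended, n_close, n_rsa)
  }
  if (n_eff < 1) return(NULL)
  drink_times <- start + (seq_len(n_eff) - 1) * pace_h
  ep <- structure(list(
    person_id = person$person_id, location = location,
    start = start, end = drink_times[n_eff] + pace_h,
    drink_times = drink_times,
    grams = rep(m$standard_drink_g, n_eff),
    preloaded = preloaded, body = body, start_bac = start_bac,
    truncated = n_eff < intended
  ), class = "alco_episode")
  ep
}

# Number of drinks that can be served before BAC reaches the RSA threshold.
# Peaks are s_i = b0 + beta*dt + i*(c - beta*dt); service stops once the
# pre-serve BAC (s_i - beta*dt) reaches the threshold.
rsa_drink_cap <- function(b0, c_inc, dt, beta, threshold) {
  step <- c_inc - beta * dt
  if (step <= 0) return(.Machine$integer.max)
  # s_i - beta*dt >= thr  <=>  i >= (thr - b0) / step
  i_stop <- ceiling((threshold - b0) / step)
  max(0L, as.integer(i_stop))
}

#' Pre-loading and takeaway purchase
#'
#' With a configured probability (higher for young and heavy agents) a
#' planned venue visit is preceded by a short home episode; the takeaway
#' purchase behind it requires a bottle shop to be open at decision time.
#'
#' @param person As in [decide_episode()].
#' @param planned_venue_visit A list with `slot` (planned session start
#'   hour).
#' @param rules An [comb_rules()].
#' @param environment An `alco_environment` (or `NULL`).
#' @param seed Integer seed.
#' @param config Full configuration.
#' @param decision_time Clock hour at which the purchase decision is made.
#' @return A list with `home_episode` (or `NULL`; carries attribute
#'   `end_bac`, the BAC handed to the venue visit) and `purchase` (or
#'   `NULL`).
#' @export
preload_and_purchase <- function(person, planned_venue_visit, rules,
                                 environment, seed,
                                 config = default_config(),
                                 decision_time = 17) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  stopifnot(!is.null(planned_venue_visit))
  cat_lab <- if (is.character(person$category)) person$category else
    CATEGORY_LEVELS[person$category + 1L]
  if (cat_lab == "abstainer") return(list(home_episode = NULL, purchase = NULL))
  p <- rules$preload$prob[[cat_lab]]
  if (person$age < 30) p <- p * rules$preload$young_mult
  shop_open <- !is.null(environment) && nrow(environment$bottle_shops) > 0 &&
    any(decision_time >= environment$bottle_shops$opening_hour &
        decision_time < environment$bottle_shops$closing_hour)
  if (!shop_open || runif(1) >= min(p, 1))
    return(list(home_episode = NULL, purchase = NULL))
  n <- rules$preload$drinks
  g <- rules$motivation$standard_drink_g
  sexlab <- if (is.numeric(person$sex))
    c("male", "female")[person$sex] else person$sex
  body <- body_params(person$weight, sexlab,
    widmark_r = if (sexlab == "male") config$pharmacokinetics$widmark_r_male
                else config$pharmacokinetics$widmark_r_female,
    beta = config$pharmacokinetics$beta)
  start <- planned_venue_visit$slot - 1
  pace_h <- 0.5
  drink_times <- start + (seq_len(n) - 1) * pace_h
  ep <- structure(list(
    person_id = person$person_id, location = "home",
    start = start, end = planned_venue_visit$slot,
    drink_times = drink_times, grams = rep(g, n),
    preloaded = TRUE, body = body, start_bac = 0, truncated = FALSE
  ), class = "alco_episode")
  end_bac <- max(0, n * widmark_increment(g, body$widmark_r, body$weight) -
                   body$beta * (planned_venue_visit$slot - start))
  attr(ep, "end_bac") <- end_bac
  purchase <- list(person_id = person$person_id, drinks = n,
                   time = decision_time)
  list(home_episode = ep, purchase = purchase)
}

#' Episode log IO
#'
#' Writes consumption episodes to CSV with columns
#' `person_id, start, end, location_type, n_drinks, grams_total, preloaded`.
#'
#' @param episodes A list of `alco_episode` objects.
#' @param path CSV path.
#' @export
write_episode_log <- function(episodes, path) {
  d <- do.call(rbind, lapply(episodes, function(e) data.frame(
    person_id = e$person_id, start = e$start, end = e$end,
    location_type = e$location, n_drinks = length(e$drink_times),
    grams_total = sum(e$grams), preloaded = e$preloaded)))
  if (is.null(d)) d <- data.frame(person_id = integer(0), start = numeric(0),
    end = numeric(0), location_type = character(0), n_drinks = integer(0),
    grams_total = numeric(0), preloaded = logical(0))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.alco_episode <- function(x, ...) {
  cat(sprintf("<alco_episode> person %s at %s: %d drinks, %.1f-%.1fh%s\n",
              x$person_id, x$location, length(x$drink_times), x$start, x$end,
              if (x$preloaded) " (preloaded)" else ""))
  invisible(x)
}
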