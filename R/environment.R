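# The physical and social world: licensed venues grouped in entertainment
# precincts, bottle shops, homes, workplaces, lognormal travel-time proxies
# (no geographic routing), a small-world friend network over representative
# agents, and Poisson-scheduled peer events hosted at home.

#' Build the simulation environment
#'
#' Creates venues grouped into precincts of configured density classes,
#' bottle shops, workplace assignments, per-person travel-time draws
#' (lognormal per density class; travel time substitutes for distance) and a
#' Watts-Strogatz small-world friend network over representative agents,
#' stratified by age band.
#'
#' @param config A model configuration ([default_config()]).
#' @param population An `alco_population`.
#' @param seed Integer seed.
#' @return A list of class `alco_environment`.
#' @export
build_environment <- function(config, population, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  env_cfg <- config$environment
  pr <- env_cfg$precincts
  n_venues_total <- sum(pr$n_precincts * pr$venues_each)
  if (n_venues_total == 0 && any(config$behaviour$venue_prob > 0))
    stop(errorCondition(
      "no venues configured but venue-dependent behaviour rules are enabled",
      class = c("alco_config_error", "error")))

  precincts <- data.frame(
    precinct_id = seq_len(sum(pr$n_precincts)),
    density_class = rep(pr$density_class, pr$n_precincts),
    stringsAsFactors = FALSE)
  cls_idx <- match(precincts$density_class, pr$density_class)
  precincts$mean_travel_time <- exp(pr$travel_time_meanlog[cls_idx] +
                                    pr$travel_time_sdlog[cls_idx]^2 / 2)
  venues_each <- pr$venues_each[cls_idx]
  v <- env_cfg$venues
  nv <- sum(venues_each)
  venues <- data.frame(
    venue_id = seq_len(nv),
    precinct_id = rep(precincts$precinct_id, venues_each),
    opening_hour = rep(v$opening_hour, nv),
    closing_hour = rep(v$closing_hour, nv),
    closing_wraps = rep(v$closing_wraps, nv),
    lockout_hour = rep(v$lockout_hour, nv),
    rsa_refusal_bac = rep(v$rsa_refusal_bac, nv))

  bs <- env_cfg$bottle_shops
  bottle_shops <- data.frame(
    shop_id = seq_len(bs$n),
    closing_hour = bs$closing_hour, opening_hour = bs$opening_hour,
    mean_travel_time = exp(bs$travel_time_meanlog + bs$travel_time_sdlog^2 / 2))

  n <- length(population$person_id)
  if (nrow(precincts) > 0) {
    person_precinct <- sample.int(nrow(precincts), n, replace = TRUE,
                                  prob = venues_each)
    pcls <- cls_idx[person_precinct]
    travel_time_venue <- exp(rnorm(n, pr$travel_time_meanlog[pcls],
                                   pr$travel_time_sdlog[pcls]))
  } else {
    person_precinct <- rep(NA_integer_, n)
    travel_time_venue <- rep(exp(pr$travel_time_meanlog[2]), n)
  }
  travel_time_shop <- exp(rnorm(n, bs$travel_time_meanlog, bs$travel_time_sdlog))
  working <- population$age < 65 & runif(n) < 0.75
  workplace_id <- ifelse(working,
                         sample.int(env_cfg$n_workplaces, n, replace = TRUE),
                         NA_integer_)

  rep_idx <- which(population$role == 1L)
  network <- friend_network(population$age[rep_idx], env_cfg$network)

  structure(list(
    venues = venues, precincts = precincts, bottle_shops = bottle_shops,
    person_precinct = person_precinct,
    travel_time_venue = travel_time_venue,
    travel_time_shop = travel_time_shop,
    workplace_id = workplace_id,
    network = network,
    network_person_id = population$person_id[rep_idx]
  ), class = c("alco_environment", "list"))
}

# Watts-Strogatz graph per age band (mean degree = 2 * nei), then combined.
friend_network <- function(ages, net_cfg, band_width = 10) {
  band <- pmin(findInterval(ages, seq(18, 78, by = band_width)), 7)
  nei <- max(1L, round(net_cfg$mean_degree / 2))
  graphs <- lapply(split(seq_along(ages), band), function(members) {
    nmem <- length(members)
    if (nmem < 2 * nei + 2) {
      g <- igraph::make_full_graph(nmem)
    } else {
      g <- igraph::sample_smallworld(1, nmem, nei, net_cfg$rewiring)
    }
    igraph::set_vertex_attr(g, "orig", value = members)
  })
  g <- Reduce(igraph::disjoint_union, graphs)
  perm <- order(igraph::vertex_attr(g, "orig"))
  igraph::permute(g, order(perm))
}

#' Venue admission decision
#'
#' Applies the door policy in precedence order closed > lockout > RSA:
#' arrival outside open hours is refused; arrival after the lockout hour is
#' refused unless the person is already inside; arrival (or service) at or
#' above the responsible-service-of-alcohol BAC threshold is refused.
#'
#' @param person Unused beyond interface symmetry (admission depends on BAC
#'   and time, not identity); may be `NULL`.
#' @param bac Current blood alcohol concentration, g/100mL.
#' @param venue A venue record (row of `environment$venues`, as a list) with
#'   `opening_hour`, `closing_hour`, `closing_wraps`, `lockout_hour`,
#'   `rsa_refusal_bac`.
#' @param clock_time Clock hour in \[0, 24).
#' @param inside Logical; is the person already inside (lockout does not
#'   apply to patrons already inside)?
#' @return One of `"admitted"`, `"refused_closed"`, `"refused_lockout"`,
#'   `"refused_rsa"`.
#' @export
#' @examples
#' v <- list(opening_hour = 12, closing_hour = 3, closing_wraps = TRUE,
#'           lockout_hour = 1, rsa_refusal_bac = 0.15)
#' venue_admission(NULL, 0, v, clock_time = 1.5)   # refused_lockout
venue_admission <- function(person, bac, venue, clock_time, inside = FALSE) {
  stopifnot(clock_time >= 0, clock_time < 24)
  open <- venue$opening_hour
  close_s <- if (isTRUE(venue$closing_wraps) || venue$closing_hour <= open)
    venue$closing_hour + 24 else venue$closing_hour
  t_s <- if (clock_time < open) clock_time + 24 else clock_time
  if (t_s < open || t_s >= close_s) return("refused_closed")
  if (!is.na(venue$lockout_hour) && !inside) {
    lock_s <- session_hour(venue$lockout_hour, open)
    if (t_s >= lock_s) return("refused_lockout")
  }
  if (bac >= venue$rsa_refusal_bac) return("refused_rsa")
  "admitted"
}

#' Schedule peer events
#'
#' Draws Poisson-distributed home-hosted peer events for each person over a
#' horizon; invitees are the host's friends (from the environment's network)
#' when available, otherwise the host alone.
#'
#' @param population An `alco_population`.
#' @param rate Events per person per year (>= 0).
#' @param seed Integer seed.
#' @param horizon Years covered.
#' @param environment Optional `alco_environment` providing the friend
#'   network.
#' @param mean_duration_hours Mean event duration.
#' @return A data.frame with one row per event: `event_id`, `host_id`,
#'   `start` (years from now), `duration` (hours), and `invitees`
#'   (list column of person ids).
#' @export
schedule_peer_events <- function(population, rate, seed, horizon = 1,
                                 environment = NULL,
                                 mean_duration_hours = 4) {
  stopifnot(rate >= 0, horizon > 0)
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- length(population$person_id)
  counts <- rpois(n, rate * horizon)
  host <- rep(population$person_id, counts)
  total <- sum(counts)
  events <- data.frame(event_id = seq_len(total), host_id = host,
                       start = runif(total, 0, horizon),
                       duration = pmax(1, rexp(total, 1 / mean_duration_hours)))
  events$invitees <- lapply(seq_len(total), function(i) {
    friends_of(environment, events$host_id[i])
  })
  events[order(events$start), , drop = FALSE]
}

#' Friends of a person
#'
#' @param environment An `alco_environment` (or `NULL`).
#' @param person_id A person id.
#' @return Integer vector of friend person ids (empty when the person is not
#'   in the network).
#' @export
friends_of <- function(environment, person_id) {
  if (is.null(environment)) return(integer(0))
  pos <- match(person_id, environment$network_person_id)
  if (is.na(pos)) return(integer(0))
  nb <- igraph::neighbors(environment$network, pos)
  environment$network_person_id[as.integer(nb)]
}

#' @export
print.alco_environment <- function(x, ...) {
  cat("<alco_environment>", nrow(x$venues), "venues in",
      nrow(x$precincts), "precincts;", nrow(x$bottle_shops),
      "bottle shops;", length(x$network_person_id),
      "networked representatives\n")
  invisible(x)
}
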