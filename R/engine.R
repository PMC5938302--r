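# Simulation orchestration. Each replicate synthesises a population and
# environment, spins up under baseline conditions (2011-2016 by default),
# then simulates the scenario window (2017-2021) with the scenario overlay
# active from its start date. Scheduling is hybrid: daily behavioural
# decision epochs (vectorised a month at a time), continuous-time BAC within
# episodes via closed-form Widmark integrals, monthly demography and event
# accounting, and annual consumption/category/chronic/treatment passes.
# Per-replicate seeds are derived deterministically from the master seed, so
# identical (seed, configs) give bit-identical event logs.

#' Run specification
#'
#' @param seed Master integer seed; all replicate randomness derives from it.
#' @param n_replicates Number of replicate runs (default 12).
#' @param population_size Number of agents (default 50,000; outputs are
#'   per-100k so results are scale-free to first order).
#' @param representative_fraction Fraction of agents modelled in behavioural
#'   detail (default 0.05).
#' @param spin_up_start,spin_up_end Calibration/spin-up window run under
#'   baseline conditions regardless of scenario.
#' @param window_start,window_end Scenario/reporting window.
#' @return A list of class `alco_run_spec`.
#' @export
run_spec <- function(seed, n_replicates = 12, population_size = 50000,
                     representative_fraction = 0.05,
                     spin_up_start = "2011-01-01",
                     spin_up_end = "2016-12-31",
                     window_start = "2017-01-01",
                     window_end = "2021-12-31") {
  spec <- list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
               population_size = as.integer(population_size),
               representative_fraction = representative_fraction,
               spin_up_start = as.Date(spin_up_start),
               spin_up_end = as.Date(spin_up_end),
               window_start = as.Date(window_start),
               window_end = as.Date(window_end))
  if (spec$n_replicates < 1) stop("n_replicates must be >= 1")
  if (spec$window_start <= spec$spin_up_end)
    stop(errorCondition("scenario window must start after spin-up ends",
                        class = c("alco_config_error", "error")))
  class(spec) <- c("alco_run_spec", "list")
  spec
}

#' Derive a replicate seed from the master seed
#'
#' Counter-based derivation keeping the result inside the 32-bit integer
#' range; distinct counters give distinct, reproducible streams.
#'
#' @param master Master seed.
#' @param counter Replicate (or subsystem) counter.
#' @return An integer seed.
#' @export
derive_seed <- function(master, counter) {
  x <- ((as.double(master) %% 2147483647) * 48271 +
          as.double(counter) * 1009) %% 2147483647
  as.integer(x)
}

#' Run a simulation experiment
#'
#' Executes `n_replicates` independent replicates of the model under a
#' scenario overlay (or pure baseline when `scenario` is `NULL` or has no
#' overrides). The spin-up window always runs under baseline conditions; a
#' scenario whose `start_date` precedes the end of spin-up is a
#' configuration error.
#'
#' @param spec An [run_spec()].
#' @param baseline_config An `alco_config` ([default_config()]).
#' @param scenario An `alco_scenario` or `NULL`.
#' @param progress Print per-replicate progress.
#' @return A list of class `alco_run`: `replicates` (each with `event_log`,
#'   `pop_series`, `summary`), `months` (month table), `spec`, `scenario`,
#'   and a `manifest` (seeds and settings).
#' @export
run <- function(spec, baseline_config = default_config(), scenario = NULL,
                progress = FALSE) {
  validate_config(baseline_config)
  if (!is.null(scenario) && scenario$start_date <= spec$spin_up_end)
    stop(errorCondition("scenario starts before spin-up ends",
                        class = c("alco_config_error", "error")))
  months <- month_table(spec)
  reps <- vector("list", spec$n_replicates)
  for (i in seq_len(spec$n_replicates)) {
    if (progress) message("replicate ", i, "/", spec$n_replicates)
    reps[[i]] <- sim_replicate(spec, baseline_config, scenario,
                               derive_seed(spec$seed, i), months)
  }
  structure(list(
    replicates = reps, months = months, spec = spec, scenario = scenario,
    manifest = list(
      seed = spec$seed,
      replicate_seeds = vapply(seq_len(spec$n_replicates),
                               function(i) derive_seed(spec$seed, i),
                               integer(1)),
      n_agents = spec$population_size,
      scenario = if (is.null(scenario)) "baseline" else scenario$name,
      package_version = as.character(utils::packageVersion("alcosim")))
  ), class = c("alco_run", "list"))
}

# Calendar month table covering spin-up + scenario window.
month_table <- function(spec) {
  starts <- seq(spec$spin_up_start, spec$window_end, by = "month")
  ends <- c(starts[-1] - 1, spec$window_end)
  data.frame(month = seq_along(starts), start = starts, end = ends,
             days = as.integer(ends - starts) + 1L,
             day0 = as.integer(starts - spec$spin_up_start),
             in_window = starts >= spec$window_start,
             is_december = format(starts, "%m") == "12")
}

# ---- one replicate --------------------------------------------------------

sim_replicate <- function(spec, baseline_cfg, scn, rep_seed, months) {
  dm <- demographic_model(baseline_cfg$population)
  st <- init_population(dm, spec$population_size,
                        spec$representative_fraction,
                        seed = derive_seed(rep_seed, 1))
  env <- build_environment(baseline_cfg, st, seed = derive_seed(rep_seed, 2))
  # fold per-person environment attributes and engine state into one
  # column-wise state object so person removal stays generic
  n <- length(st$person_id)
  st$tt_venue <- env$travel_time_venue
  st$tt_shop <- env$travel_time_shop
  st$ann_drinks <- numeric(n)
  C <- nrow(baseline_cfg$chronic_model$conditions)
  st$ill_active <- matrix(FALSE, n, C)
  st$ill_years <- matrix(0, n, C)

  set.seed(derive_seed(rep_seed, 3))
  bands <- baseline_cfg$population$age_band_lower
  logs <- vector("list", nrow(months))
  pop_series <- data.frame(month = months$month,
                           denominator = NA_real_)
  year_count <- 0L

  for (m in seq_len(nrow(months))) {
    eff <- apply_scenario(baseline_cfg, scn, months$start[m])
    pop_series$denominator[m] <- sum(st$alive)

    out <- sim_month(st, eff, months[m, ], bands)
    st <- out$state
    ev <- out$events
    if (!is.null(ev) && nrow(ev)) {
      ev$month <- months$month[m]
      logs[[m]] <- ev
      # deaths from acute events: marked now, removed at the year boundary
      dead_idx <- match(unique(ev$person_id[ev$death]), st$person_id)
      dead_idx <- dead_idx[!is.na(dead_idx)]
      st$alive[dead_idx] <- FALSE
    }

    # monthly ageing + background mortality (dead persons are flagged and
    # physically removed at the year boundary; entrants also join there)
    dt <- months$days[m] / 365.25
    st$age <- st$age + dt
    haz <- mortality_hazard(st$age, dm$background_mortality)
    p_die <- (1 - exp(-haz * dt)) * st$alive
    p_die[st$age >= dm$max_age & st$alive] <- 1
    st$alive[runif(length(st$age)) < p_die] <- FALSE

    if (months$is_december[m]) {
      year_count <- year_count + 1L
      st <- remove_persons(st, which(!st$alive))
      res <- annual_pass(st, eff, baseline_cfg, dm,
                         seed = derive_seed(rep_seed, 100 + year_count))
      st <- res$state
      if (nrow(res$events)) {
        res$events$month <- months$month[m]
        logs[[m]] <- rbind(logs[[m]], res$events)
      }
      if (length(res$deaths)) st <- remove_persons(st, res$deaths)
      # new legal-age entrants join at the year boundary
      st <- engine_entrants(st, dm, 1, baseline_cfg)
    }
  }
  event_log <- data.table::rbindlist(logs[!vapply(logs, is.null, logical(1))])
  event_log <- as.data.frame(event_log)
  list(event_log = event_log, pop_series = pop_series,
       summary = list(final_n = length(st$person_id),
                      final_categories = tabulate(st$category + 1L, 4L)))
}

# legal-age entrants for `dt` years, with engine-state extension fields
engine_entrants <- function(st, dm, dt, cfg) {
  expected <- dm$entry_rate_per100k / 1e5 * length(st$person_id) * dt
  n_new <- rpois(1, expected)
  if (n_new > 0) {
    n_old <- length(st$person_id)
    st <- add_entrants(st, dm, n_new)
    idx <- n_old + seq_len(n_new)
    pr <- cfg$environment$precincts
    cls <- sample.int(length(pr$density_class), n_new, replace = TRUE,
                      prob = pr$n_precincts * pr$venues_each)
    st$tt_venue[idx] <- exp(rnorm(n_new, pr$travel_time_meanlog[cls],
                                  pr$travel_time_sdlog[cls]))
    bs <- cfg$environment$bottle_shops
    st$tt_shop[idx] <- exp(rnorm(n_new, bs$travel_time_meanlog,
                                 bs$travel_time_sdlog))
    st$ann_drinks[idx] <- 0
  }
  st
}

# ---- one month of behaviour + acute harms (vectorised) --------------------

sim_month <- function(st, cfg, minfo, bands) {
  b <- cfg$behaviour
  ah <- cfg$acute_hazards
  ph <- cfg$pharmacokinetics
  v <- cfg$environment$venues
  open_h <- v$opening_hour
  close_s <- if (isTRUE(v$closing_wraps) || v$closing_hour <= open_h)
    v$closing_hour + 24 else v$closing_hour
  lock_s <- if (is.na(v$lockout_hour)) Inf else
    session_hour(v$lockout_hour, open_h)
  bs <- cfg$environment$bottle_shops
  shop_open_17 <- bs$n > 0 && bs$opening_hour <= 17 && bs$closing_hour > 17

  reps <- which(st$role == 1L & st$category > 0L & st$alive)
  nr <- length(reps)
  D <- minfo$days
  if (nr == 0) return(list(state = st, events = NULL))
  dow <- as.integer(format(seq(minfo$start, by = "day", length.out = D),
                           "%u"))
  weekend <- dow %in% c(5L, 6L)                 # Friday, Saturday

  cat_r <- st$category[reps]                    # 1..3
  age_r <- st$age[reps]
  sex_r <- st$sex[reps]
  band_r <- age_band(pmin(age_r, 100), bands)
  young_r <- age_r < 30
  r_w <- c(ph$widmark_r_male, ph$widmark_r_female)[sex_r]
  cinc_r <- widmark_increment(b$standard_drink_g, r_w, st$weight[reps])
  ttpen_r <- exp(-(st$tt_venue[reps] - 20) / 120)

  # --- daily drink decision over the rep x day grid
  p_day <- unname(b$drink_day_prob)[cat_r + 1L]
  wk_mult <- 1 + (b$weekend_drink_mult - 1) * weekend
  p_cell <- rep(p_day, D) * rep(wk_mult, each = nr)
  cells <- which(runif(nr * D) < pmin(p_cell, 1))
  if (!length(cells)) return(list(state = st, events = NULL))
  ri <- ((cells - 1L) %% nr) + 1L               # rep index within reps
  di <- ((cells - 1L) %/% nr) + 1L              # day of month
  ne <- length(cells)

  # --- location
  young_e <- young_r[ri]
  pv <- unname(b$venue_prob)[cat_r[ri]] *
    (1 + (b$venue_weekend_mult - 1) * weekend[di]) *
    (1 + (b$young_venue_mult - 1) * young_e) * ttpen_r[ri]
  pv <- pmin(pv, 0.9)
  venues_exist <- nrow_venues(cfg) > 0
  if (!venues_exist) pv <- 0
  at_venue <- runif(ne) < pv
  p_peer <- cfg$environment$peer_events$rate_per_year / 365
  at_peer <- !at_venue & (runif(ne) < p_peer * 2)  # host + invited attendance
  ctx <- 1L + at_venue + 2L * at_peer           # 1 home / 2 venue / 3 peer

  # --- start times
  start_s <- numeric(ne)
  iv <- which(at_venue)
  if (length(iv)) {
    W <- b$slot_weights[cat_r[ri[iv]], , drop = FALSE]
    late <- b$slot_hours >= 24
    tilt <- b$late_tilt * (1 + (b$young_late_tilt - 1) * young_e[iv])
    W[, late] <- W[, late] * tilt
    u <- runif(length(iv)) * rowSums(W)
    acc <- W[, 1]
    slot_idx <- rep(1L, length(iv))
    for (jj in 2:ncol(W)) {
      slot_idx <- slot_idx + (u > acc)
      acc <- acc + W[, jj]
    }
    start_s[iv] <- b$slot_hours[slot_idx]
  }
  ih <- which(!at_venue & !at_peer)
  start_s[ih] <- sample(b$home_start_hours, length(ih), replace = TRUE,
                        prob = b$home_start_weights)
  ip <- which(at_peer)
  start_s[ip] <- 19 + 2 * runif(length(ip))

  # --- pre-loading (venue visits only, requires an open bottle shop)
  ppl <- (at_venue & shop_open_17) *
    unname(b$preload_prob)[cat_r[ri]] *
    (1 + (b$preload_young_mult - 1) * young_e)
  preload <- runif(ne) < pmin(ppl, 1)
  beta <- ph$beta
  b0 <- preload * pmax(0, b$preload_drinks * cinc_r[ri] - 1.5 * beta)

  # --- admission (closed > lockout; arrival BAC never reaches RSA here)
  blocked <- at_venue & (start_s >= pmin(close_s, lock_s))
  # blocked patrons abandon the outing (bottle shops are shut late at night)
  keep <- !blocked | runif(ne) >= b$blocked_abandon_prob
  keep <- keep & !blocked                        # abandon_prob = 1 default
  if (!all(keep)) {
    ri <- ri[keep]; di <- di[keep]; ctx <- ctx[keep]; start_s <- start_s[keep]
    at_venue <- at_venue[keep]; preload <- preload[keep]; b0 <- b0[keep]
    ne <- length(ri)
    if (!ne) return(list(state = st, events = NULL))
  }

  # --- motivation: intended drinks and pace
  mu <- unname(b$intended_drinks_mean)[cat_r[ri]] *
    (1 + (b$venue_intent_mult - 1) * at_venue)
  n_int <- 1L + rnbinom(ne, size = b$intended_drinks_size,
                        mu = pmax(mu - 1, 0.1))
  pace <- unname(b$pace_min)[ctx_pace_index(ctx)] / 60

  # --- truncation: the severe-intoxication capacity gate stops drinking in
  # any context; venues additionally truncate at closing time and at the
  # RSA refusal threshold
  cinc_e <- cinc_r[ri]
  step_all <- pmax(cinc_e - beta * pace, 1e-9)
  n_sev <- pmax(1, ceiling((b$severe_intoxication_bac - b0) / step_all))
  n_eff <- pmin(n_int, n_sev)
  if (length(iv <- which(at_venue))) {
    n_close <- pmax(0, floor((close_s - start_s[iv]) / pace[iv]) + 1)
    n_rsa <- pmax(1, ceiling((v$rsa_refusal_bac - b0[iv]) / step_all[iv]))
    n_eff[iv] <- pmin(n_eff[iv], n_close, n_rsa)
  }
  n_eff <- as.integer(n_eff)
  ok <- n_eff >= 1L
  if (!all(ok)) {
    ri <- ri[ok]; di <- di[ok]; ctx <- ctx[ok]; start_s <- start_s[ok]
    at_venue <- at_venue[ok]; preload <- preload[ok]; b0 <- b0[ok]
    n_int <- n_int[ok]; n_eff <- n_eff[ok]; pace <- pace[ok]
    cinc_e <- cinc_e[ok]
    ne <- length(ri)
    if (!ne) return(list(state = st, events = NULL))
  }

  # --- append pre-load mini-episodes as home-context rows
  ipl <- which(preload)
  if (length(ipl)) {
    ri <- c(ri, ri[ipl]); di <- c(di, di[ipl])
    ctx <- c(ctx, rep(1L, length(ipl)))
    start_s <- c(start_s, start_s[ipl] - 1)
    at_venue <- c(at_venue, rep(FALSE, length(ipl)))
    n_eff <- c(n_eff, rep(b$preload_drinks, length(ipl)))
    pace <- c(pace, rep(0.5, length(ipl)))
    cinc_e <- c(cinc_e, cinc_e[ipl])
    b0 <- c(b0, rep(0, length(ipl)))
    ne <- length(ri)
  }

  # --- intensity integrals per harm type and phase
  # Components are indexed (type, site): sites 1-3 are the drinking phase
  # split by episode context (home / venue / peer event), site 4 the transit
  # phase after a venue episode, site 5 the post-episode decay tail at home.
  iv <- which(at_venue)
  tt_h <- st$tt_venue[reps[ri[iv]]] / 60
  base_cov <- ah$scale * (ah$age_mult[band_r[ri]]) # per-cell covariate part
  sex_e <- sex_r[ri]
  heavy_e <- cat_r[ri] == 3L
  # sawtooth geometry shared across harm types:
  # post-drink peaks s_i = s_base + i * step_all, i = 1..n_eff
  step_all <- pmax(cinc_e - beta * pace, 1e-9)   # episode set changed above
  m_seg <- n_eff - 1L
  s_base <- b0 + beta * pace
  end_bac <- pmax(b0 + n_eff * cinc_e - m_seg * beta * pace, 0)
  bac_tail <- end_bac
  bac_tail[iv] <- pmax(end_bac[iv] - beta * tt_h, 0)
  site_names <- c("home", "venue", "peer_event", "transit", "home")
  lam25 <- matrix(0, ne, 25)
  is_home <- ctx == 1L; is_ven <- ctx == 2L; is_peer <- ctx == 3L
  sexm <- ah$sex_mult
  ctxm <- ah$context_mult
  for (t in 1:5) {
    k <- ah$bac_slope[t]
    o <- (t - 1L) * 5L
    bt <- base_cov * ah$base[t] * sexm[t, ][sex_e]
    if (t == 5L && isTRUE(ah$exacerbation_heavy_only))
      bt <- bt * heavy_e
    kb <- k * beta
    # drinking phase: geometric sum over inter-drink segments
    seg_factor <- -expm1(-kb * pace) / kb
    d <- expm1(k * step_all)
    d[abs(d) < 1e-12] <- 1e-12
    gsum <- exp(k * s_base) * (1 + d) * ((1 + d)^m_seg - 1) / d
    main <- bt * ctxm[t, ][ctx] * gsum * seg_factor
    lam25[, o + 1L] <- main * is_home
    lam25[, o + 2L] <- main * is_ven
    lam25[, o + 3L] <- main * is_peer
    # transit phase (venue episodes only); sober remainder at multiplier 1
    if (length(iv) && ctxm[t, "transit"] > 0) {
      t_eff <- pmin(tt_h, end_bac[iv] / beta)
      tr <- (exp(k * end_bac[iv]) -
               exp(k * (end_bac[iv] - beta * t_eff))) / kb + (tt_h - t_eff)
      lam25[iv, o + 4L] <- bt[iv] * ctxm[t, "transit"] * tr
    }
    # decay-to-zero tail at home
    lam25[, o + 5L] <- bt * ctxm[t, "home"] * expm1(k * bac_tail) / kb
  }
  lam_tot <- .rowSums(lam25, ne, 25L)

  # --- representative events
  n_ev <- rpois(ne, lam_tot)
  ev_rows <- list()
  hit <- which(n_ev > 0)
  tt_h_all <- numeric(ne); tt_h_all[iv] <- tt_h
  for (i in hit) {
    for (e in seq_len(n_ev[i])) {
      comp <- sample.int(25, 1, prob = lam25[i, ])
      t <- ((comp - 1L) %/% 5L) + 1L
      site <- ((comp - 1L) %% 5L) + 1L
      phase <- c(1L, 1L, 1L, 2L, 3L)[site]
      etime <- event_time_in_phase(phase, ah$bac_slope[t], n_eff[i],
                                   cinc_e[i], pace[i], beta, b0[i],
                                   start_s[i], end_bac[i], tt_h_all[i])
      p <- reps[ri[i]]
      ev_rows[[length(ev_rows) + 1]] <- data.frame(
        person_id = st$person_id[p],
        time = minfo$day0 + di[i] - 1 + etime / 24,
        kind = "acute", subtype = HARM_TYPES[t],
        age = st$age[p], sex = c("male", "female")[st$sex[p]],
        category = CATEGORY_LEVELS[st$category[p] + 1L],
        context = site_names[site], stringsAsFactors = FALSE)
    }
  }

  # --- synthetic persons: independent draws at the representative's
  #     realised monthly intensity (not event copying), preserving count
  #     distributions
  lam_rep_comp <- rowsum(lam25, ri, reorder = FALSE)
  lam_map <- integer(nr)
  lam_map[as.integer(rownames(lam_rep_comp))] <- seq_len(nrow(lam_rep_comp))
  cells_by_rep <- split(seq_len(ne), ri)
  syn <- which(st$role == 2L & st$alive)
  if (length(syn)) {
    rep_pos <- match(st$rep_id[syn], st$person_id[reps])
    lrow <- integer(length(syn))
    okp <- !is.na(rep_pos)
    lrow[okp] <- lam_map[rep_pos[okp]]
    lam_syn <- numeric(length(syn))
    hasl <- lrow > 0L
    lam_syn[hasl] <- rowSums(lam_rep_comp)[lrow[hasl]]
    n_syn_ev <- rpois(length(syn), lam_syn)
    for (i in which(n_syn_ev > 0)) {
      comp_p <- lam_rep_comp[lrow[i], ]
      own_cells <- cells_by_rep[[as.character(rep_pos[i])]]
      for (e in seq_len(n_syn_ev[i])) {
        comp <- sample.int(25, 1, prob = comp_p)
        t <- ((comp - 1L) %/% 5L) + 1L
        site <- ((comp - 1L) %% 5L) + 1L
        phase <- c(1L, 1L, 1L, 2L, 3L)[site]
        # draw the timestamp from one of the representative's episodes,
        # weighted by that episode's intensity in the chosen component
        wc <- lam25[own_cells, comp]
        if (length(own_cells) > 1 && sum(wc) > 0) {
          j <- own_cells[sample.int(length(own_cells), 1, prob = wc)]
        } else j <- own_cells[1]
        etime <- event_time_in_phase(phase, ah$bac_slope[t], n_eff[j],
                                     cinc_e[j], pace[j], beta, b0[j],
                                     start_s[j], end_bac[j], tt_h_all[j])
        p <- syn[i]
        ev_rows[[length(ev_rows) + 1]] <- data.frame(
          person_id = st$person_id[p],
          time = minfo$day0 + di[j] - 1 + etime / 24,
          kind = "acute", subtype = HARM_TYPES[t],
          age = st$age[p], sex = c("male", "female")[st$sex[p]],
          category = CATEGORY_LEVELS[st$category[p] + 1L],
          context = site_names[site], stringsAsFactors = FALSE)
      }
    }
  }

  events <- if (length(ev_rows)) {
    ev <- as.data.frame(data.table::rbindlist(ev_rows))
    sev <- route_severity(ev$subtype, cfg$severity_routing)
    ev$ed <- sev$ed; ev$hospital <- sev$hospital; ev$death <- sev$death
    ev
  } else NULL

  # --- consumption accounting (standard drinks this year, representatives)
  st$ann_drinks <- st$ann_drinks +
    tabulate_sum(reps[ri], n_eff, length(st$person_id))
  list(state = st, events = events)
}

# sum `values` grouped by integer index `idx` into a vector of length n
tabulate_sum <- function(idx, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, idx, reorder = FALSE)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

nrow_venues <- function(cfg) {
  pr <- cfg$environment$precincts
  sum(pr$n_precincts * pr$venues_each)
}

ctx_pace_index <- function(ctx) c(1L, 2L, 3L)[ctx]  # home/venue/peer order

# Sample an event time (session hours) within a phase of an episode.
# Phase 1: drinking sawtooth - pick an inter-drink segment with probability
# proportional to its exp(k*bac) integral, then invert within the segment.
# Phase 2/3: exponential-decay inversion over transit / home tail.
event_time_in_phase <- function(phase, k, n, c_inc, dt, beta, b0,
                                start_s, end_bac, tt_h) {
  if (phase == 1L) {
    if (n <= 1) return(start_s + runif(1) * dt)
    i <- seq_len(n - 1)
    s <- b0 + beta * dt + i * (c_inc - beta * dt)
    seg <- sample.int(n - 1, 1, prob = exp(k * s))
    start_seg <- start_s + (seg - 1) * dt
    u <- runif(1)
    # invert integral of exp(k*(s_seg - beta t)) over [0, dt]
    A <- exp(k * s[seg]); Bv <- exp(k * (s[seg] - beta * dt))
    tt <- -log(A - u * (A - Bv)) / (k * beta) + log(A) / (k * beta)
    start_seg + min(max(tt, 0), dt)
  } else {
    bstart <- if (phase == 2L) end_bac else
      max(end_bac - beta * tt_h, 0)
    Tmax <- if (phase == 2L) tt_h else (bstart / beta)
    if (Tmax <= 0 || bstart <= 0) return(start_s + n * dt + runif(1) * 0.2)
    u <- runif(1)
    A <- exp(k * bstart); Bv <- exp(k * max(bstart - beta * Tmax, 0))
    tt <- (log(A) - log(A - u * (A - Bv))) / (k * beta)
    off <- if (phase == 2L) 0 else tt_h
    start_s + n * dt + off + min(max(tt, 0), Tmax)
  }
}

# ---- annual pass ----------------------------------------------------------

annual_pass <- function(st, eff_cfg, baseline_cfg, dm, seed) {
  set.seed(seed)
  bands <- baseline_cfg$population$category_bands
  b <- baseline_cfg$behaviour
  reps <- which(st$role == 1L)
  # trailing annual consumption in standard drinks/day
  ann <- st$ann_drinks[reps] / 365.25
  drinkers <- st$category[reps] > 0L
  new_cat <- st$category[reps]
  recat <- drinkers & !(st$enrolled[reps] & st$category[reps] == 2L)
  new_cat[recat] <- category_from_consumption(
    ann[recat], bands, drinks_at_all = drinkers[recat] & ann[recat] > 0)
  # habit drift: small symmetric category perturbation among drinkers;
  # drift INTO the heavy category (habit formation) is suppressed when
  # late-night venue entry is restricted
  drift <- drinkers & (runif(length(reps)) < b$habit_drift_prob)
  dirn <- ifelse(runif(length(reps)) < 0.5, -1L, 1L)
  restriction <- late_restriction_index(eff_cfg, baseline_cfg)
  supp <- (baseline_cfg$treatment$habit_env_coupling %||% 0) * restriction
  into_heavy <- drift & dirn == 1L & new_cat == 2L
  blocked_up <- into_heavy & (runif(length(reps)) < supp)
  drift <- drift & !blocked_up
  new_cat[drift] <- pmin(pmax(new_cat[drift] + dirn[drift], 1L), 3L)
  st$category[reps] <- new_cat

  # append history (representatives: own consumption)
  st <- append_history(st, reps, ann)

  # treatment step (only active when the effective config carries coverage)
  if (!is.null(eff_cfg$treatment$coverage) && eff_cfg$treatment$coverage > 0 ||
      any(st$enrolled)) {
    st <- treatment_step(st, eff_cfg, year = NA, seed = derive_seed(seed, 7),
                         baseline_cfg = baseline_cfg)
  }

  # synthetic persons mirror their representative's category and history
  syn <- which(st$role == 2L)
  if (length(syn)) {
    rp <- match(st$rep_id[syn], st$person_id)
    okm <- !is.na(rp)
    st$category[syn[okm]] <- st$category[rp[okm]]
    st$history[syn[okm], ] <- st$history[rp[okm], , drop = FALSE]
    st$hist_len[syn[okm]] <- st$hist_len[rp[okm]]
  }
  st$ann_drinks[] <- 0

  # chronic pass for the whole population
  ch <- chronic_annual_update(
    st, eff_cfg$chronic_model, seed = derive_seed(seed, 11),
    illness = list(active = st$ill_active, years_left = st$ill_years),
    age_band_lower = baseline_cfg$population$age_band_lower,
    bands = bands)
  st$ill_active <- ch$illness$active
  st$ill_years <- ch$illness$years_left
  ev <- ch$events
  events <- if (nrow(ev)) data.frame(
    person_id = st$person_id[ev$idx],
    time = NA_real_, kind = ev$kind, subtype = ev$subtype,
    age = st$age[ev$idx], sex = c("male", "female")[st$sex[ev$idx]],
    category = CATEGORY_LEVELS[st$category[ev$idx] + 1L],
    context = NA_character_, ed = ev$ed, hospital = ev$hospital,
    death = ev$death, stringsAsFactors = FALSE)
  else data.frame(person_id = integer(0), time = numeric(0),
                  kind = character(0), subtype = character(0),
                  age = numeric(0), sex = character(0),
                  category = character(0), context = character(0),
                  ed = logical(0), hospital = logical(0), death = logical(0))
  list(state = st, events = events, deaths = ch$deaths)
}

# append one annual consumption value per person in `idx` to the history
# ring buffer (capacity = ncol, shift once full)
append_history <- function(st, idx, values) {
  H <- ncol(st$history)
  full <- st$hist_len[idx] >= H
  if (any(full)) {
    rows <- idx[full]
    st$history[rows, -H] <- st$history[rows, -1, drop = FALSE]
    st$history[cbind(rows, H)] <- values[full]
  }
  if (any(!full)) {
    rows <- idx[!full]
    st$history[cbind(rows, st$hist_len[rows] + 1L)] <- values[!full]
    st$hist_len[rows] <- st$hist_len[rows] + 1L
  }
  st
}

#' @export
print.alco_run <- function(x, ...) {
  cat("<alco_run>", length(x$replicates), "replicate(s),",
      x$manifest$n_agents, "agents, scenario:", x$manifest$scenario, "\n")
  nev <- vapply(x$replicates, function(r) nrow(r$event_log), numeric(1))
  cat("  events per replicate:", paste(nev, collapse = ", "), "\n")
  invisible(x)
}

#' Write a run's event logs and manifest to a directory
#'
#' @param run An `alco_run`.
#' @param dir Output directory (created if needed).
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(run$replicates)) {
    write.csv(run$replicates[[i]]$event_log,
              file.path(dir, sprintf("events_rep%02d.csv", i)),
              row.names = FALSE)
    write.csv(run$replicates[[i]]$pop_series,
              file.path(dir, sprintf("population_rep%02d.csv", i)),
              row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
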