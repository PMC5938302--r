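# Harm generation. Acute harms arise from a non-homogeneous Poisson process
# whose intensity is a context/sex/age-specific base hazard times an
# exponential function of the momentary BAC; chronic disease onsets follow
# attributable-fraction epidemiology on the 20-year moving average of
# consumption. Every harm is routed to emergency-department presentation,
# hospitalisation and/or death (parallel, independent flags).

#' Attributable fraction from a relative risk
#'
#' `AF = (RR - 1) / RR`. Wholly attributable conditions (alcoholic liver
#' cirrhosis, alcohol use disorder) use the infinite-RR sentinel and return
#' exactly 1. Protective exposures (`rr < 1`) are out of scope.
#'
#' @param rr Relative risk(s), `>= 1` or `Inf`.
#' @return Attributable fraction(s) in \[0, 1\].
#' @export
#' @examples
#' attributable_fraction(2)    # 0.5
#' attributable_fraction(Inf)  # 1 (wholly attributable)
attributable_fraction <- function(rr) {
  if (any(rr < 1)) stop("relative risk below 1 is out of scope")
  ifelse(is.infinite(rr), 1, (rr - 1) / rr)
}

#' Momentary acute-harm hazard
#'
#' Hazard per harm type in events/hour for a person at a given BAC and
#' context: `scale * base * sex_mult * age_mult * context_mult * exp(k * bac)`.
#' Road traffic accidents are gated to the transit context; exacerbations of
#' alcohol use disorder are restricted to heavy-category agents (or agents
#' with an active chronic condition).
#'
#' @param person A list with `sex` (`"male"`/`"female"` or 1/2), `age`, and
#'   `category` (integer code or label).
#' @param bac BAC in g/100mL (>= 0).
#' @param context One of `"home"`, `"venue"`, `"peer_event"`, `"transit"`.
#' @param table The `acute_hazards` section of the configuration.
#' @param age_band_lower Age band lower bounds (defaults to the packaged
#'   bands).
#' @param has_chronic Logical; an active chronic condition also enables the
#'   exacerbation pathway.
#' @return Named numeric vector of hazards (events/hour) per harm type.
#' @export
acute_hazard <- function(person, bac, context, table,
                         age_band_lower = c(18, 25, 35, 45, 55, 65, 75),
                         has_chronic = FALSE) {
  stopifnot(bac >= 0, context %in% CONTEXT_LEVELS)
  sex <- if (is.character(person$sex))
    match(person$sex, c("male", "female")) else person$sex
  cat_code <- if (is.character(person$category))
    match(person$category, CATEGORY_LEVELS) - 1L else person$category
  band <- age_band(person$age, age_band_lower)
  h <- table$scale * table$base *
    table$sex_mult[, sex] *
    table$age_mult[band] *
    table$context_mult[, context] *
    exp(table$bac_slope * bac)
  if (isTRUE(table$exacerbation_heavy_only) && cat_code != 3L && !has_chronic)
    h[["chronic_exacerbation"]] <- 0
  h
}

#' Sample acute harm events along an episode's BAC trajectory
#'
#' Draws events from a non-homogeneous Poisson process by thinning: candidate
#' times are generated at the trajectory's maximum total hazard and accepted
#' with probability `lambda(t) / lambda_max`; each accepted event is assigned
#' a harm type proportional to the type-specific hazards at its time and
#' routed to severity flags.
#'
#' @param person As in [acute_hazard()]; additionally `person_id` if present
#'   is carried into the result.
#' @param trajectory A list describing the episode: `drink_times` (hours),
#'   `grams` per drink, `body` ([body_params()]), `start`, `end` (hours) and
#'   `context`.
#' @param table Acute hazard table (config section).
#' @param routing Severity routing (config section).
#' @param seed Integer seed.
#' @return A data.frame of harm events (possibly empty) with columns
#'   `time`, `subtype`, `ed`, `hospital`, `death`, `context`.
#' @export
sample_acute_events <- function(person, trajectory, table, routing, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  tr <- trajectory
  total_hazard <- function(tt) {
    bacs <- bac_trajectory(tr$drink_times, tr$grams, tr$body, tt)
    vapply(bacs, function(b)
      sum(acute_hazard(person, b, tr$context, table)), numeric(1))
  }
  # maximum BAC occurs at a drink instant (or at start); bound the intensity
  peak_times <- unique(c(tr$start, tr$drink_times[tr$drink_times <= tr$end]))
  lambda_max <- max(total_hazard(peak_times), 0)
  dur <- tr$end - tr$start
  if (lambda_max <= 0 || dur <= 0)
    return(empty_harm_frame())
  n_cand <- rpois(1, lambda_max * dur)
  if (n_cand == 0) return(empty_harm_frame())
  cand <- sort(runif(n_cand, tr$start, tr$end))
  lam <- total_hazard(cand)
  keep <- runif(n_cand) < lam / lambda_max
  cand <- cand[keep]
  if (!length(cand)) return(empty_harm_frame())
  subtype <- vapply(cand, function(tt) {
    b <- bac_trajectory(tr$drink_times, tr$grams, tr$body, tt)
    h <- acute_hazard(person, b, tr$context, table)
    sample(names(h), 1, prob = h / sum(h))
  }, character(1))
  sev <- route_severity(subtype, routing)
  data.frame(time = cand, subtype = subtype,
             ed = sev$ed, hospital = sev$hospital, death = sev$death,
             context = tr$context, stringsAsFactors = FALSE)
}

empty_harm_frame <- function() {
  data.frame(time = numeric(0), subtype = character(0), ed = logical(0),
             hospital = logical(0), death = logical(0),
             context = character(0), stringsAsFactors = FALSE)
}

# Severity routing: independent Bernoulli flags per event (ED and hospital
# are parallel pathways and may co-occur).
route_severity <- function(subtype, routing) {
  p_ed <- pmin(1, routing$ed[subtype] * (routing$ed_scale %||% 1))
  p_hosp <- pmin(1, routing$hospital[subtype] * (routing$hosp_scale %||% 1))
  p_death <- routing$death[subtype]
  n <- length(subtype)
  list(ed = runif(n) < p_ed, hospital = runif(n) < p_hosp,
       death = runif(n) < p_death)
}

#' Twenty-year moving average of consumption
#'
#' Arithmetic mean of up to the last 20 annual consumption averages
#' (standard drinks/day). Histories shorter than 20 years are averaged over
#' the available years rather than zero-padded, so young drinkers' exposure
#' is not understated.
#'
#' @param consumption_history Numeric vector of annual averages, oldest
#'   first; must be non-empty.
#' @return Mean standard drinks/day.
#' @export
#' @examples
#' twenty_year_mean(c(rep(0, 10), rep(8, 10)))  # 4
twenty_year_mean <- function(consumption_history) {
  if (!length(consumption_history)) stop("consumption history is empty")
  mean(tail(consumption_history, 20))
}

#' Annual chronic-disease update
#'
#' Performs the once-a-year chronic pass for a population: for each person
#' and condition not already active, samples onset with probability
#' `baseline_incidence(age) * RR(category) * AF(RR)` (only the
#' alcohol-attributable share of incidence is modelled); for wholly
#' attributable conditions the category columns act as incidence weights
#' with AF = 1. The female-breast-cancer pathway applies to female agents
#' only. Ongoing conditions emit ED/hospitalisation events at their annual
#' probabilities, may be fatal at the annual case fatality, and resolve when
#' their duration elapses. The drinking category used is derived from the
#' 20-year moving average in each person's consumption history.
#'
#' @param population An `alco_population`.
#' @param chronic_model The `chronic_model` config section.
#' @param seed Integer seed.
#' @param illness Optional illness state from a previous call (list with
#'   `active` and `years_left` matrices); created if missing.
#' @param age_band_lower Age band lower bounds.
#' @param bands Category band cut points for the 20-year mean.
#' @param year Simulation year label recorded on events.
#' @return A list with `events` (data.frame: person index, kind, subtype,
#'   ed/hospital/death flags), `illness` (updated state) and `deaths`
#'   (indices of persons dying of chronic disease this year).
#' @export
chronic_annual_update <- function(population, chronic_model, seed,
                                  illness = NULL,
                                  age_band_lower = c(18, 25, 35, 45, 55, 65, 75),
                                  bands = list(low_upper = 2.5,
                                               moderate_upper = 6.5),
                                  year = NA) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  pop <- population
  cm <- chronic_model$conditions
  n <- length(pop$person_id)
  C <- nrow(cm)
  if (is.null(illness))
    illness <- list(active = matrix(FALSE, n, C),
                    years_left = matrix(0, n, C))
  # illness matrices must track population size (rows are persons)
  stopifnot(nrow(illness$active) == n)

  # exposure category from the 20-year moving window of consumption;
  # history rows are zero beyond the filled prefix, so the row sum divided
  # by the filled length is the window mean
  win_mean <- rowSums(pop$history) / pmax(pop$hist_len, 1L)
  expo_cat <- category_from_consumption(win_mean, bands,
                                        drinks_at_all = win_mean > 0)
  band <- age_band(pmin(pop$age, 100), age_band_lower)

  ev <- list()
  deaths <- integer(0)
  for (j in seq_len(C)) {
    inc <- chronic_model$scale * cm$incidence_per100k[[j]][band] / 1e5
    rr <- cbind(1, cm$rr_low[j], cm$rr_moderate[j], cm$rr_heavy[j])[1, expo_cat + 1L]
    if (cm$wholly_attributable[j]) {
      # category columns are incidence weights; abstainers are unexposed
      p_onset <- inc * ifelse(expo_cat == 0L, 0, rr)
    } else {
      p_onset <- inc * rr * attributable_fraction(pmax(rr, 1))
    }
    p_onset[illness$active[, j]] <- 0
    if (cm$female_only[j]) p_onset[pop$sex == 1L] <- 0
    onset <- runif(n) < p_onset
    if (any(onset)) {
      illness$active[onset, j] <- TRUE
      illness$years_left[onset, j] <- cm$duration_years[j]
      idx <- which(onset)
      ev[[length(ev) + 1]] <- data.frame(
        idx = idx, kind = "chronic_onset", subtype = cm$condition[j],
        ed = FALSE, hospital = FALSE, death = FALSE)
    }
    act <- which(illness$active[, j])
    if (length(act)) {
      ed <- runif(length(act)) < cm$ed_annual[j]
      hosp <- runif(length(act)) < cm$hosp_annual[j]
      die <- runif(length(act)) < cm$case_fatality_annual[j]
      emit <- ed | hosp | die
      if (any(emit))
        ev[[length(ev) + 1]] <- data.frame(
          idx = act[emit], kind = "chronic_annual",
          subtype = cm$condition[j],
          ed = ed[emit], hospital = hosp[emit], death = die[emit])
      deaths <- union(deaths, act[die])
      illness$years_left[act, j] <- illness$years_left[act, j] - 1
      recovered <- act[illness$years_left[act, j] <= 0]
      illness$active[recovered, j] <- FALSE
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(idx = integer(0), kind = character(0), subtype = character(0),
               ed = logical(0), hospital = logical(0), death = logical(0))
  list(events = events, illness = illness, deaths = deaths)
}

# ---- closed-form episode intensity integrals (vectorised) -----------------
#
# For an episode of n equal drinks (BAC increment c_inc each) at spacing dt
# hours with linear elimination beta and starting BAC b0, the post-drink
# peaks are s_i = b0 + beta*dt + i*(c_inc - beta*dt). The integral of
# exp(k * bac(t)) over the drinking phase plus an optional decay tail has a
# closed geometric form; the engine uses it so per-episode cost is O(1).

# integral of exp(k * (b0 - beta t)) dt from 0 to min(t_max, b0/beta),
# clamping at the zero floor. Vectorised over b0/t_max.
exp_decay_integral <- function(k, b0, beta, t_max) {
  t_eff <- pmin(t_max, b0 / beta)
  t_eff <- pmax(t_eff, 0)
  out <- (exp(k * b0) - exp(k * (b0 - beta * t_eff))) / (k * beta)
  # remaining time at zero BAC contributes multiplier exp(0) = 1
  out + pmax(t_max - t_eff, 0)
}

# Sum over i = 1..m of exp(k * s_i) with s_i = base + i * step (geometric).
geom_exp_sum <- function(k, base, step, m) {
  m <- pmax(m, 0)
  d <- expm1(k * step)                  # q - 1; near-zero replaced so the
  d[abs(d) < 1e-12] <- 1e-12            # ratio degrades gracefully to m
  q <- 1 + d
  exp(k * base) * q * (q^m - 1) / d
}

# Vectorised over episodes: integral of exp(k*bac) during the drinking phase
# (n drinks, spacing dt, increment c_inc, start BAC b0), i.e. n-1 inter-drink
# segments, plus end-of-episode BAC. Returns list(integral, end_bac).
sawtooth_integral <- function(k, n, c_inc, dt, beta, b0) {
  step <- c_inc - beta * dt
  base <- b0 + beta * dt
  m <- pmax(n - 1, 0)
  # sum over peaks s_1..s_{n-1} of per-segment integral
  seg_factor <- (1 - exp(-k * beta * dt)) / (k * beta)
  integral <- geom_exp_sum(k, base, step, m) * seg_factor
  end_bac <- pmax(b0 + n * c_inc - m * beta * dt, 0)   # peak after last drink
  list(integral = integral * (n > 0), end_bac = end_bac)
}
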