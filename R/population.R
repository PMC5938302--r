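# Synthetic agent population: demographics, weight, drinking category, the
# representative/synthetic split, ageing, legal-age entrants and background
# (non-alcohol) mortality.
#
# The population is stored column-wise (a list of parallel vectors) for
# speed; `as.data.frame()` gives the familiar rectangular view. Categories
# are integer-coded (0 abstainer, 1 low, 2 moderate, 3 heavy), sex is
# 1 = male, 2 = female, role is 1 = representative, 2 = synthetic.

#' Demographic model
#'
#' Bundles the joint age-band/sex distribution, sex-specific truncated-normal
#' weight distribution, drinking-category prevalence per age band,
#' Gompertz-Makeham background mortality and the legal-age entry rate, and
#' validates their invariants (tables normalise to 1; mortality hazard
#' non-decreasing above age 30).
#'
#' @param pop_config The `population` section of a model configuration
#'   (see [default_config()]).
#' @return A list of class `alco_demography`.
#' @export
demographic_model <- function(pop_config) {
  p <- pop_config
  if (abs(sum(p$age_band_probs) - 1) > 1e-9)
    stop("age band probabilities must sum to 1")
  if (any(abs(rowSums(p$category_prevalence) - 1) > 1e-9))
    stop("category prevalence rows must sum to 1")
  ages <- seq(30, p$max_age)
  haz <- mortality_hazard(ages, p$background_mortality)
  if (any(diff(haz) < 0))
    stop("background mortality must be non-decreasing above age 30")
  structure(p, class = "alco_demography")
}

mortality_hazard <- function(age, bm) {
  bm$makeham_a + bm$gompertz_b * exp(bm$gompertz_g * age)
}

#' Age band index for an age
#'
#' @param age Numeric ages.
#' @param band_lower Lower bounds of the age bands.
#' @return Integer band indices.
#' @export
age_band <- function(age, band_lower) {
  findInterval(age, band_lower)
}

#' Drinking category from average consumption
#'
#' Maps an average daily consumption (standard drinks/day) to the integer
#' category code using half-open bands: `[0, low_upper)` low,
#' `[low_upper, moderate_upper)` moderate, `[moderate_upper, Inf)` heavy.
#' Zero consumption with no drinking episodes is the abstainer state.
#'
#' @param x Standard drinks per day (non-negative).
#' @param bands List with `low_upper` and `moderate_upper` cut points.
#' @param drinks_at_all Logical; `FALSE` marks a non-drinker (abstainer).
#' @return Integer category codes (0 abstainer, 1 low, 2 moderate, 3 heavy).
#' @export
category_from_consumption <- function(x, bands, drinks_at_all = x > 0) {
  if (any(x < 0)) stop("consumption must be non-negative")
  out <- ifelse(!drinks_at_all & x == 0, 0L,
         ifelse(x < bands$low_upper, 1L,
         ifelse(x < bands$moderate_upper, 2L, 3L)))
  as.integer(out)
}

# stratum index from (age band, sex, category); bands frozen at assignment
stratum_index <- function(band, sex, category, n_band) {
  as.integer((band - 1L) * 8L + (sex - 1L) * 4L + category + 1L)
}

#' Initialise the agent population
#'
#' Synthesises `n_agents` adults from a demographic model: ages and sexes
#' from the joint distribution, weights from sex-specific truncated normals,
#' drinking category from the per-band prevalence, and a consumption history
#' consistent with the category. A fraction `representative_fraction` of
#' agents is flagged as representatives (modelled in behavioural detail);
#' every synthetic person is linked to a representative matched on
#' (age band, sex, category) at assignment. Strata without a representative
#' have one synthetic member promoted (counted in
#' `attr(pop, "promotions")`).
#'
#' @param demographic_model An [demographic_model()].
#' @param n_agents Number of agents (>= 100).
#' @param representative_fraction Fraction in (0, 1] modelled in detail.
#' @param seed Integer seed.
#' @return A list of class `alco_population`.
#' @export
#' @examples
#' dm <- demographic_model(default_config()$population)
#' pop <- init_population(dm, 1000, 0.1, seed = 1)
#' table(category_labels(pop$category))
init_population <- function(demographic_model, n_agents,
                            representative_fraction, seed) {
  stopifnot(n_agents >= 100,
            representative_fraction > 0, representative_fraction <= 1)
  dm <- demographic_model
  set.seed(as.integer(seed %% .Machine$integer.max))
  nb <- length(dm$age_band_lower)
  band <- sample.int(nb, n_agents, replace = TRUE, prob = dm$age_band_probs)
  upper <- c(dm$age_band_lower[-1], min(92, dm$max_age))
  age <- dm$age_band_lower[band] +
    runif(n_agents) * (upper[band] - dm$age_band_lower[band])
  sex <- ifelse(runif(n_agents) < dm$male_fraction, 1L, 2L)
  weight <- sample_weight(sex, dm$weight)
  category <- sample_category(band, dm$category_prevalence)

  n_rep <- round(n_agents * representative_fraction)
  role <- rep(2L, n_agents)
  role[sample.int(n_agents, n_rep)] <- 1L

  stratum <- stratum_index(band, sex, category, nb)
  rep_id <- seq_len(n_agents)                     # self for representatives
  promotions <- 0L
  syn <- which(role == 2L)
  if (length(syn)) {
    # match each synthetic person to a representative in its stratum
    reps_by_stratum <- split(which(role == 1L), stratum[role == 1L])
    for (s in unique(stratum[syn])) {
      members <- syn[stratum[syn] == s]
      cands <- reps_by_stratum[[as.character(s)]]
      if (is.null(cands) || !length(cands)) {
        # empty stratum: promote one synthetic member to representative
        role[members[1]] <- 1L
        promotions <- promotions + 1L
        cands <- members[1]
        members <- members[-1]
      }
      if (length(members))
        rep_id[members] <- cands[sample.int(length(cands), length(members),
                                            replace = TRUE)]
    }
  }

  hist <- init_history(age, category, dm)
  pop <- list(
    person_id = seq_len(n_agents),
    age = age, sex = sex, weight = weight, category = category,
    role = role, rep_id = rep_id, stratum = stratum,
    alive = rep(TRUE, n_agents),
    home_id = seq_len(n_agents),
    workplace_id = rep(NA_integer_, n_agents),
    enrolled = rep(FALSE, n_agents),
    history = hist$values, hist_len = hist$len,
    next_id = n_agents + 1L
  )
  attr(pop, "representative_fraction") <- representative_fraction
  attr(pop, "promotions") <- promotions
  class(pop) <- c("alco_population", "list")
  pop
}

sample_weight <- function(sex, w) {
  mu <- ifelse(sex == 1L, w$male_mean, w$female_mean)
  sdv <- ifelse(sex == 1L, w$male_sd, w$female_sd)
  lo <- pnorm(w$min, mu, sdv); hi <- pnorm(w$max, mu, sdv)
  qnorm(lo + runif(length(sex)) * (hi - lo), mu, sdv)
}

sample_category <- function(band, prevalence) {
  u <- runif(length(band))
  cum <- t(apply(prevalence, 1, cumsum))
  cat <- integer(length(band))
  for (b in seq_len(nrow(prevalence))) {
    i <- band == b
    cat[i] <- findInterval(u[i], cum[b, ], left.open = TRUE)
  }
  as.integer(cat)                                  # 0..3
}

# category-typical intake used to seed consumption histories
category_typical_intake <- function(category, bands) {
  c(0, bands$low_upper / 2,
    (bands$low_upper + bands$moderate_upper) / 2,
    bands$moderate_upper + 2)[category + 1L]
}

init_history <- function(age, category, dm) {
  n <- length(age)
  H <- dm$history_years
  len <- pmax(1L, pmin(H, as.integer(floor(age)) - (dm$legal_age - 1L) - 1L))
  values <- matrix(0, n, H)
  typical <- category_typical_intake(category, dm$category_bands)
  for (i in seq_len(n)) {
    if (typical[i] > 0) {
      v <- typical[i] * exp(rnorm(len[i], 0, 0.10))
      # keep seeded history inside the category band
      v <- pmin(pmax(v, band_floor(category[i], dm$category_bands)),
                band_ceiling(category[i], dm$category_bands))
      values[i, seq_len(len[i])] <- v
    }
  }
  list(values = values, len = len)
}

band_floor <- function(cat, bands)
  c(0, 0, bands$low_upper, bands$moderate_upper)[cat + 1L]
band_ceiling <- function(cat, bands)
  c(0, bands$low_upper - 1e-6, bands$moderate_upper - 1e-6, Inf)[cat + 1L]

#' Advance demography
#'
#' Ages the population by `dt` years, samples background (non-alcohol)
#' deaths from the Gompertz-Makeham hazard, removes the dead (reassigning
#' synthetic persons whose representative died), and adds new legal-age
#' entrants at the configured entry rate. With the default configuration and
#' no migration the net population change is a slow decline.
#'
#' @param population An `alco_population`.
#' @param demographic_model An [demographic_model()].
#' @param dt Time step in years (> 0).
#' @param seed Integer seed.
#' @return The updated population; deaths and entrant counts are recorded in
#'   `attr(pop, "last_step")`.
#' @export
advance_demography <- function(population, demographic_model, dt, seed) {
  stopifnot(dt > 0)
  set.seed(as.integer(seed %% .Machine$integer.max))
  pop <- population
  dm <- demographic_model
  pop$age <- pop$age + dt
  haz <- mortality_hazard(pop$age, dm$background_mortality)
  p_die <- 1 - exp(-haz * dt)
  p_die[pop$age >= dm$max_age] <- 1
  dead <- runif(length(pop$age)) < p_die
  n_dead <- sum(dead)
  pop <- remove_persons(pop, which(dead))

  expected <- dm$entry_rate_per100k / 1e5 * length(pop$age) * dt
  n_new <- rpois(1, expected)
  if (n_new > 0) pop <- add_entrants(pop, dm, n_new)
  attr(pop, "last_step") <- list(deaths = n_dead, entrants = n_new)
  pop
}

# Remove persons (death); synthetic persons whose representative died are
# reassigned within their stratum, promoting one if the stratum empties.
# Subsetting is generic: every person-length vector and every matrix with a
# person row dimension is filtered, so engine-side extensions of the state
# (illness matrices, accumulators) stay aligned.
remove_persons <- function(pop, idx) {
  if (!length(idx)) return(pop)
  n <- length(pop$person_id)
  dead_ids <- pop$person_id[idx]
  keep <- setdiff(seq_len(n), idx)
  for (f in names(pop)) {
    x <- pop[[f]]
    if (is.matrix(x) && nrow(x) == n) pop[[f]] <- x[keep, , drop = FALSE]
    else if (is.atomic(x) && !is.matrix(x) && length(x) == n)
      pop[[f]] <- x[keep]
  }
  orphan <- pop$role == 2L & pop$rep_id %in% dead_ids
  if (any(orphan)) {
    for (s in unique(pop$stratum[orphan])) {
      members <- which(orphan & pop$stratum == s)
      cands <- which(pop$role == 1L & pop$stratum == s)
      if (!length(cands)) {
        pop$role[members[1]] <- 1L
        pop$rep_id[members[1]] <- pop$person_id[members[1]]
        attr(pop, "promotions") <-
          (attr(pop, "promotions") %||% 0L) + 1L
        cands <- members[1]
        members <- members[-1]
      }
      if (length(members))
        pop$rep_id[members] <-
          pop$person_id[cands[sample.int(length(cands), length(members),
                                         replace = TRUE)]]
    }
  }
  pop
}

add_entrants <- function(pop, dm, n_new) {
  ids <- pop$next_id + seq_len(n_new) - 1L
  pop$next_id <- pop$next_id + n_new
  sex <- ifelse(runif(n_new) < dm$male_fraction, 1L, 2L)
  weight <- sample_weight(sex, dm$weight)
  category <- sample_category(rep(1L, n_new), dm$category_prevalence)
  band <- rep(1L, n_new)
  stratum <- stratum_index(band, sex, category, length(dm$age_band_lower))
  rf <- attr(pop, "representative_fraction") %||% 1
  role <- ifelse(runif(n_new) < rf, 1L, 2L)
  rep_id <- ids
  for (i in which(role == 2L)) {
    cands <- which(pop$role == 1L & pop$stratum == stratum[i])
    if (length(cands)) {
      rep_id[i] <- pop$person_id[cands[sample.int(length(cands), 1)]]
    } else {
      role[i] <- 1L
      attr(pop, "promotions") <- (attr(pop, "promotions") %||% 0L) + 1L
    }
  }
  H <- ncol(pop$history)
  hist_new <- matrix(0, n_new, H)
  typical <- category_typical_intake(category, dm$category_bands)
  hist_new[, 1] <- typical
  n_old <- length(pop$person_id)
  known <- list(person_id = ids, age = rep(dm$legal_age, n_new), sex = sex,
                weight = weight, category = category, role = role,
                rep_id = rep_id, stratum = stratum,
                alive = rep(TRUE, n_new), home_id = ids,
                workplace_id = rep(NA_integer_, n_new),
                enrolled = rep(FALSE, n_new), hist_len = rep(1L, n_new))
  for (f in names(pop)) {
    x <- pop[[f]]
    if (f == "history") {
      pop[[f]] <- rbind(x, hist_new)
    } else if (!is.null(known[[f]])) {
      pop[[f]] <- c(x, known[[f]])
    } else if (is.matrix(x) && nrow(x) == n_old) {
      pop[[f]] <- rbind(x, matrix(vector(mode(x), 1), n_new, ncol(x)))
    } else if (is.atomic(x) && !is.matrix(x) && length(x) == n_old) {
      # engine-side per-person extension fields: pad with NA, the engine
      # fills entrant-specific values afterwards
      pop[[f]] <- c(x, rep(x[NA_integer_], n_new))
    }
  }
  pop
}

#' Update a person's drinking category from trailing consumption
#'
#' Appends the trailing annual average to the person's consumption history
#' (a ring buffer of up to 20 annual entries) and re-derives the category
#' from the band thresholds.
#'
#' @param person A list with at least `category`, `consumption_history`
#'   (numeric vector) fields, e.g. from [get_person()].
#' @param trailing_annual_consumption Average standard drinks/day over the
#'   trailing year (non-negative).
#' @param bands Category band cut points (see
#'   [default_config()]`$population$category_bands`).
#' @param had_episodes Logical; whether the person drank at all this year.
#' @return The updated person.
#' @export
update_drinking_category <- function(person, trailing_annual_consumption,
                                     bands = list(low_upper = 2.5,
                                                  moderate_upper = 6.5),
                                     had_episodes =
                                       trailing_annual_consumption > 0) {
  if (trailing_annual_consumption < 0) stop("consumption must be non-negative")
  h <- c(person$consumption_history, trailing_annual_consumption)
  if (length(h) > 20) h <- tail(h, 20)
  person$consumption_history <- h
  person$category <- category_from_consumption(trailing_annual_consumption,
                                               bands, had_episodes)
  person
}

#' Extract one person from a population
#'
#' @param population An `alco_population`.
#' @param i Row index.
#' @return A list view of that agent (class `alco_person`).
#' @export
get_person <- function(population, i) {
  p <- list(
    person_id = population$person_id[i], age = population$age[i],
    sex = c("male", "female")[population$sex[i]],
    weight = population$weight[i],
    category = population$category[i], role =
      c("representative", "synthetic")[population$role[i]],
    representative_id = population$rep_id[i],
    alive = population$alive[i],
    consumption_history =
      population$history[i, seq_len(population$hist_len[i])]
  )
  class(p) <- c("alco_person", "list")
  p
}

#' @export
category_labels <- function(code) factor(CATEGORY_LEVELS[code + 1L],
                                         levels = CATEGORY_LEVELS)

#' @export
as.data.frame.alco_population <- function(x, ...) {
  data.frame(person_id = x$person_id, age = x$age,
             sex = c("male", "female")[x$sex], weight_kg = x$weight,
             category = as.character(category_labels(x$category)),
             role = c("representative", "synthetic")[x$role],
             representative_id = x$rep_id, stringsAsFactors = FALSE)
}

#' Population snapshot IO
#'
#' Writes/reads the population snapshot CSV with columns
#' `person_id, age, sex, weight_kg, category, role, representative_id`.
#'
#' @param population An `alco_population`.
#' @param path CSV path.
#' @return `read_population_snapshot` returns a data.frame.
#' @export
write_population_snapshot <- function(population, path) {
  write.csv(as.data.frame(population), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_snapshot
#' @export
read_population_snapshot <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.alco_population <- function(x, ...) {
  cat("<alco_population>", length(x$person_id), "agents (",
      sum(x$role == 1L), "representative /", sum(x$role == 2L),
      "synthetic )\n")
  print(table(category_labels(x$category)))
  invisible(x)
}
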