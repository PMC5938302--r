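# Harm generation: attributable fractions, acute hazards, the
# non-homogeneous Poisson sampler, the 20-year consumption window and the
# chronic disease pass.

test_that("attributable fraction follows (RR-1)/RR with the sentinel", {
  expect_equal(attributable_fraction(1), 0)
  expect_equal(attributable_fraction(2), 0.5)
  expect_equal(attributable_fraction(4), 0.75)
  expect_equal(attributable_fraction(Inf), 1)      # wholly attributable
  expect_error(attributable_fraction(0.8), "out of scope")
  expect_equal(attributable_fraction(c(1, 3, Inf)), c(0, 2 / 3, 1))
})

test_that("acute hazards honour context, sex, age and BAC monotonicity", {
  tab <- default_config()$acute_hazards
  male <- list(sex = "male", age = 20, category = 3L)
  female <- list(sex = "female", age = 20, category = 3L)
  old <- list(sex = "male", age = 70, category = 3L)
  # road traffic accidents are gated to transit
  for (ctx in c("home", "venue", "peer_event"))
    expect_equal(acute_hazard(male, 0.1, ctx, tab)[["road_traffic_accident"]],
                 0)
  expect_gt(acute_hazard(male, 0.1, "transit",
                         tab)[["road_traffic_accident"]], 0)
  # multiplier is non-decreasing in BAC across all strata
  for (p in list(male, female, old)) for (ctx in c("home", "venue")) {
    h1 <- acute_hazard(p, 0.05, ctx, tab)
    h2 <- acute_hazard(p, 0.15, ctx, tab)
    expect_true(all(h2 >= h1))
  }
  # males more violence-prone than females at equal covariates
  expect_gt(acute_hazard(male, 0.1, "venue", tab)[["violence_assault"]],
            acute_hazard(female, 0.1, "venue", tab)[["violence_assault"]])
  # young adults exceed older adults in total acute hazard
  expect_gt(sum(acute_hazard(male, 0.1, "venue", tab)),
            sum(acute_hazard(old, 0.1, "venue", tab)))
  # exacerbation pathway is restricted to heavy drinkers
  lowp <- list(sex = "male", age = 20, category = 1L)
  expect_equal(acute_hazard(lowp, 0.1, "home",
                            tab)[["chronic_exacerbation"]], 0)
})

test_that("the NHPP sampler matches a homogeneous Poisson oracle", {
  cfg <- default_config()
  tab <- cfg$acute_hazards
  # constant hazard: flat multiplier (slope 0), one active type
  tab$bac_slope[] <- 0
  tab$base[] <- 0
  tab$base[["unintentional_injury"]] <- 1
  tab$sex_mult[, ] <- 1
  tab$age_mult[] <- 1
  tab$context_mult[, ] <- 1
  tab$scale <- 0.05
  routing <- cfg$severity_routing
  person <- list(sex = "male", age = 30, category = 2L)
  body <- body_params(80, "male")
  tr <- list(drink_times = c(0, 1, 2), grams = 10, body = body,
             start = 0, end = 10, context = "home")
  counts <- vapply(1:400, function(s)
    nrow(sample_acute_events(person, tr, tab, routing, seed = s)),
    numeric(1))
  lambda <- 0.05 * 1 * 10                      # scale * base * duration
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 400))
  # zero hazard table -> no events
  tab0 <- tab; tab0$scale <- 0
  expect_equal(nrow(sample_acute_events(person, tr, tab0, routing,
                                        seed = 1)), 0)
})

test_that("severity routing flags follow their probabilities", {
  cfg <- default_config()
  routing <- cfg$severity_routing
  routing$ed[] <- 1; routing$hospital[] <- 0; routing$death[] <- 0
  routing$ed_scale <- 1; routing$hosp_scale <- 1
  tab <- cfg$acute_hazards
  tab$bac_slope[] <- 0; tab$scale <- 0.2
  tab$context_mult[, ] <- 1; tab$sex_mult[, ] <- 1; tab$age_mult[] <- 1
  person <- list(sex = "female", age = 25, category = 3L)
  tr <- list(drink_times = 0, grams = 10, body = body_params(60, "female"),
             start = 0, end = 8, context = "home")
  ev <- do.call(rbind, lapply(1:50, function(s)
    sample_acute_events(person, tr, tab, routing, seed = s)))
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$ed))
  expect_false(any(ev$hospital))
  expect_false(any(ev$death))
})

test_that("twenty-year window averages correctly", {
  expect_equal(twenty_year_mean(rep(4, 25)), 4)
  expect_equal(twenty_year_mean(c(rep(0, 10), rep(8, 10))), 4)
  expect_equal(twenty_year_mean(rep(6, 5)), 6)    # short-history rule
  expect_equal(twenty_year_mean(c(rep(9, 10), rep(0, 10), rep(8, 10))), 4)
  expect_error(twenty_year_mean(numeric(0)), "empty")
})

# build a single-condition chronic model for oracle checks
one_condition_model <- function(inc_per100k, rr_heavy = 3,
                                wholly = FALSE, female_only = FALSE,
                                duration = 5) {
  d <- chronic_condition_table()[9, ]
  d$condition <- "test_condition"
  d$female_only <- female_only
  d$wholly_attributable <- wholly
  d$rr_low <- if (wholly) 0.0 else 1
  d$rr_moderate <- if (wholly) 0.0 else 1
  d$rr_heavy <- rr_heavy
  d$duration_years <- duration
  d$ed_annual <- 0; d$hosp_annual <- 0; d$case_fatality_annual <- 0
  d$incidence_per100k <- I(list(rep(inc_per100k, 7)))
  list(scale = 1, conditions = d)
}

test_that("chronic onsets match the incidence x RR x AF closed form", {
  dm <- point_mass_demography(male_fraction = 1, category = "heavy")
  pop <- init_population(dm, 10000, 1.0, seed = 1)
  # incidence 0.002/yr, RR 3, AF 2/3 -> attributable probability 0.004
  cm <- one_condition_model(inc_per100k = 200, rr_heavy = 3)
  out <- chronic_annual_update(pop, cm, seed = 2)
  onsets <- sum(out$events$kind == "chronic_onset")
  expect_lt(abs(onsets - 40), 4 * sqrt(40))
})

test_that("abstainers and protected sexes have zero onset probability", {
  dm <- point_mass_demography(male_fraction = 1, category = "abstainer")
  pop <- init_population(dm, 3000, 1.0, seed = 3)
  cm <- one_condition_model(inc_per100k = 5000, rr_heavy = 5)
  out <- chronic_annual_update(pop, cm, seed = 4)
  expect_equal(nrow(out$events), 0)
  # male agents never develop a female-only condition
  dmh <- point_mass_demography(male_fraction = 1, category = "heavy")
  poph <- init_population(dmh, 3000, 1.0, seed = 5)
  cmf <- one_condition_model(inc_per100k = 5000, rr_heavy = 5,
                             female_only = TRUE)
  outf <- chronic_annual_update(poph, cmf, seed = 6)
  expect_equal(nrow(outf$events), 0)
})

test_that("conditions resolve after their duration and can be fatal", {
  dm <- point_mass_demography(male_fraction = 1, category = "heavy")
  pop <- init_population(dm, 2000, 1.0, seed = 7)
  cm <- one_condition_model(inc_per100k = 30000, rr_heavy = 2,
                            duration = 2)
  out1 <- chronic_annual_update(pop, cm, seed = 8)
  expect_gt(sum(out1$illness$active), 0)
  out2 <- chronic_annual_update(pop, cm, seed = 9, illness = out1$illness)
  out3 <- chronic_annual_update(pop, cm, seed = 10, illness = out2$illness)
  # everyone who onset in year 1 has recovered by the end of year 3
  first_onset <- out1$events$idx[out1$events$kind == "chronic_onset"]
  expect_false(any(out3$illness$active[first_onset, 1] &
                     !(first_onset %in%
                         out3$events$idx[out3$events$kind ==
                                           "chronic_onset"])))
  # a fatal condition reports deaths
  cmf <- one_condition_model(inc_per100k = 30000, rr_heavy = 2)
  cmf$conditions$case_fatality_annual <- 0.5
  outf <- chronic_annual_update(pop, cmf, seed = 11)
  expect_gt(length(outf$deaths), 0)
})
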