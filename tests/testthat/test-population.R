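# Population synthesis, representative/synthetic linkage, ageing, entrants,
# background mortality, and the drinking-category bands.

test_that("degenerate representative splits behave as specified", {
  dm <- demographic_model(default_config()$population)
  pop <- init_population(dm, 1000, 1.0, seed = 1)
  expect_equal(sum(pop$role == 1L), 1000)
  expect_equal(sum(pop$role == 2L), 0)
  expect_true(all(pop$rep_id == pop$person_id))
})

test_that("point-mass distributions produce a uniform population", {
  dm <- point_mass_demography(male_fraction = 1, category = "heavy")
  pop <- init_population(dm, 500, 0.2, seed = 2)
  expect_true(all(pop$sex == 1L))
  expect_true(all(pop$category == 3L))
})

test_that("sampled category prevalence matches the specification", {
  p <- default_config()$population
  spec_prev <- c(0.20, 0.50, 0.22, 0.08)
  p$category_prevalence <- matrix(spec_prev, nrow(p$category_prevalence),
                                  4, byrow = TRUE)
  dm <- demographic_model(p)
  pop <- init_population(dm, 20000, 0.05, seed = 3)
  emp <- tabulate(pop$category + 1L, 4) / 20000
  expect_true(all(abs(emp - spec_prev) < 0.015))
  # chi-square goodness of fit does not reject at alpha = 0.001
  expect_gt(stats::chisq.test(tabulate(pop$category + 1L, 4),
                              p = spec_prev)$p.value, 0.001)
})

test_that("every synthetic person links to a stratum-matched representative", {
  pop <- small_population(n = 2000, rep_frac = 0.1, seed = 7)
  syn <- which(pop$role == 2L)
  rp <- match(pop$rep_id[syn], pop$person_id)
  expect_false(any(is.na(rp)))
  expect_true(all(pop$role[rp] == 1L))
  expect_true(all(pop$stratum[syn] == pop$stratum[rp]))
  expect_true(all(pop$sex[syn] == pop$sex[rp]))
  expect_true(all(pop$category[syn] == pop$category[rp]))
})

test_that("no agent under legal age exists and histories fit the window", {
  pop <- small_population(n = 1000)
  expect_true(all(pop$age >= 18))
  expect_true(all(pop$hist_len <= 20))
  expect_true(all(pop$hist_len >= 1))
})

test_that("ageing with zero mortality and zero entry preserves the roster", {
  p <- default_config()$population
  p$background_mortality <- list(makeham_a = 0, gompertz_b = 0,
                                 gompertz_g = 0.1)
  p$entry_rate_per100k <- 0
  p$max_age <- 200
  dm <- demographic_model(p)
  pop <- init_population(dm, 500, 0.2, seed = 4)
  ages <- pop$age
  pop2 <- advance_demography(pop, dm, dt = 1, seed = 5)
  expect_equal(length(pop2$person_id), 500)
  expect_equal(pop2$age, ages + 1)
})

test_that("a flat hazard produces binomially many deaths", {
  p <- default_config()$population
  haz <- 0.01
  p$background_mortality <- list(makeham_a = -log(1 - haz),
                                 gompertz_b = 1e-12, gompertz_g = 0.01)
  p$entry_rate_per100k <- 0
  dm <- demographic_model(p)
  pop <- init_population(dm, 20000, 0.1, seed = 6)
  pop2 <- advance_demography(pop, dm, dt = 1, seed = 7)
  deaths <- 20000 - length(pop2$person_id)
  # binomial oracle: np +/- 4 sd
  expect_lt(abs(deaths - 20000 * haz), 4 * sqrt(20000 * haz * (1 - haz)))
})

test_that("entrants arrive at the legal age at the configured rate", {
  p <- default_config()$population
  p$background_mortality <- list(makeham_a = 0, gompertz_b = 0,
                                 gompertz_g = 0.1)
  p$max_age <- 200
  p$entry_rate_per100k <- 2000
  dm <- demographic_model(p)
  pop <- init_population(dm, 10000, 0.1, seed = 8)
  pop2 <- advance_demography(pop, dm, dt = 1, seed = 9)
  entrants <- length(pop2$person_id) - 10000
  expect_lt(abs(entrants - 200), 4 * sqrt(200))
  expect_true(all(pop2$age[-(1:10000)] == 18))
})

test_that("births minus deaths equals the net change each step", {
  dm <- demographic_model(default_config()$population)
  pop <- init_population(dm, 5000, 0.1, seed = 10)
  pop2 <- advance_demography(pop, dm, dt = 1, seed = 11)
  step <- attr(pop2, "last_step")
  expect_equal(length(pop2$person_id) - 5000,
               step$entrants - step$deaths)
})

test_that("category bands follow the half-open convention", {
  bands <- list(low_upper = 2.5, moderate_upper = 6.5)
  expect_equal(category_from_consumption(1.5, bands), 1L)   # low
  expect_equal(category_from_consumption(7.0, bands), 3L)   # heavy
  expect_equal(category_from_consumption(2.5, bands), 2L)   # gap -> moderate
  expect_equal(category_from_consumption(6.4, bands), 2L)
  expect_equal(category_from_consumption(6.5, bands), 3L)
  expect_equal(category_from_consumption(0, bands,
                                         drinks_at_all = FALSE), 0L)
  expect_error(category_from_consumption(-1, bands), "non-negative")
})

test_that("update_drinking_category appends history and recodes", {
  person <- list(category = 3L, consumption_history = rep(8, 20))
  p2 <- update_drinking_category(person, 1.5)
  expect_equal(p2$category, 1L)
  expect_length(p2$consumption_history, 20)
  expect_equal(tail(p2$consumption_history, 1), 1.5)
})

test_that("population snapshots round-trip through CSV", {
  pop <- small_population(n = 200)
  path <- tempfile(fileext = ".csv")
  write_population_snapshot(pop, path)
  d <- read_population_snapshot(path)
  expect_equal(nrow(d), 200)
  expect_equal(names(d), c("person_id", "age", "sex", "weight_kg",
                           "category", "role", "representative_id"))
  expect_equal(d$person_id, pop$person_id)
})

test_that("representative statistics agree with whole-population statistics", {
  # stratified-resampling property: stats over representatives, being a
  # uniform random subsample within strata, match the full population
  dm <- demographic_model(default_config()$population)
  pop <- init_population(dm, 20000, 0.2, seed = 12)
  reps <- pop$role == 1L
  expect_lt(abs(mean(pop$age[reps]) - mean(pop$age)), 1.5)
  expect_lt(abs(mean(pop$category[reps] == 3L) -
                mean(pop$category == 3L)), 0.02)
  expect_lt(abs(mean(pop$sex[reps] == 1L) - mean(pop$sex == 1L)), 0.03)
})
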