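# The COM-B rules engine: capacity gates, opportunity weights, motivation
# draws, pre-loading, and the emergent consumption bands.

test_that("capacity rules veto drinking where they should", {
  rules <- comb_rules(default_config()$behaviour)
  p <- list(category = 3L, age = 30)
  expect_false(capacity_ok(list(category = 0L), context_state("home"), rules))
  expect_false(capacity_ok(p, context_state("work"), rules))
  expect_false(capacity_ok(p, context_state("transit"), rules))
  expect_false(capacity_ok(p, context_state("home"), rules, bac = 0.3))
  expect_false(capacity_ok(c(p, hospitalised = TRUE),
                           context_state("home"), rules))
  expect_true(capacity_ok(p, context_state("home"), rules))
})

test_that("context states respect their construction invariants", {
  expect_error(context_state("home", "with_coworkers"), "work or venue")
  expect_silent(context_state("venue", "with_coworkers"))
  expect_error(context_state("office"))
})

test_that("abstainers and zero opportunity yield no episode", {
  cfg <- tiny_config()
  rules <- comb_rules(cfg$behaviour)
  pop <- small_population(120)
  env <- build_environment(cfg, pop, seed = 1)
  abst <- list(person_id = 1L, age = 40, sex = "male", weight = 80,
               category = "abstainer")
  expect_null(decide_episode(abst, context_state("home"), rules, env,
                             17, seed = 1, config = cfg))
  w <- opportunity_weights(abst, rules)
  expect_true(all(w == 0))
})

test_that("drinkers generate episodes whose drinks respect the schedule", {
  cfg <- tiny_config()
  rules <- comb_rules(cfg$behaviour)
  pop <- small_population(120)
  env <- build_environment(cfg, pop, seed = 1)
  p <- list(person_id = 2L, age = 35, sex = "female", weight = 70,
            category = "heavy")
  found <- FALSE
  for (s in 1:30) {
    ep <- decide_episode(p, context_state("home"), rules, env, 17,
                         seed = s, config = cfg)
    if (!is.null(ep)) {
      found <- TRUE
      expect_s3_class(ep, "alco_episode")
      expect_true(all(ep$drink_times >= ep$start))
      expect_true(all(ep$drink_times <= ep$end))
      expect_true(all(ep$grams > 0))
      expect_true(ep$location %in% c("home", "venue", "peer_event"))
    }
  }
  expect_true(found)
})

test_that("identical seeds give identical episode streams", {
  cfg <- tiny_config()
  rules <- comb_rules(cfg$behaviour)
  pop <- small_population(120)
  env <- build_environment(cfg, pop, seed = 1)
  p <- list(person_id = 3L, age = 24, sex = "male", weight = 85,
            category = "moderate")
  a <- lapply(1:20, function(s) decide_episode(p, context_state("home"),
                                               rules, env, 17, seed = s,
                                               config = cfg))
  b <- lapply(1:20, function(s) decide_episode(p, context_state("home"),
                                               rules, env, 17, seed = s,
                                               config = cfg))
  expect_identical(a, b)
})

test_that("long-run heavy-drinker intake stays in the heavy band", {
  cfg <- tiny_config()
  rules <- comb_rules(cfg$behaviour)
  pop <- small_population(120)
  env <- build_environment(cfg, pop, seed = 1)
  p <- list(person_id = 4L, age = 45, sex = "male", weight = 85,
            category = "heavy")
  drinks <- vapply(1:2000, function(s) {
    ep <- decide_episode(p, context_state("home"), rules, env, 17,
                         seed = 1e6 + s, config = cfg,
                         weekend = (s %% 7) %in% c(0, 1))
    if (is.null(ep)) 0 else length(ep$drink_times)
  }, numeric(1))
  expect_gte(mean(drinks), 6.5)
})

test_that("emergent means order heavy > moderate > low", {
  cfg <- tiny_config()
  rules <- comb_rules(cfg$behaviour)
  mean_for <- function(cat) {
    p <- list(person_id = 5L, age = 45, sex = "male", weight = 85,
              category = cat)
    mean(vapply(1:600, function(s) {
      ep <- decide_episode(p, context_state("home"), rules, NULL, 17,
                           seed = 2e6 + s, config = cfg)
      if (is.null(ep)) 0 else length(ep$drink_times)
    }, numeric(1)))
  }
  m <- c(low = mean_for("low"), moderate = mean_for("moderate"),
         heavy = mean_for("heavy"))
  expect_true(m[["heavy"]] > m[["moderate"]])
  expect_true(m[["moderate"]] > m[["low"]])
  expect_lt(m[["low"]], 2.5)
})

test_that("pre-loading requires an open bottle shop and obeys its rate", {
  cfg <- tiny_config()
  rules <- comb_rules(cfg$behaviour)
  pop <- small_population(120)
  env <- build_environment(cfg, pop, seed = 1)
  p <- list(person_id = 6L, age = 24, sex = "male", weight = 80,
            category = "heavy")
  # closed shops: never a purchase
  env_closed <- env
  env_closed$bottle_shops$opening_hour <- 2
  env_closed$bottle_shops$closing_hour <- 3
  for (s in 1:20) {
    pp <- preload_and_purchase(p, list(slot = 22), rules, env_closed,
                               seed = s, config = cfg)
    expect_null(pp$purchase)
    expect_null(pp$home_episode)
  }
  # probability 1: always a home episode before the visit
  rules1 <- rules
  rules1$preload$prob[] <- 1
  rules1$preload$young_mult <- 1
  for (s in 1:10) {
    pp <- preload_and_purchase(p, list(slot = 22), rules1, env,
                               seed = s, config = cfg)
    expect_false(is.null(pp$home_episode))
    expect_true(pp$home_episode$end <= 22)
  }
  # binomial oracle at probability 0.3
  rules3 <- rules
  rules3$preload$prob[] <- 0.3
  rules3$preload$young_mult <- 1
  hits <- sum(vapply(1:1000, function(s) {
    !is.null(preload_and_purchase(p, list(slot = 22), rules3, env,
                                  seed = 5e6 + s, config = cfg)$home_episode)
  }, logical(1)))
  expect_lt(abs(hits - 300), 4 * sqrt(1000 * 0.3 * 0.7))
})

test_that("episode logs round-trip through CSV", {
  cfg <- tiny_config()
  rules <- comb_rules(cfg$behaviour)
  p <- list(person_id = 7L, age = 30, sex = "male", weight = 80,
            category = "moderate")
  eps <- Filter(Negate(is.null), lapply(1:30, function(s)
    decide_episode(p, context_state("home"), rules, NULL, 17, seed = s,
                   config = cfg)))
  path <- tempfile(fileext = ".csv")
  write_episode_log(eps, path)
  d <- read.csv(path)
  expect_equal(nrow(d), length(eps))
  expect_true(all(d$n_drinks >= 1))
  expect_equal(d$grams_total, d$n_drinks * 10)
})
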