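# Monthly per-100k series, replicate summaries, scenario comparison and the
# calibration harness.

test_that("monthly per-100k counting scales by the denominator", {
  log1 <- data.frame(month = rep(1, 45), kind = "acute", ed = FALSE,
                     hospital = FALSE)
  pops <- data.frame(month = 1, denominator = 1e5)
  expect_equal(monthly_per100k(log1, pops)$acute_per100k, 45)
  pops2 <- data.frame(month = 1, denominator = 2e4)
  log2 <- data.frame(month = rep(1, 9), kind = "acute", ed = FALSE,
                     hospital = FALSE)
  expect_equal(monthly_per100k(log2, pops2)$acute_per100k, 45)
  # empty log -> all-zero series
  empty <- data.frame(month = integer(0), kind = character(0),
                      ed = logical(0), hospital = logical(0))
  s <- monthly_per100k(empty, data.frame(month = 1:3, denominator = 1000))
  expect_equal(s$acute_per100k, c(0, 0, 0))
  expect_equal(s$chronic_per100k, c(0, 0, 0))
  expect_error(monthly_per100k(empty, data.frame(month = 1,
                                                 denominator = 0)),
               "positive")
})

test_that("ED and hospitalisation series count flagged acute events", {
  log <- data.frame(month = c(1, 1, 1, 1),
                    kind = c("acute", "acute", "acute", "chronic_annual"),
                    ed = c(TRUE, TRUE, FALSE, TRUE),
                    hospital = c(TRUE, FALSE, FALSE, TRUE))
  pops <- data.frame(month = 1, denominator = 1e5)
  s <- monthly_per100k(log, pops)
  expect_equal(s$acute_per100k, 3)
  expect_equal(s$ed_per100k, 2)
  expect_equal(s$hosp_per100k, 1)
  expect_equal(s$chronic_per100k, 1)
  # flagged series never exceed acute incidence
  expect_true(all(s$ed_per100k <= s$acute_per100k))
  expect_true(all(s$hosp_per100k <= s$acute_per100k))
})

fake_series <- function(means) lapply(means, function(m)
  data.frame(month = 1:60, acute_per100k = m))

test_that("replicate summaries match the textbook t-interval", {
  set.seed(1)
  means <- rnorm(12, 44, 2)
  s <- summarize_replicates(fake_series(means), "acute_per100k")
  expect_equal(s$mean, mean(means), tolerance = 1e-9)
  expect_equal(s$sd, sd(means), tolerance = 1e-9)
  expect_equal(s$margin_of_error,
               qt(0.975, 11) * sd(means) / sqrt(12), tolerance = 1e-9)
  expect_error(summarize_replicates(fake_series(44), "acute_per100k"),
               "at least 2")
  # zero spread gives a zero margin
  s0 <- summarize_replicates(fake_series(rep(3, 5)), "acute_per100k")
  expect_equal(s0$margin_of_error, 0)
})

test_that("published-style margins reproduce from (sd, n = 12)", {
  margin <- function(sdv) qt(0.975, 11) * sdv / sqrt(12)
  expect_equal(round(margin(1.8), 1), 1.1)
  expect_equal(round(margin(1.0), 1), 0.6)
  expect_equal(round(margin(0.3), 1), 0.2)
})

test_that("scenario comparison computes percent reduction of means", {
  base <- fake_series(rep(44.5, 6))
  cmp <- compare_scenarios(base, fake_series(rep(35.82, 6)))
  expect_equal(cmp$percent_reduction, 100 * (44.5 - 35.82) / 44.5,
               tolerance = 1e-9)
  expect_equal(round(cmp$percent_reduction, 1), 19.5)
  cmp2 <- compare_scenarios(base, fake_series(rep(29.68, 6)))
  expect_equal(round(cmp2$percent_reduction, 1), 33.3)
  # identical sets -> zero reduction
  expect_equal(compare_scenarios(base, base)$percent_reduction, 0)
  expect_error(compare_scenarios(fake_series(rep(0, 3)), base), "zero")
})

test_that("comparison is antisymmetric up to the baseline normaliser", {
  set.seed(2)
  a <- fake_series(rnorm(8, 40, 2)); b <- fake_series(rnorm(8, 30, 2))
  ab <- compare_scenarios(a, b)$percent_reduction
  ba <- compare_scenarios(b, a)$percent_reduction
  # swapping negates the absolute difference (normalised by the new base)
  expect_equal(ab * compare_scenarios(a, b)$baseline_mean,
               -ba * compare_scenarios(b, a)$baseline_mean,
               tolerance = 1e-9)
  expect_lt(ba, 0)
})

test_that("calibration recovers a known scale from a linear outcome", {
  # synthetic truth: outcome = 100 * scale; target generated at scale 3e-7
  evaluate <- function(cfg) list(acute_rate = 1.5e8 *
                                   cfg$acute_hazards$scale)
  fp <- data.frame(path = "acute_hazards.scale", lower = 1e-8,
                   upper = 1e-6)
  tg <- data.frame(outcome = "acute_rate", value = 45, tolerance = 0.1)
  fit <- calibrate(fp, tg, budget = 60, seed = 9, evaluate = evaluate)
  expect_true(fit$met)
  expect_equal(fit$config$acute_hazards$scale, 45 / 1.5e8,
               tolerance = 0.01)
  # seeded determinism
  fit2 <- calibrate(fp, tg, budget = 60, seed = 9, evaluate = evaluate)
  expect_identical(fit$parameters, fit2$parameters)
})

test_that("calibration returns immediately when targets are already met", {
  evaluate <- function(cfg) list(x = 1)
  fp <- data.frame(path = "acute_hazards.scale", lower = 0, upper = 1)
  tg <- data.frame(outcome = "x", value = 1, tolerance = 0.5)
  fit <- calibrate(fp, tg, budget = 50, seed = 1, evaluate = evaluate)
  expect_true(fit$met)
  expect_equal(fit$n_eval, 1L)
})

test_that("two-parameter calibration improves a noisy objective", {
  evaluate <- function(cfg)
    list(a = 10 * cfg$acute_hazards$scale,
         b = cfg$chronic_model$scale^2)
  fp <- data.frame(path = c("acute_hazards.scale", "chronic_model.scale"),
                   lower = c(0, 0), upper = c(10, 4))
  tg <- data.frame(outcome = c("a", "b"), value = c(20, 4),
                   tolerance = c(0.5, 0.5))
  fit <- calibrate(fp, tg, budget = 120, seed = 4, evaluate = evaluate)
  expect_true(fit$met)
  expect_equal(unname(fit$parameters["acute_hazards.scale"]), 2,
               tolerance = 0.05)
  expect_equal(unname(fit$parameters["chronic_model.scale"]), 2,
               tolerance = 0.05)
})

test_that("comparison and series writers emit readable files", {
  base <- fake_series(rep(40, 4)); scen <- fake_series(rep(30, 4))
  cmp <- compare_scenarios(base, scen)
  p1 <- tempfile(fileext = ".json")
  write_comparison(cmp, p1)
  back <- jsonlite::read_json(p1)
  expect_equal(back$percent_reduction, 25)
  p2 <- tempfile(fileext = ".csv")
  write_monthly_series(base[[1]], p2)
  expect_equal(nrow(read.csv(p2)), 60)
})
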