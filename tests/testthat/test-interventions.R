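# Scenario overlays and the treatment-expansion mechanism.

test_that("an empty scenario is the identity overlay", {
  cfg <- default_config()
  eff <- apply_scenario(cfg, scenario_baseline(), "2019-06-01")
  expect_identical(eff, cfg)
  expect_identical(apply_scenario(cfg, NULL, "2019-06-01"), cfg)
})

test_that("overrides apply only from the start date", {
  cfg <- default_config()
  s1 <- scenario_closing_lockout("2017-01-01")
  before <- apply_scenario(cfg, s1, "2016-06-01")
  expect_identical(before, cfg)
  after <- apply_scenario(cfg, s1, "2018-01-01")
  expect_equal(after$environment$venues$closing_hour, 3)
  expect_true(after$environment$venues$closing_wraps)
  expect_equal(after$environment$venues$lockout_hour, 1)
  expect_equal(after$environment$bottle_shops$closing_hour, 22)
  # untouched parameters stay untouched; the baseline object is unmutated
  expect_equal(after$acute_hazards, cfg$acute_hazards)
  expect_equal(cfg$environment$venues$closing_hour, 5)
})

test_that("the combined scenario is the union of its parts", {
  s1 <- scenario_closing_lockout()
  s3 <- scenario_treatment()
  s4 <- scenario_combined()
  expect_equal(s4$overrides[names(s1$overrides)], s1$overrides)
  expect_equal(s4$overrides[names(s3$overrides)], s3$overrides)
  expect_setequal(names(s4$overrides),
                  union(names(s1$overrides), names(s3$overrides)))
})

test_that("unknown override keys raise a configuration error", {
  s <- scenario_closing_only()
  s$overrides$minimum_price <- 1.5
  expect_error(apply_scenario(default_config(), s, "2018-01-01"),
               class = "alco_config_error")
})

test_that("disjoint overlays commute", {
  cfg <- default_config()
  sa <- scenario("a", "2017-01-01", venue_closing_hour = 3)
  sb <- scenario("b", "2017-01-01", treatment_coverage = 0.2)
  ab <- apply_scenario(apply_scenario(cfg, sa, "2018-01-01"), sb,
                       "2018-01-01")
  ba <- apply_scenario(apply_scenario(cfg, sb, "2018-01-01"), sa,
                       "2018-01-01")
  expect_identical(ab, ba)
})

test_that("scenario files round-trip through YAML", {
  s <- scenario_combined()
  path <- tempfile(fileext = ".yaml")
  write_scenario(s, path)
  s2 <- read_scenario(path)
  expect_equal(s2$name, s$name)
  expect_equal(s2$start_date, s$start_date)
  expect_equal(s2$overrides[order(names(s2$overrides))],
               s$overrides[order(names(s$overrides))])
  # the four packaged scenario files load and match their constructors
  dir <- system.file("extdata", "scenarios", package = "alcosim")
  files <- list.files(dir, full.names = TRUE)
  expect_gte(length(files), 5)
})

test_that("treatment enrolment follows the binomial coverage", {
  dm <- point_mass_demography(male_fraction = 1, category = "heavy")
  pop <- init_population(dm, 1000, 1.0, seed = 1)
  cfg <- default_config()
  # coverage 0: unchanged
  cfg$treatment$coverage <- 0
  pop0 <- treatment_step(pop, cfg, 2017, seed = 2)
  expect_equal(pop0$category, pop$category)
  # coverage 1, certain effect, no relapse: no heavy drinkers remain
  cfg1 <- cfg
  cfg1$treatment$coverage <- 1
  cfg1$treatment$effect_heavy_to_moderate <- 1
  cfg1$treatment$relapse_rate <- 0
  pop1 <- treatment_step(pop, cfg1, 2017, seed = 3)
  expect_equal(sum(pop1$category == 3L), 0)
  expect_true(all(pop1$category == 2L))
  # coverage 0.2 on 1000 heavy drinkers: ~200 enrolled
  cfg2 <- cfg
  cfg2$treatment$coverage <- 0.2
  pop2 <- treatment_step(pop, cfg2, 2017, seed = 4)
  n_enrol <- attr(pop2, "treatment")$enrolled
  expect_lt(abs(n_enrol - 200), 4 * sqrt(1000 * 0.2 * 0.8))
})

test_that("relapse is suppressed by late-night restriction", {
  cfg <- default_config()
  s1cfg <- apply_scenario(cfg, scenario_closing_lockout(), "2018-01-01")
  s2cfg <- apply_scenario(cfg, scenario_closing_only(), "2018-01-01")
  expect_equal(alcosim:::late_restriction_index(cfg, cfg), 0)
  expect_equal(alcosim:::late_restriction_index(s2cfg, cfg), 0.5)
  expect_equal(alcosim:::late_restriction_index(s1cfg, cfg), 1)
  # treated agents relapse under permissive conditions, not under lockout
  dm <- point_mass_demography(male_fraction = 1, category = "heavy")
  pop <- init_population(dm, 800, 1.0, seed = 5)
  cfg1 <- cfg
  cfg1$treatment$coverage <- 1
  cfg1$treatment$effect_heavy_to_moderate <- 1
  pop_t <- treatment_step(pop, cfg1, 2017, seed = 6)
  open_env <- treatment_step(pop_t, cfg1, 2018, seed = 7,
                             baseline_cfg = cfg)
  s4cfg <- apply_scenario(cfg1, scenario_closing_lockout(), "2018-01-01")
  s4cfg$treatment <- cfg1$treatment
  locked_env <- treatment_step(pop_t, s4cfg, 2018, seed = 7,
                               baseline_cfg = cfg)
  expect_gt(attr(open_env, "treatment")$relapsed,
            attr(locked_env, "treatment")$relapsed)
})
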