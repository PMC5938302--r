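# Shared fixtures: small configurations and populations built in code.

tiny_config <- function() {
  cfg <- default_config()
  cfg$environment$precincts$n_precincts <- c(1, 1, 1)
  cfg$environment$precincts$venues_each <- c(1, 1, 2)
  cfg$environment$bottle_shops$n <- 2
  cfg
}

# a demographic model with point-mass age/sex/category, handy for
# deterministic composition checks
point_mass_demography <- function(male_fraction = 1,
                                  category = "heavy") {
  p <- default_config()$population
  p$male_fraction <- male_fraction
  idx <- match(category, c("abstainer", "low", "moderate", "heavy"))
  prev <- matrix(0, nrow(p$category_prevalence), 4)
  prev[, idx] <- 1
  p$category_prevalence <- prev
  demographic_model(p)
}

small_population <- function(n = 500, rep_frac = 0.2, seed = 42) {
  dm <- demographic_model(default_config()$population)
  init_population(dm, n, rep_frac, seed = seed)
}

# default venue record used by admission tests
venue_record <- function(closing_hour = 5, lockout_hour = NA,
                         rsa = 0.15, opening_hour = 12) {
  list(opening_hour = opening_hour, closing_hour = closing_hour,
       closing_wraps = closing_hour <= opening_hour,
       lockout_hour = lockout_hour, rsa_refusal_bac = rsa)
}

# run a very small simulation quickly (2 years spin-up + 1 window year)
quick_spec <- function(seed = 5, n_replicates = 1, n = 3000) {
  run_spec(seed = seed, n_replicates = n_replicates, population_size = n,
           representative_fraction = 0.1,
           spin_up_start = "2015-01-01", spin_up_end = "2016-12-31",
           window_start = "2017-01-01", window_end = "2017-12-31")
}
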