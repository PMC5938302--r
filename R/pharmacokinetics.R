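# Continuous-time blood alcohol concentration via the Widmark equation.
#
# A drink of A grams ethanol raises BAC by 100 * A / (r * W * 1000) g/100mL
# (Widmark distribution factor r, body weight W kg); elimination is linear at
# beta g/100mL per hour with a floor at zero. Absorption is treated as
# instantaneous at drink time, so trajectories are piecewise linear with
# upward jumps at drink times.

#' Body parameters for BAC computation
#'
#' @param weight Body weight in kilograms.
#' @param sex `"male"` or `"female"`.
#' @param widmark_r Widmark distribution factor in (0, 1); defaults to the
#'   configured sex-specific value (0.68 male, 0.55 female).
#' @param beta Elimination rate, g/100mL per hour.
#' @return A list of class `alco_body`.
#' @export
#' @examples
#' body_params(80, "male")
body_params <- function(weight, sex, widmark_r = NULL, beta = 0.015) {
  stopifnot(weight > 0, sex %in% c("male", "female"), beta > 0)
  if (is.null(widmark_r)) widmark_r <- if (sex == "male") 0.68 else 0.55
  stopifnot(widmark_r > 0, widmark_r < 1)
  structure(list(weight = weight, sex = sex, widmark_r = widmark_r,
                 beta = beta), class = "alco_body")
}

#' Blood alcohol concentration state
#'
#' @param bac Current BAC, g/100mL (non-negative).
#' @param last_update Time of last update, hours since run origin.
#' @return A list of class `alco_bac`.
#' @export
bac_state <- function(bac = 0, last_update = 0) {
  stopifnot(bac >= 0)
  structure(list(bac = bac, last_update = last_update), class = "alco_bac")
}

#' Metabolic decay of BAC
#'
#' Advances a BAC state by `t` hours of linear elimination,
#' `bac' = max(0, bac - beta * t)`.
#'
#' @param state An [bac_state()].
#' @param body A [body_params()].
#' @param t Hours elapsed since the state's `last_update`; must be >= 0.
#' @return The updated `alco_bac` state.
#' @export
#' @examples
#' s <- bac_decay(bac_state(0.05), body_params(80, "male"), t = 2)
#' s$bac  # 0.02
bac_decay <- function(state, body, t) {
  if (t < 0) stop("time increment must be non-negative")
  state$bac <- max(0, state$bac - body$beta * t)
  state$last_update <- state$last_update + t
  state
}

#' Instantaneous BAC increment from a drink
#'
#' Applies the Widmark equation: a drink of `grams_ethanol` grams raises BAC
#' by `100 * grams / (r * W * 1000)` g/100mL.
#'
#' @inheritParams bac_decay
#' @param grams_ethanol Grams of ethanol in the drink; must be positive.
#' @return The updated `alco_bac` state.
#' @export
#' @examples
#' s <- add_drink(bac_state(), body_params(80, "male", widmark_r = 0.68), 10)
#' s$bac  # ~0.0184
add_drink <- function(state, body, grams_ethanol) {
  if (grams_ethanol <= 0) stop("grams_ethanol must be positive")
  state$bac <- state$bac + widmark_increment(grams_ethanol, body$widmark_r,
                                             body$weight)
  state
}

widmark_increment <- function(grams, r, weight_kg) {
  100 * grams / (r * weight_kg * 1000)
}

#' Closed-form BAC trajectory for a drink schedule
#'
#' Evaluates the Widmark sum-minus-decay form
#' `bac(t) = max(0, sum_i c_i 1[t >= t_i] - beta * elapsed drinking-down time)`
#' exactly, accounting for the zero floor between widely spaced drinks by
#' sequential piecewise-linear evaluation.
#'
#' @param drink_times Numeric vector of drink times (hours), non-decreasing.
#' @param grams Grams of ethanol per drink (scalar or vector).
#' @param body A [body_params()].
#' @param at Times at which to evaluate the trajectory.
#' @return Numeric vector of BAC values at `at`.
#' @export
bac_trajectory <- function(drink_times, grams, body, at) {
  stopifnot(!is.unsorted(drink_times))
  grams <- rep_len(grams, length(drink_times))
  inc <- widmark_increment(grams, body$widmark_r, body$weight)
  vapply(at, function(tt) {
    b <- 0; tcur <- -Inf
    for (i in seq_along(drink_times)) {
      ti <- drink_times[i]
      if (ti > tt) break
      if (is.finite(tcur)) b <- max(0, b - body$beta * (ti - tcur))
      b <- b + inc[i]
      tcur <- ti
    }
    if (is.finite(tcur)) max(0, b - body$beta * (tt - tcur)) else 0
  }, numeric(1))
}

# Vectorised episode BAC geometry for evenly spaced equal drinks.
# n drinks of increment c at spacing dt (hours), elimination beta:
# peak after drink i is s_i = i*c - (i-1)*beta*dt (assumes c > beta*dt so the
# floor never binds within the episode). Returns peaks and end-of-episode BAC.
episode_peaks <- function(n, c_inc, dt, beta) {
  i <- seq_len(max(n, 0))
  s <- i * c_inc - (i - 1) * beta * dt
  pmax(s, 0)
}
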