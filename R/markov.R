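#' Model settings for the cohort simulation
#'
#' @param cycle_days Cycle length in days (default 28, a four-week cycle).
#' @param horizon_cycles Number of cycles (default 65: five years of
#'   28-day cycles, `floor(5 * 365.25 / 28)`, i.e. 4.98 years).
#' @param annual_discount_rate Annual discount rate for costs and
#'   utilities (default 0.03).
#' @param half_cycle_correction If `TRUE`, accrue on the average of
#'   start- and end-of-cycle occupancy instead of start-of-cycle
#'   occupancy.
#' @return A list of class `model_settings`.
#' @export
model_settings <- function(cycle_days = 28, horizon_cycles = 65,
                           annual_discount_rate = 0.03,
                           half_cycle_correction = FALSE) {
  stopifnot(cycle_days > 0, horizon_cycles >= 1, annual_discount_rate >= 0)
  structure(list(cycle_days = cycle_days,
                 horizon_cycles = as.integer(horizon_cycles),
                 annual_discount_rate = annual_discount_rate,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "model_settings")
}

#' One transition step of the three-state cohort
#'
#' Stable patients remain, progress, or die; progressive patients remain
#' or die (no return to the stable state); death is absorbing.
#'
#' @param occupancy Numeric length-3 vector `(stable, progressive, dead)`
#'   summing to 1.
#' @param p_sp,p_sd,p_pd Per-cycle transition probabilities (stable to
#'   progressive, stable to dead, progressive to dead).
#' @return The next occupancy vector.
#' @export
markov_step <- function(occupancy, p_sp, p_sd, p_pd) {
  stopifnot(length(occupancy) == 3, abs(sum(occupancy) - 1) < 1e-9)
  if (p_sp + p_sd > 1 + 1e-12) {
    stop("p_sp + p_sd exceeds 1", call. = FALSE)
  }
  s <- occupancy[1]; p <- occupancy[2]; d <- occupancy[3]
  c(s * (1 - p_sp - p_sd),
    s * p_sp + p * (1 - p_pd),
    d + s * p_sd + p * p_pd)
}

#' Per-cycle discount factor
#'
#' `(1 + r)^(-(cycle * cycle_days / 365.25))`: continuous-in-cycles
#' compounding of the annual rate on the day grid.
#'
#' @param cycle Cycle index (0-based) or vector of indices.
#' @param settings A [model_settings()].
#' @return Discount factor(s) in (0, 1\].
#' @export
discount_factor <- function(cycle, settings) {
  stopifnot(all(cycle >= 0))
  (1 + settings$annual_discount_rate)^(-(cycle * settings$cycle_days / 365.25))
}

#' Run the cohort simulation for one strategy
#'
#' Starts the whole cohort in the stable state and iterates the
#' transition schedule, accruing per cycle (on start-of-cycle occupancy,
#' or the half-cycle average if enabled):
#' cost \eqn{= \sum_{state} occ \cdot cost(state, cycle) \cdot df},
#' life-years \eqn{= alive \cdot (cycle\_days / 365.25) \cdot df}, and
#' QALYs \eqn{= \sum_{state} occ \cdot utility(state, cycle) \cdot
#' (cycle\_days/365.25) \cdot df}. Death accrues zero cost and zero
#' utility.
#'
#' @param schedule A [build_schedule()] tibble for the strategy.
#' @param cost_fun Function `(state, cycle)` returning the per-cycle cost
#'   (euro) for `state` in `{"stable", "progressive"}` at 0-based `cycle`.
#' @param utility_fun Function `(state, cycle)` returning the utility.
#' @param settings A [model_settings()]; its horizon must match the
#'   schedule length.
#' @return A tibble of class `cohort_trace` with per-cycle occupancies and
#'   discounted/undiscounted incremental accruals, plus attribute
#'   `totals` (named vector: `cost`, `ly`, `qaly`, `cost_undisc`,
#'   `ly_undisc`, `qaly_undisc`).
#' @export
run_cohort <- function(schedule, cost_fun, utility_fun,
                       settings = model_settings()) {
  n <- nrow(schedule)
  if (n != settings$horizon_cycles) {
    stop("schedule length (", n, ") does not match settings horizon (",
         settings$horizon_cycles, ")", call. = FALSE)
  }
  cycles <- schedule$cycle
  occ <- matrix(NA_real_, n + 1, 3,
                dimnames = list(NULL, c("stable", "progressive", "dead")))
  occ[1, ] <- c(1, 0, 0)
  for (i in seq_len(n)) {
    occ[i + 1, ] <- markov_step(occ[i, ], schedule$p_sp[i], schedule$p_sd[i],
                                schedule$p_pd[i])
  }
  w <- if (settings$half_cycle_correction) {
    (occ[seq_len(n), , drop = FALSE] + occ[seq_len(n) + 1, , drop = FALSE]) / 2
  } else {
    occ[seq_len(n), , drop = FALSE]
  }
  df <- discount_factor(cycles, settings)
  yrs <- settings$cycle_days / 365.25
  cost_s <- vapply(cycles, function(c) cost_fun("stable", c), numeric(1))
  cost_p <- vapply(cycles, function(c) cost_fun("progressive", c), numeric(1))
  util_s <- vapply(cycles, function(c) utility_fun("stable", c), numeric(1))
  util_p <- vapply(cycles, function(c) utility_fun("progressive", c),
                   numeric(1))

  cost_cyc <- w[, 1] * cost_s + w[, 2] * cost_p
  ly_cyc <- (w[, 1] + w[, 2]) * yrs
  qaly_cyc <- (w[, 1] * util_s + w[, 2] * util_p) * yrs

  trace <- tibble::tibble(
    cycle = cycles,
    stable = occ[seq_len(n), 1],
    progressive = occ[seq_len(n), 2],
    dead = occ[seq_len(n), 3],
    disc_cost = cost_cyc * df,
    disc_ly = ly_cyc * df,
    disc_qaly = qaly_cyc * df
  )
  class(trace) <- c("cohort_trace", class(trace))
  attr(trace, "final_occupancy") <- occ[n + 1, ]
  attr(trace, "totals") <- c(
    cost = sum(cost_cyc * df), ly = sum(ly_cyc * df),
    qaly = sum(qaly_cyc * df),
    cost_undisc = sum(cost_cyc), ly_undisc = sum(ly_cyc),
    qaly_undisc = sum(qaly_cyc)
  )
  trace
}

#' @rdname run_cohort
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return `glance()`: a one-row tibble of discounted and undiscounted
#'   totals.
#' @method glance cohort_trace
#' @export
glance.cohort_trace <- function(x, ...) {
  tibble::as_tibble(as.list(attr(x, "totals")))
}
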