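test_that("a single step does direct arithmetic and death is absorbing", {
  expect_equal(markov_step(c(1, 0, 0), 0.3, 0.1, 0), c(0.6, 0.3, 0.1))
  expect_equal(markov_step(c(0, 1, 0), 0, 0, 1), c(0, 0, 1))
  occ <- c(0.4, 0.35, 0.25)
  expect_equal(markov_step(occ, 0, 0, 0), occ)
  expect_error(markov_step(c(1, 0, 0), 0.8, 0.3, 0), "exceeds 1")
})

test_that("discount factors follow annual compounding on the day grid", {
  s <- model_settings(annual_discount_rate = 0.03)
  expect_equal(discount_factor(0, s), 1)
  expect_equal(discount_factor(13, s), 1.03^(-(13 * 28 / 365.25)),
               tolerance = 1e-12)
  expect_equal(discount_factor(13, s), 0.9710, tolerance = 1e-4)
  s0 <- model_settings(annual_discount_rate = 0)
  expect_equal(discount_factor(0:64, s0), rep(1, 65))
})

test_that("cohort engine matches the path-enumeration oracle exactly", {
  settings <- model_settings(horizon_cycles = 6)
  cost <- function(state, cycle) if (state == "stable") 100 + cycle else 40
  util <- function(state, cycle) if (state == "stable") 0.61 else 0.5
  for (seed in 1:5) {
    sched <- random_schedule(6, seed)
    tr <- run_cohort(sched, cost, util, settings)
    oracle <- enumerate_cohort(sched, cost, util, settings)
    expect_equal(as.matrix(tr[, c("stable", "progressive", "dead")]),
                 oracle$occ, ignore_attr = TRUE, tolerance = 1e-12)
    totals <- glance(tr)
    expect_equal(totals$cost, oracle$cost, tolerance = 1e-12)
    expect_equal(totals$ly, oracle$ly, tolerance = 1e-12)
    expect_equal(totals$qaly, oracle$qaly, tolerance = 1e-12)
  }
})

test_that("two-cycle pencil-and-paper example reproduces exactly", {
  # cycle 0: half progress; cycle 1: half of the progressive die
  sched <- tibble::tibble(arm = "a", cycle = 0:1, time_months = c(0, 0.92),
                          p_sp = c(0.5, 0), p_sd = 0, p_pd = c(0, 0.5))
  settings <- model_settings(horizon_cycles = 2, annual_discount_rate = 0)
  tr <- run_cohort(sched, function(s, c) 10, function(s, c) 1, settings)
  expect_equal(tr$stable, c(1, 0.5))
  expect_equal(tr$progressive, c(0, 0.5))
  yrs <- 28 / 365.25
  expect_equal(glance(tr)$qaly, 2 * yrs) # everyone alive both cycle starts
  expect_equal(glance(tr)$cost, 10 * (1 + 1)) # both alive states accrue 10
  expect_equal(attr(tr, "final_occupancy"),
               c(stable = 0.5, progressive = 0.25, dead = 0.25))
})

test_that("mass conservation, absorbing death, monotone accumulators", {
  sched <- random_schedule(30, 11)
  settings <- model_settings(horizon_cycles = 30)
  tr <- run_cohort(sched, function(s, c) 50, function(s, c) 0.6, settings)
  expect_equal(tr$stable + tr$progressive + tr$dead, rep(1, 30),
               tolerance = 1e-12)
  expect_true(all(diff(tr$dead) >= -1e-15))
  expect_true(all(tr$disc_cost >= 0))
})

test_that("stable cohort at r = 0 accrues utility times years", {
  n <- 13
  sched <- tibble::tibble(arm = "a", cycle = 0:(n - 1), time_months = 0,
                          p_sp = 0, p_sd = 0, p_pd = 0)
  settings <- model_settings(horizon_cycles = n, annual_discount_rate = 0)
  tr <- run_cohort(sched, function(s, c) 0, function(s, c) 0.61, settings)
  expect_equal(glance(tr)$qaly, 0.61 * n * 28 / 365.25, tolerance = 1e-12)
  expect_equal(glance(tr)$cost, 0)
})

test_that("discounting reduces totals; r = 0 leaves them equal", {
  sched <- random_schedule(20, 3)
  cost <- function(s, c) 100
  util <- function(s, c) 0.5
  tr_r <- run_cohort(sched, cost, util,
                     model_settings(horizon_cycles = 20,
                                    annual_discount_rate = 0.03))
  g <- glance(tr_r)
  expect_lt(g$cost, g$cost_undisc)
  expect_lt(g$qaly, g$qaly_undisc)
  tr_0 <- run_cohort(sched, cost, util,
                     model_settings(horizon_cycles = 20,
                                    annual_discount_rate = 0))
  g0 <- glance(tr_0)
  expect_equal(g0$cost, g0$cost_undisc)
})

test_that("unit utilities make QALYs equal life-years", {
  sched <- random_schedule(25, 8)
  tr <- run_cohort(sched, function(s, c) 0, function(s, c) 1,
                   model_settings(horizon_cycles = 25))
  g <- glance(tr)
  expect_equal(g$qaly, g$ly, tolerance = 1e-12)
})

test_that("half-cycle correction averages start and end occupancy", {
  sched <- random_schedule(5, 2)
  cost <- function(s, c) 100
  util <- function(s, c) 1
  s_off <- model_settings(horizon_cycles = 5, annual_discount_rate = 0)
  s_on <- model_settings(horizon_cycles = 5, annual_discount_rate = 0,
                         half_cycle_correction = TRUE)
  g_off <- glance(run_cohort(sched, cost, util, s_off))
  g_on <- glance(run_cohort(sched, cost, util, s_on))
  # with a shrinking alive fraction the corrected total must be smaller
  expect_lt(g_on$ly, g_off$ly)
})
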