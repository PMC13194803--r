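test_that("survivor-fraction conversion matches hand arithmetic", {
  expect_equal(interval_prob_from_survivor_fraction(1, 5), 0)
  expect_equal(interval_prob_from_survivor_fraction(0.5, 1), 0.5)
  # 0.25^{1/2} = 0.5 -> per-cycle probability 0.5
  expect_equal(interval_prob_from_survivor_fraction(0.25, 2), 0.5)
  expect_equal(interval_prob_from_survivor_fraction(0, 3), 1)
  expect_error(interval_prob_from_survivor_fraction(1.1, 1), "exceed 1")
})

test_that("annual-to-cycle mortality conversion and round-trip", {
  expect_equal(annual_to_cycle_mortality(0), 0)
  # closed form at the life-table-like value, independent arithmetic
  expect_equal(annual_to_cycle_mortality(0.0122),
               1 - 0.9878^(28 / 365.25), tolerance = 1e-12)
  # compounding per-cycle survival over a year returns the annual value
  pc <- annual_to_cycle_mortality(0.0122)
  expect_equal(1 - (1 - pc)^(365.25 / 28), 0.0122, tolerance = 1e-12)
})

test_that("background mortality tracks attained age and clips at table end", {
  lt <- generate_life_table(64, 3, 0.01, 2.0) # 0.01, 0.02, 0.04
  bg <- background_mortality(lt, horizon_cycles = 65, start_age = 64)
  expect_length(bg, 65)
  expect_true(all(diff(bg) >= 0)) # non-decreasing table -> non-decreasing bg
  expect_equal(bg[1], annual_to_cycle_mortality(0.01))
  # cycle 14 starts after 364 days -> still age 64; cycle 15 crosses age 65
  expect_equal(bg[14], annual_to_cycle_mortality(0.01))
  expect_equal(bg[15], annual_to_cycle_mortality(0.02))
  # ages beyond the table carry the last row forward
  expect_equal(bg[65], annual_to_cycle_mortality(0.04))
})

test_that("flat disease curves yield background-only death probabilities", {
  flat <- surv_model("exponential", c(rate = 1e-12))
  sched <- build_schedule(flat, flat, bg = 0.001, horizon_cycles = 10,
                          arm = "x")
  expect_equal(sched$p_sd, rep(0.001, 10))
  expect_equal(sched$p_sp, rep(0, 10), tolerance = 1e-9)
  expect_equal(sched$p_pd, rep(0, 10))
  # no disease, no background: everything zero
  sched0 <- build_schedule(flat, flat, bg = 0, horizon_cycles = 10)
  expect_equal(unlist(sched0[, c("p_sp", "p_sd", "p_pd")]),
               rep(0, 30), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("OS equal to PFS keeps the progressive compartment empty", {
  m <- surv_model("exponential", c(rate = 0.1))
  sched <- build_schedule(m, m, bg = 0, horizon_cycles = 12)
  settings <- model_settings(horizon_cycles = 12, annual_discount_rate = 0)
  zero <- function(state, cycle) 0
  tr <- run_cohort(sched, zero, zero, settings)
  expect_equal(tr$progressive, rep(0, 12), tolerance = 1e-12)
})

test_that("trace reconstruction: engine on a built schedule reproduces the curves", {
  fx <- base_fixture()
  for (arm in c("mirv", "standard")) {
    models <- fx$fits$models[[arm]]
    sched <- build_schedule(models$pfs, models$os, bg = 0,
                            horizon_cycles = 65, arm = arm)
    settings <- model_settings(horizon_cycles = 65)
    zero <- function(state, cycle) 0
    tr <- run_cohort(sched, zero, zero, settings)
    t_grid <- (0:64) * 28 / 30.4375
    s_pfs <- surv_prob(models$pfs, t_grid)
    s_os <- pmax(surv_prob(models$os, t_grid), s_pfs)
    expect_equal(tr$stable, s_pfs, tolerance = 1e-9)
    expect_equal(tr$stable + tr$progressive, s_os, tolerance = 1e-9)
  }
})

test_that("all emitted probabilities lie in [0, 1] with clip accounting", {
  # an OS curve that crosses below PFS forces clipping, which is surfaced
  pfs <- surv_model("exponential", c(rate = 0.05))
  os <- surv_model("exponential", c(rate = 0.08)) # below PFS for t > 0
  expect_message(
    sched <- build_schedule(pfs, os, bg = 0, horizon_cycles = 24),
    "clipped")
  expect_true(all(sched$p_sp >= 0 & sched$p_sp <= 1))
  expect_true(all(sched$p_pd >= 0 & sched$p_pd <= 1))
  expect_true(all(sched$p_sp + sched$p_sd <= 1 + 1e-12))
  clips <- attr(sched, "clip_events")
  expect_gt(clips[["os_below_pfs"]], 0)
})
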