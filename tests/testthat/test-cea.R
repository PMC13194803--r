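test_that("incremental ratios, NMB and dominance flags", {
  a <- c(cost = 100000, ly = 1.5, qaly = 1.0)
  b <- c(cost = 40000, ly = 1.1, qaly = 0.8)
  res <- incremental(a, b, wtp_grid = c(50000, 155499))
  expect_equal(res$delta_cost, 60000)
  expect_equal(res$icer, 60000 / 0.4)
  expect_equal(res$icur, 60000 / 0.2)
  expect_equal(res$nmb$nmb, c(50000, 155499) * 0.2 - 60000)
  # homogeneity: scaling increments by k leaves the ratio unchanged
  res2 <- incremental(b + 3 * (a - b), b)
  expect_equal(res2$icur, res$icur, tolerance = 1e-12)
  # identical strategies: undefined ratios, no dominance
  same <- incremental(a, a)
  expect_true(is.na(same$icur))
  expect_equal(same$dominance, "none")
  # cheaper and more effective: dominance flagged instead of signed ratio
  dom <- incremental(c(cost = 1000, ly = 2, qaly = 1.5), a)
  expect_equal(dom$dominance, "intervention_dominant")
  expect_true(is.na(dom$icur))
})

test_that("base-case pipeline produces a coherent incremental result", {
  fx <- base_fixture()
  res <- run_cea(fx$fits$models, fx$config, fx$life_table,
                 keep_traces = TRUE)
  # the intervention survival curves dominate, so it gains LYs and QALYs
  expect_gt(res$delta_ly, 0)
  expect_gt(res$delta_qaly, 0)
  expect_gt(res$delta_cost, 0)
  expect_equal(res$icur, res$delta_cost / res$delta_qaly)
  expect_gt(res$icur, res$icer) # QALYs < LYs since utilities < 1
  # traces conserve mass
  for (tr in res$traces) {
    expect_equal(tr$stable + tr$progressive + tr$dead,
                 rep(1, nrow(tr)), tolerance = 1e-12)
  }
  # deterministic: identical call, identical numbers
  res_again <- run_cea(fx$fits$models, fx$config, fx$life_table)
  expect_equal(glance(res_again), glance(res))
})

test_that("tornado: drug price is the widest bar, zero-range bars vanish", {
  fx <- base_fixture()
  tor <- one_way_dsa(fx$fits$models, fx$config, fx$life_table)
  expect_equal(tor$parameter[1], "mirv_drug_cost")
  expect_true(all(diff(tor$width) <= 1e-9))
  # a parameter the model ignores has a zero-width bar
  specs <- tibble::tibble(parameter = "monitoring_cost", low = 1, high = 1)
  flat <- one_way_dsa(fx$fits$models, fx$config, fx$life_table,
                      specs = specs)
  expect_equal(flat$width, 0)
  # utilities occupy ranks 2-4 on this fixture, behind the drug price
  expect_true(all(c("utility_stable", "utility_progressive") %in%
                    tor$parameter[2:4]))
  # finite-difference cross-check: widths are nonzero iff the model
  # responds to the parameter
  expect_true(all(tor$width[tor$parameter != "monitoring_cost"] >= 0))
})

test_that("bivariate utility grid: ICUR falls as intervention utilities rise", {
  fx <- base_fixture()
  grid <- bivariate_utility(fx$fits$models, fx$config, fx$life_table,
                            stable_utils = c(0.61, 0.732),
                            prog_utils = c(0.5, 0.6))
  base_row <- grid[grid$utility_stable == 0.61 &
                     grid$utility_progressive == 0.5, ]
  base <- run_cea(fx$fits$models, fx$config, fx$life_table)
  # identity scenario reproduces the base case
  expect_equal(base_row$icur, base$icur, tolerance = 1e-9)
  icur_at <- function(us, up) {
    grid$icur[grid$utility_stable == us & grid$utility_progressive == up]
  }
  expect_lt(icur_at(0.732, 0.6), icur_at(0.732, 0.5))
  expect_lt(icur_at(0.732, 0.5), icur_at(0.61, 0.5))
})

test_that("price threshold inverts the price-to-ICUR map", {
  fx <- base_fixture()
  base <- run_cea(fx$fits$models, fx$config, fx$life_table)
  wtp <- fx$config$thresholds$primary_wtp
  th <- price_threshold(fx$fits$models, fx$config, fx$life_table,
                        wtp = wtp)
  expect_lt(th$relative_error, 1e-4)
  expect_lt(th$price, fx$config$drugs$mirv_cost_per_cycle)
  # fixed point: WTP equal to the base ICUR returns the base price
  th_fp <- price_threshold(fx$fits$models, fx$config, fx$life_table,
                           wtp = base$icur,
                           bounds = c(0, 2 * fx$config$drugs$mirv_cost_per_cycle))
  expect_equal(th_fp$price, fx$config$drugs$mirv_cost_per_cycle,
               tolerance = 0.01)
  # halving the WTP lowers the threshold price
  th_half <- price_threshold(fx$fits$models, fx$config, fx$life_table,
                             wtp = wtp / 2)
  expect_lt(th_half$price, th$price)
  # closed-form oracle: delta cost is affine in price,
  # dcost(p) = a + b p with b the discounted stable exposure of the arm
  p1 <- 1000; p2 <- 2000
  d1 <- run_cea(fx$fits$models, fx$config, fx$life_table,
                mirv_drug_cost = p1)$delta_cost
  d2 <- run_cea(fx$fits$models, fx$config, fx$life_table,
                mirv_drug_cost = p2)$delta_cost
  b <- (d2 - d1) / (p2 - p1)
  a <- d1 - b * p1
  dq <- base$delta_qaly
  expect_equal(th$price, (wtp * dq - a) / b, tolerance = 0.01)
  # unbracketed thresholds are refused
  expect_error(price_threshold(fx$fits$models, fx$config, fx$life_table,
                               wtp = 1e12), "not bracketed")
})

test_that("horizon and discount scenarios behave monotonically", {
  fx <- base_fixture()
  sc <- scenario_settings(fx$fits$models, fx$config, fx$life_table,
                          horizon_years = c(5, 10),
                          discount = c(0, 0.03, 0.05))
  expect_equal(nrow(sc), 6)
  pick <- function(h, r) sc[sc$horizon_years == h & sc$discount == r, ]
  # no discounting yields at least as many QALYs as discounting
  expect_gte(pick(5, 0)$delta_qaly, pick(5, 0.03)$delta_qaly)
  expect_gte(pick(5, 0.03)$delta_qaly, pick(5, 0.05)$delta_qaly)
  # longer horizon accrues more incremental QALYs when the intervention
  # curves dominate
  expect_gte(pick(10, 0.03)$delta_qaly, pick(5, 0.03)$delta_qaly)
  # identical settings give identical results
  sc2 <- scenario_settings(fx$fits$models, fx$config, fx$life_table,
                           horizon_years = 5, discount = 0.03)
  expect_equal(sc2$icur, pick(5, 0.03)$icur)
})
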