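test_that("adverse-event amortization reproduces the cross-arm cost cells", {
  cfg <- default_config()
  entries <- cfg$adverse_events$entries
  anemia <- entries[entries$name == "anemia", ]
  neutro <- entries[entries$name == "neutropenia", ]
  # per-episode cost inferred from the intervention-arm cell ...
  expect_equal(ae_cost_per_cycle(anemia, "mirv"), 0.50, tolerance = 1e-9)
  expect_equal(ae_cost_per_cycle(neutro, "mirv"), 0.41, tolerance = 1e-9)
  # ... applied at the standard-arm incidence reproduces that arm's cell
  expect_equal(ae_cost_per_cycle(anemia, "standard"), 5.28, tolerance = 0.01)
  expect_equal(ae_cost_per_cycle(neutro, "standard"), 7.41, tolerance = 0.01)
  # zero incidence, zero cost
  zero <- anemia
  zero$incidence_mirv <- 0
  expect_equal(ae_cost_per_cycle(zero, "mirv"), 0)
})

test_that("chi-square gate matches the hand formula and handles degeneracy", {
  # oracle: Pearson chi-square from expected counts, no correction
  chisq_oracle <- function(a, b, na, nb) {
    o <- c(a, na - a, b, nb - b)
    n <- na + nb
    e <- c((a + b) * na / n, (n - a - b) * na / n,
           (a + b) * nb / n, (n - a - b) * nb / n)
    sum((o - e)^2 / e)
  }
  g <- ae_inclusion_gate(2, 21, 227, 226)
  expect_equal(g$statistic, chisq_oracle(2, 21, 227, 226), tolerance = 1e-9)
  expect_true(g$include)
  expect_lt(g$p_value, 0.05)
  # identical proportions: p ~ 1, excluded
  same <- ae_inclusion_gate(20, 20, 200, 200)
  expect_false(same$include)
  expect_gt(same$p_value, 0.9)
  # zero-margin tables are degenerate
  expect_warning(deg <- ae_inclusion_gate(0, 0, 227, 226), "degenerate")
  expect_false(deg$include)
})

test_that("gate monotonicity: more standard-arm events never drops an included AE", {
  base <- ae_inclusion_gate(2, 21, 227, 226)
  expect_true(base$include)
  for (k in 22:60) {
    expect_true(ae_inclusion_gate(2, k, 227, 226)$include)
  }
})

test_that("standard-arm drug cost: blended default and weighted alternative", {
  cfg <- default_config()
  expect_equal(standard_arm_drug_cost(cfg), 1276.83)
  weighted <- standard_arm_drug_cost(cfg, mode = "weighted")
  expect_equal(weighted, 0.41 * 519.77 + 0.23 * 299.43 + 0.36 * 457.63,
               tolerance = 1e-9)
  one <- cfg
  one$drugs$standard_components <- tibble::tibble(
    drug = "paclitaxel", cost_per_cycle = 519.77, proportion = 1)
  expect_equal(standard_arm_drug_cost(one, mode = "weighted"), 519.77)
  bad <- cfg
  bad$drugs$standard_components$proportion <- c(0.5, 0.2, 0.2)
  expect_error(standard_arm_drug_cost(bad, mode = "weighted"), "sum to 1")
})

test_that("per-cycle stable-state cost sums the configured components", {
  cfg <- default_config()
  # first cycle: drug + monitoring + imaging(early) + premedication + AEs
  expect_equal(cycle_cost(cfg, "mirv", 0),
               18231.66 + 96.96 + 141.12 + 82.06 + 0.50 + 0.41,
               tolerance = 1e-6)
  expect_equal(cycle_cost(cfg, "mirv", 0), 18552.71, tolerance = 1e-6)
  # the imaging step is the only cycle dependence
  expect_equal(cycle_cost(cfg, "mirv", 8) - cycle_cost(cfg, "mirv", 9),
               141.12 - 70.56, tolerance = 1e-9)
  expect_equal(cycle_cost(cfg, "standard", 0),
               1276.83 + 96.96 + 141.12 + 27.93 + 5.28 + 7.422,
               tolerance = 0.02)
  # non-increasing in cycle
  costs <- cycle_cost(cfg, "mirv", 0:64)
  expect_true(all(diff(costs) <= 0))
  # zeroed components give zero cost
  z <- cfg
  z$drugs$mirv_cost_per_cycle <- 0
  z$monitoring$per_cycle <- 0
  z$monitoring$imaging_early <- 0
  z$monitoring$imaging_late <- 0
  z$premedication$mirv <- 0
  z$adverse_events$entries$drg_cost <- c(1e-12, 1e-12)
  expect_equal(cycle_cost(z, "mirv", 0), 0, tolerance = 1e-9)
})

test_that("utilities decline linearly per cycle with a floor at zero", {
  cfg <- default_config()
  expect_equal(utility_at(cfg, "mirv", "stable", 0:64), rep(0.61, 65))
  expect_equal(utility_at(cfg, "mirv", "dead", 5), 0)
  dec <- cfg
  dec$utilities$decline_per_cycle <- c(mirv = 0.01, standard = 0.01)
  expect_equal(utility_at(dec, "mirv", "stable", 10), 0.51)
  expect_equal(utility_at(dec, "mirv", "progressive", 100), 0)
  slow <- cfg
  slow$utilities$decline_per_cycle <- c(mirv = 0.005, standard = 0.005)
  expect_equal(utility_at(slow, "standard", "stable", 10), 0.56)
})

test_that("arm accrual functions agree with the tabular helpers", {
  cfg <- default_config()
  econ <- arm_econ_functions(cfg, "mirv")
  for (cyc in c(0, 5, 9, 30)) {
    expect_equal(econ$cost("stable", cyc), cycle_cost(cfg, "mirv", cyc))
    expect_equal(econ$utility("stable", cyc),
                 utility_at(cfg, "mirv", "stable", cyc))
  }
  expect_equal(econ$cost("progressive", 3), 0)
  expect_equal(econ$utility("dead", 3), 0)
})
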