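# Shared fixtures and independent oracles.

# noise-free digitized curve from a truth model on a monthly grid
truth_points <- function(model, t = 0:24) {
  tibble::tibble(time_months = t, survival = surv_prob(model, t))
}

# one truth model per family, in the data regime of the synthetic trial
family_truths <- function() {
  list(
    exponential = surv_model("exponential", c(rate = log(2) / 3.98)),
    weibull = surv_model("weibull",
                         c(shape = 1.2, scale = 3.98 / log(2)^(1 / 1.2))),
    gompertz = surv_model("gompertz", c(shape = 0.15, rate = 0.1)),
    loglogistic = surv_model("loglogistic", c(shape = 1.5, scale = 5.62)),
    lognormal = surv_model("lognormal",
                           c(meanlog = log(5.62), sdlog = 0.8))
  )
}

# Path-enumeration oracle for the cohort engine: walks every state path of
# the three-state chain, accumulating path probability, start-of-cycle
# occupancy and discounted accruals. Exponential in the horizon; use only
# for short instances. Independent of the matrix recursion in run_cohort.
enumerate_cohort <- function(schedule, cost_fun, utility_fun, settings) {
  n <- nrow(schedule)
  states <- c("stable", "progressive", "dead")
  acc <- new.env()
  acc$occ <- matrix(0, n, 3, dimnames = list(NULL, states))
  acc$cost <- 0; acc$ly <- 0; acc$qaly <- 0
  yrs <- settings$cycle_days / 365.25
  recurse <- function(state, cycle, prob) {
    if (prob == 0 || cycle > n) return(invisible())
    i <- match(state, states)
    acc$occ[cycle, i] <- acc$occ[cycle, i] + prob
    df <- discount_factor(cycle - 1, settings)
    if (state != "dead") {
      acc$cost <- acc$cost + prob * cost_fun(state, cycle - 1) * df
      acc$ly <- acc$ly + prob * yrs * df
      acc$qaly <- acc$qaly + prob * utility_fun(state, cycle - 1) * yrs * df
    }
    if (cycle == n) return(invisible())
    psp <- schedule$p_sp[cycle]; psd <- schedule$p_sd[cycle]
    ppd <- schedule$p_pd[cycle]
    if (state == "stable") {
      recurse("stable", cycle + 1, prob * (1 - psp - psd))
      recurse("progressive", cycle + 1, prob * psp)
      recurse("dead", cycle + 1, prob * psd)
    } else if (state == "progressive") {
      recurse("progressive", cycle + 1, prob * (1 - ppd))
      recurse("dead", cycle + 1, prob * ppd)
    } else {
      recurse("dead", cycle + 1, prob)
    }
  }
  recurse("stable", 1, 1)
  list(occ = acc$occ, cost = acc$cost, ly = acc$ly, qaly = acc$qaly)
}

# a random, valid short transition schedule
random_schedule <- function(n_cycles, seed, arm = "arm") {
  set.seed(seed)
  psd <- runif(n_cycles, 0, 0.2)
  psp <- runif(n_cycles, 0, 1 - psd)
  tibble::tibble(arm = arm, cycle = 0:(n_cycles - 1),
                 time_months = (0:(n_cycles - 1)) * 28 / 30.4375,
                 p_sp = psp, p_sd = psd,
                 p_pd = runif(n_cycles, 0, 1))
}

# noise-free default fixture shared across analysis tests (computed once)
fixture_env <- new.env()
base_fixture <- function() {
  if (is.null(fixture_env$fx)) {
    curves <- generate_km_curves(synthetic_trial_spec())
    fits <- fit_trial_curves(curves)
    fixture_env$fx <- list(
      curves = curves, fits = fits,
      life_table = generate_life_table(),
      config = default_config()
    )
  }
  fixture_env$fx
}
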