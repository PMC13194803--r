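#' Probabilistic sampling distributions
#'
#' Parameter uncertainty follows the conventional distributional choices
#' for health-economic models: gamma for costs (positive, right-skewed),
#' beta for utilities (bounded in (0, 1)), and lognormal multiplicative
#' factors for the per-cycle transition probabilities, whose fitted
#' survival parameters carry no published standard errors.
#'
#' `sample_cost()` moment-matches a gamma: shape `mean^2/sd^2`, scale
#' `sd^2/mean`. `sample_utility()` derives `sd = ci_halfwidth / 1.96`
#' (treating the half-width as a 95% interval) and moment-matches a beta:
#' `alpha = mean (mean(1-mean)/sd^2 - 1)`, `beta = (1-mean) (...)`.
#' `sample_transition_multiplier()` draws lognormal with meanlog 0, so
#' the median multiplier is 1 and `sdlog = 0.10` corresponds to roughly
#' +-20% variation at the 95% level.
#'
#' @param n Number of draws.
#' @param mean Mean (euro for costs; utility in (0, 1)).
#' @param sd Standard deviation (euro), > 0.
#' @return Numeric vector of draws.
#' @name psa_sampling
#' @export
sample_cost <- function(n, mean, sd) {
  stopifnot(mean > 0, sd > 0)
  stats::rgamma(n, shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' @rdname psa_sampling
#' @param ci_halfwidth Half-width of the 95% interval around the mean.
#' @export
sample_utility <- function(n, mean, ci_halfwidth) {
  stopifnot(mean > 0, mean < 1, ci_halfwidth > 0)
  sd <- ci_halfwidth / 1.96
  if (sd^2 >= mean * (1 - mean)) {
    stop("infeasible beta moments: sd^2 must be < mean(1-mean)",
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  stats::rbeta(n, shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' @rdname psa_sampling
#' @param sdlog Standard deviation of logs, > 0 (meanlog fixed at 0).
#' @export
sample_transition_multiplier <- function(n, sdlog) {
  stopifnot(sdlog > 0)
  stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

# deterministic per-parameter substream seed: adding a parameter must not
# reshuffle the draws of the others
substream_seed <- function(master, index) {
  (as.integer(master) + 7919L * as.integer(index)) %% 2147483629L
}

#' First-order Monte Carlo probabilistic sensitivity analysis
#'
#' For each iteration, draws every uncertain parameter from its
#' distribution — gamma costs (spreads taken from the deterministic
#' ranges re-expressed as 95% intervals), beta utilities, and two
#' lognormal transition multipliers (one applied to the per-cycle death
#' probabilities, one to the progression probabilities, each sampled once
#' per iteration and shared across cycles and arms, products clipped to
#' \[0, 1\]) — reruns the deterministic pipeline, and records the
#' incremental cost and QALYs.
#'
#' The headline summary is the mean of the per-iteration ICURs with a
#' normal-approximation 95% CI of that mean, computed over iterations
#' with positive incremental QALYs (non-positive ones are counted and
#' reported separately); the ratio of means — the economically standard
#' summary — is reported alongside. The cost-effectiveness acceptability
#' curve is the fraction of all iterations with positive net monetary
#' benefit at each willingness-to-pay value.
#'
#' Each parameter draws from its own deterministically derived substream
#' of the master seed, so runs are reproducible and adding a parameter
#' does not reshuffle the others.
#'
#' @inheritParams run_cea
#' @param n_iterations Number of Monte Carlo iterations.
#' @param seed Master RNG seed.
#' @return An object of class `psa_result`: list with `draws` (tibble
#'   `iter`, `delta_cost`, `delta_qaly`, `icur`), `ceac` (tibble `wtp`,
#'   `prob_ce`), `mean_icur`, `ci_low`, `ci_high`, `icur_ratio_of_means`,
#'   `n_nonpositive_dqaly`, `n_iterations`, `seed`.
#' @export
run_psa <- function(models, config = default_config(), life_table = NULL,
                    settings = NULL,
                    n_iterations = config$psa$n_iterations, seed = 1L) {
  n <- as.integer(n_iterations)
  stopifnot(n >= 1)
  dsa <- config$dsa
  u <- config$utilities
  hw_frac <- config$psa$utility_ci_halfwidth_frac
  ae_means <- config$adverse_events$entries$drg_cost

  draw <- function(index, fn, ...) {
    with_seed(substream_seed(seed, index), fn(n, ...))
  }
  sd_of <- function(mean, mult) mult * mean / 1.96
  draws <- list(
    mirv_drug = draw(1, sample_cost, config$drugs$mirv_cost_per_cycle,
                     sd_of(config$drugs$mirv_cost_per_cycle,
                           dsa$drug_multiplier)),
    standard_drug = draw(2, sample_cost, standard_arm_drug_cost(config),
                         sd_of(standard_arm_drug_cost(config),
                               dsa$drug_multiplier)),
    monitoring = draw(3, sample_cost, config$monitoring$per_cycle,
                      sd_of(config$monitoring$per_cycle,
                            dsa$monitoring_multiplier)),
    u_stable = draw(4, sample_utility, u$stable, hw_frac * u$stable),
    u_prog = draw(5, sample_utility, u$progressive,
                  hw_frac * u$progressive),
    mult_mortality = draw(6, sample_transition_multiplier,
                          config$psa$transition_sdlog),
    mult_progression = draw(7, sample_transition_multiplier,
                            config$psa$transition_sdlog)
  )
  draws$ae <- purrr::map(seq_along(ae_means), function(j) {
    draw(7 + j, sample_cost, ae_means[j], sd_of(ae_means[j],
                                                dsa$ae_multiplier))
  })

  results <- purrr::map_dfr(seq_len(n), function(i) {
    cfg <- config
    cfg$drugs$mirv_cost_per_cycle <- draws$mirv_drug[i]
    cfg$drugs$standard_blended_cost <- draws$standard_drug[i]
    cfg$drugs$standard_mode <- "blended"
    cfg$monitoring$per_cycle <- draws$monitoring[i]
    cfg$utilities$stable <- draws$u_stable[i]
    cfg$utilities$progressive <- min(draws$u_prog[i], draws$u_stable[i])
    cfg$adverse_events$entries$drg_cost <-
      vapply(draws$ae, `[`, numeric(1), i)
    mm <- draws$mult_mortality[i]
    mp <- draws$mult_progression[i]
    modifier <- function(sched, arm) {
      sched$p_sp <- pmin(pmax(sched$p_sp * mp, 0), 1)
      sched$p_sd <- pmin(pmax(sched$p_sd * mm, 0), 1)
      sched$p_pd <- pmin(pmax(sched$p_pd * mm, 0), 1)
      over <- sched$p_sp + sched$p_sd > 1
      sched$p_sp[over] <- 1 - sched$p_sd[over]
      sched
    }
    res <- run_cea(models, cfg, life_table, settings,
                   schedule_modifier = modifier)
    tibble::tibble(iter = i, delta_cost = res$delta_cost,
                   delta_qaly = res$delta_qaly)
  })
  results$icur <- ifelse(results$delta_qaly > 0,
                         results$delta_cost / results$delta_qaly, NA_real_)

  ok <- !is.na(results$icur)
  icurs <- results$icur[ok]
  mean_icur <- mean(icurs)
  se <- stats::sd(icurs) / sqrt(length(icurs))
  wtp <- config$thresholds$wtp_grid
  ceac <- tibble::tibble(
    wtp = wtp,
    prob_ce = vapply(wtp, function(w) {
      mean(w * results$delta_qaly - results$delta_cost > 0)
    }, numeric(1))
  )
  structure(list(
    draws = results, ceac = ceac,
    mean_icur = mean_icur,
    ci_low = mean_icur - 1.96 * se, ci_high = mean_icur + 1.96 * se,
    icur_ratio_of_means = sum(results$delta_cost) /
      sum(results$delta_qaly),
    n_nonpositive_dqaly = sum(!ok), n_iterations = n, seed = seed
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$n_iterations, " iterations (seed ", x$seed, ")\n",
      sep = "")
  cat(sprintf("  mean ICUR %.0f (95%% CI %.0f to %.0f) /QALY\n",
              x$mean_icur, x$ci_low, x$ci_high))
  cat(sprintf("  ratio of means %.0f; %d iteration(s) with dQALY <= 0\n",
              x$icur_ratio_of_means, x$n_nonpositive_dqaly))
  print(x$ceac)
  invisible(x)
}

#' @rdname run_psa
#' @param x A `psa_result`.
#' @param ... Unused.
#' @method tidy psa_result
#' @export
tidy.psa_result <- function(x, ...) x$draws

#' @rdname run_psa
#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ...) {
  tibble::tibble(mean_icur = x$mean_icur, ci_low = x$ci_low,
                 ci_high = x$ci_high,
                 icur_ratio_of_means = x$icur_ratio_of_means,
                 n_nonpositive_dqaly = x$n_nonpositive_dqaly,
                 n_iterations = x$n_iterations)
}
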