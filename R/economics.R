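#' Amortized per-cycle cost of an adverse event
#'
#' Grade >= 3 adverse events enter the model as their cumulative trial
#' incidence times the per-episode inpatient (DRG) cost, spread evenly
#' over the amortization window: `incidence * drg_cost /
#' amortization_months`. Months are treated as model cycles (a four-week
#' cycle approximates a month over the 60-month window).
#'
#' @param entry One row of the adverse-event table (fields
#'   `incidence_mirv`, `incidence_standard`, `drg_cost`).
#' @param arm `"mirv"` or `"standard"`.
#' @param amortization_months Amortization window (default 60).
#' @return Euro per cycle.
#' @export
ae_cost_per_cycle <- function(entry, arm = c("mirv", "standard"),
                              amortization_months = 60) {
  arm <- match.arg(arm)
  stopifnot(amortization_months > 0)
  inc <- if (arm == "mirv") entry$incidence_mirv else entry$incidence_standard
  inc * entry$drg_cost / amortization_months
}

#' Chi-square inclusion gate for an adverse event
#'
#' Pearson chi-square (no continuity correction) on the 2x2
#' event/no-event by arm table; the event contributes cost only when the
#' between-arm difference is significant at p < 0.05. Degenerate tables
#' (a zero margin) are excluded with a warning.
#'
#' @param count_mirv,count_standard Event counts per arm.
#' @param n_mirv,n_standard Arm sizes (defaults 227 and 226).
#' @return A one-row tibble: `include`, `statistic`, `p_value`.
#' @export
ae_inclusion_gate <- function(count_mirv, count_standard,
                              n_mirv = 227, n_standard = 226) {
  stopifnot(count_mirv <= n_mirv, count_standard <= n_standard)
  tab <- matrix(c(count_mirv, n_mirv - count_mirv,
                  count_standard, n_standard - count_standard),
                nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    warning("degenerate 2x2 table; adverse event excluded", call. = FALSE)
    return(tibble::tibble(include = FALSE, statistic = NA_real_,
                          p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(include = ct$p.value < 0.05,
                 statistic = unname(ct$statistic),
                 p_value = ct$p.value)
}

#' Per-cycle drug cost of the standard-chemotherapy arm
#'
#' `blended` mode returns the single configured average therapy expense
#' per treatment interval (1,276.83 euro in the base case); `weighted`
#' mode returns the proportion-weighted sum of the per-drug monthly
#' costs. The two published figures do not reconcile (the weighted sum of
#' the printed per-drug costs is about 447 euro); both modes are exposed
#' and `blended` is the base-case default.
#'
#' @param config A `mirvcea_config`.
#' @param mode Override for `config$drugs$standard_mode`.
#' @return Euro per cycle.
#' @export
standard_arm_drug_cost <- function(config, mode = NULL) {
  mode <- mode %||% config$drugs$standard_mode
  mode <- match.arg(mode, c("blended", "weighted"))
  if (mode == "blended") return(config$drugs$standard_blended_cost)
  comp <- config$drugs$standard_components
  if (abs(sum(comp$proportion) - 1) > 1e-9) {
    stop("standard-arm proportions must sum to 1", call. = FALSE)
  }
  sum(comp$proportion * comp$cost_per_cycle)
}

#' Included adverse events and their per-cycle costs
#'
#' Applies the chi-square gate to every configured adverse event and
#' returns the gated table with per-arm per-cycle costs.
#'
#' @param config A `mirvcea_config`.
#' @return Tibble: `name`, `include`, `statistic`, `p_value`,
#'   `cost_mirv`, `cost_standard` (euro per cycle; zero when excluded).
#' @export
ae_cost_table <- function(config) {
  ae <- config$adverse_events
  sizes <- config$model$arm_sizes
  purrr::map_dfr(seq_len(nrow(ae$entries)), function(i) {
    e <- ae$entries[i, ]
    gate <- ae_inclusion_gate(e$count_mirv, e$count_standard,
                              sizes[["mirv"]], sizes[["standard"]])
    dplyr::mutate(
      gate,
      name = e$name, .before = 1,
      cost_mirv = ifelse(gate$include,
                         ae_cost_per_cycle(e, "mirv", ae$amortization_months),
                         0),
      cost_standard = ifelse(
        gate$include,
        ae_cost_per_cycle(e, "standard", ae$amortization_months), 0)
    )
  })
}

#' Per-cycle stable-state cost for an arm
#'
#' Drug + monitoring + premedication + included adverse-event
#' amortization + imaging, where imaging costs 141.12 euro in cycles 1-9
#' and 70.56 euro from cycle 10 onward (1-based cycle numbering for the
#' imaging switch). Treatment runs until progression, so all treatment
#' components accrue in the stable state only; the progressive state
#' accrues no modelled cost.
#'
#' @param config A `mirvcea_config`.
#' @param arm `"mirv"` or `"standard"`.
#' @param cycle 0-based cycle index (vectorised).
#' @param drug_cost Optional override of the arm's per-cycle drug cost
#'   (used by the price-threshold search).
#' @return Euro per cycle (vector).
#' @export
cycle_cost <- function(config, arm = c("mirv", "standard"), cycle,
                       drug_cost = NULL) {
  arm <- match.arg(arm)
  stopifnot(all(cycle >= 0))
  if (is.null(drug_cost)) {
    drug_cost <- if (arm == "mirv") {
      config$drugs$mirv_cost_per_cycle
    } else {
      standard_arm_drug_cost(config)
    }
  }
  premed <- config$premedication[[arm]]
  aes <- ae_cost_table(config)
  ae_cost <- sum(aes[[paste0("cost_", arm)]])
  mon <- config$monitoring
  cycle1 <- cycle + 1 # imaging schedule is stated in 1-based cycles
  imaging <- ifelse(cycle1 <= mon$imaging_switch_cycle,
                    mon$imaging_early, mon$imaging_late)
  drug_cost + mon$per_cycle + premed + ae_cost + imaging
}

#' Health-state utility at a cycle
#'
#' Base utilities 0.61 (stable) and 0.5 (progressive), optionally
#' declining linearly per cycle (per arm), floored at 0. Dead has
#' utility 0.
#'
#' @param config A `mirvcea_config`.
#' @param arm `"mirv"` or `"standard"`.
#' @param state `"stable"`, `"progressive"` or `"dead"`.
#' @param cycle 0-based cycle index (vectorised).
#' @return Utility value(s) in \[0, 1\].
#' @export
utility_at <- function(config, arm = c("mirv", "standard"),
                       state = c("stable", "progressive", "dead"), cycle) {
  arm <- match.arg(arm)
  state <- match.arg(state)
  if (state == "dead") return(rep(0, length(cycle)))
  base <- config$utilities[[state]]
  decline <- config$utilities$decline_per_cycle[[arm]]
  pmax(base - decline * cycle, 0)
}

#' Per-cycle cost and utility functions for an arm
#'
#' Builds the `(state, cycle)` accrual functions that [run_cohort()]
#' expects, with the adverse-event gate evaluated once.
#'
#' @inheritParams cycle_cost
#' @return List with functions `cost` and `utility`.
#' @export
arm_econ_functions <- function(config, arm = c("mirv", "standard"),
                               drug_cost = NULL) {
  arm <- match.arg(arm)
  if (is.null(drug_cost)) {
    drug_cost <- if (arm == "mirv") {
      config$drugs$mirv_cost_per_cycle
    } else {
      standard_arm_drug_cost(config)
    }
  }
  premed <- config$premedication[[arm]]
  ae_cost <- sum(ae_cost_table(config)[[paste0("cost_", arm)]])
  mon <- config$monitoring
  base_u <- config$utilities
  decline <- config$utilities$decline_per_cycle[[arm]]
  list(
    cost = function(state, cycle) {
      if (state != "stable") return(0)
      imaging <- if (cycle + 1 <= mon$imaging_switch_cycle) {
        mon$imaging_early
      } else {
        mon$imaging_late
      }
      drug_cost + mon$per_cycle + premed + ae_cost + imaging
    },
    utility = function(state, cycle) {
      if (state == "dead") return(0)
      max(base_u[[state]] - decline * cycle, 0)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
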