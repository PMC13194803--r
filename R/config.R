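#' Base-case model configuration
#'
#' Returns the full configuration of the base-case evaluation: all euro
#' amounts per 28-day cycle from the payer (German statutory health
#' insurance) perspective, health-state utilities, discounting, the model
#' horizon, deterministic sensitivity ranges, probabilistic sensitivity
#' distribution settings and the willingness-to-pay grid (multiples of
#' German GDP per capita).
#'
#' Sections:
#' * `model`: `cycle_days` (28), `horizon_years` (5), `horizon_cycles` (65,
#'   i.e. `floor(5 * 365.25 / 28)`), `annual_discount_rate` (0.03),
#'   `start_age` (64), `half_cycle_correction` (FALSE).
#' * `drugs`: `mirv_cost_per_cycle` (18,231.66; the alternative published
#'   figure 18,281.66 is carried as `mirv_cost_per_cycle_alt`),
#'   `standard_mode` (`"blended"`), `standard_blended_cost` (1,276.83) and
#'   the per-drug table (paclitaxel 519.77 at proportion 0.41, topotecan
#'   299.43 at 0.23, pegylated liposomal doxorubicin 457.63 at 0.36).
#' * `monitoring`: `per_cycle` (96.96), `imaging_early` (141.12, cycles
#'   1-9), `imaging_late` (70.56, cycle 10 onward).
#' * `premedication`: `mirv` (82.06), `standard` (27.93).
#' * `adverse_events`: grade >= 3 events with cumulative incidences, event
#'   counts for the chi-square inclusion gate, inpatient episode cost
#'   (DRG tariff) and the 60-month amortisation window.
#' * `utilities`: `stable` (0.61), `progressive` (0.5), per-arm per-cycle
#'   declines (0 in the base case; 0.005 / 0.01 in the decline scenarios).
#' * `dsa`: variation multipliers (drug +-50%, adverse events +-25%,
#'   monitoring +-25%, utilities +-20%).
#' * `psa`: `n_iterations` (10,000), lognormal transition-multiplier
#'   `sdlog` (0.10, meanlog 0).
#' * `thresholds`: `gdp_per_capita` (51,833), WTP grid
#'   {151,833; 155,499; 310,998; 466,497} with 155,499 (3x GDP per capita)
#'   as the primary benchmark.
#'
#' @return A nested named list with class `mirvcea_config`.
#' @export
default_config <- function() {
  cfg <- list(
    model = list(
      cycle_days = 28,
      horizon_years = 5,
      horizon_cycles = 65L,
      annual_discount_rate = 0.03,
      start_age = 64,
      half_cycle_correction = FALSE,
      arm_sizes = c(mirv = 227L, standard = 226L)
    ),
    drugs = list(
      mirv_cost_per_cycle = 18231.66,
      mirv_cost_per_cycle_alt = 18281.66,
      mirv_price_per_mg = 30.39,
      standard_mode = "blended",
      standard_blended_cost = 1276.83,
      standard_components = tibble::tibble(
        drug = c("paclitaxel", "topotecan", "pld"),
        cost_per_cycle = c(519.77, 299.43, 457.63),
        proportion = c(0.41, 0.23, 0.36)
      )
    ),
    monitoring = list(
      per_cycle = 96.96,
      imaging_early = 141.12,
      imaging_late = 70.56,
      imaging_switch_cycle = 9L
    ),
    premedication = list(mirv = 82.06, standard = 27.93),
    adverse_events = list(
      amortization_months = 60,
      entries = tibble::tibble(
        name = c("anemia", "neutropenia"),
        incidence_mirv = c(0.0088, 0.0088),
        incidence_standard = c(0.0929, 0.1593),
        count_mirv = c(2L, 2L),
        count_standard = c(21L, 36L),
        # per-episode inpatient cost implied by the per-cycle cells at the
        # stated incidences over the 60-month window
        drg_cost = c(0.50 * 60 / 0.0088, 0.41 * 60 / 0.0088)
      )
    ),
    utilities = list(
      stable = 0.61,
      progressive = 0.5,
      decline_per_cycle = c(mirv = 0, standard = 0)
    ),
    dsa = list(
      drug_multiplier = 0.50,
      ae_multiplier = 0.25,
      monitoring_multiplier = 0.25,
      utility_multiplier = 0.20
    ),
    psa = list(
      n_iterations = 10000L,
      transition_sdlog = 0.10,
      # spreads are not published: DSA ranges re-expressed as sds,
      # treating the +-x% variation as a 95% interval
      cost_sd_from_range = TRUE,
      utility_ci_halfwidth_frac = 0.20
    ),
    thresholds = list(
      gdp_per_capita = 51833,
      wtp_grid = c(151833, 155499, 310998, 466497),
      primary_wtp = 155499
    )
  )
  class(cfg) <- c("mirvcea_config", "list")
  cfg
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, overlays it on [default_config()] (absent
#' keys keep their defaults) and validates the result. Validation errors
#' name the offending key and the violated constraint. An empty file yields
#' the full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated `mirvcea_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      bad <- setdiff(names(user), names(cfg))
      if (length(bad)) {
        stop("unknown config section(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      for (sec in names(user)) {
        leaf <- user[[sec]]
        bad_key <- setdiff(names(leaf), names(cfg[[sec]]))
        if (length(bad_key)) {
          stop("unknown key(s) in section '", sec, "': ",
               paste(bad_key, collapse = ", "), call. = FALSE)
        }
        for (k in names(leaf)) {
          v <- leaf[[k]]
          tmpl <- cfg[[sec]][[k]]
          if (is.data.frame(tmpl)) v <- tibble::as_tibble(as.data.frame(v))
          if (!is.null(names(tmpl)) && !is.list(tmpl) && !is.data.frame(tmpl)) {
            v <- unlist(v)
            if (is.null(names(v))) names(v) <- names(tmpl)
          }
          cfg[[sec]][[k]] <- v
        }
      }
    }
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @param config A configuration list to validate.
#' @export
validate_config <- function(config) {
  fail <- function(key, constraint) {
    stop("invalid config: '", key, "' must ", constraint, call. = FALSE)
  }
  chk_pos <- function(x, key, strict = TRUE) {
    if (!is.numeric(x) || any(if (strict) x <= 0 else x < 0)) {
      fail(key, if (strict) "be > 0" else "be >= 0")
    }
  }
  chk_unit <- function(x, key) {
    if (!is.numeric(x) || any(x < 0 | x > 1)) fail(key, "lie in [0, 1]")
  }

  m <- config$model
  chk_pos(m$cycle_days, "model.cycle_days")
  chk_pos(m$horizon_cycles, "model.horizon_cycles")
  chk_pos(m$annual_discount_rate, "model.annual_discount_rate", strict = FALSE)

  d <- config$drugs
  chk_pos(d$mirv_cost_per_cycle, "drugs.mirv_cost_per_cycle", strict = FALSE)
  if (!d$standard_mode %in% c("blended", "weighted")) {
    fail("drugs.standard_mode", "be 'blended' or 'weighted'")
  }
  comp <- d$standard_components
  chk_pos(comp$cost_per_cycle, "drugs.standard_components.cost_per_cycle",
          strict = FALSE)
  if (abs(sum(comp$proportion) - 1) > 1e-9) {
    fail("drugs.standard_components.proportion", "sum to 1 (+-1e-9)")
  }

  chk_pos(config$monitoring$per_cycle, "monitoring.per_cycle", strict = FALSE)
  chk_pos(config$premedication$mirv, "premedication.mirv", strict = FALSE)

  ae <- config$adverse_events
  chk_pos(ae$amortization_months, "adverse_events.amortization_months")
  chk_unit(ae$entries$incidence_mirv, "adverse_events.entries.incidence_mirv")
  chk_unit(ae$entries$incidence_standard,
           "adverse_events.entries.incidence_standard")

  u <- config$utilities
  chk_unit(u$stable, "utilities.stable")
  chk_unit(u$progressive, "utilities.progressive")
  chk_pos(u$decline_per_cycle, "utilities.decline_per_cycle", strict = FALSE)

  chk_pos(config$psa$n_iterations, "psa.n_iterations")
  chk_pos(config$psa$transition_sdlog, "psa.transition_sdlog")

  th <- config$thresholds
  chk_pos(th$wtp_grid, "thresholds.wtp_grid")
  if (is.unsorted(th$wtp_grid)) fail("thresholds.wtp_grid", "be increasing")

  class(config) <- c("mirvcea_config", "list")
  config
}
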