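#' Constant per-cycle event probability from a survivor fraction
#'
#' Converts the proportion `y` of a cohort surviving `t` cycles into the
#' constant per-cycle event probability consistent with it:
#' \eqn{P = 1 - y^{1/t} = 1 - e^{\ln(y)/t}}.
#'
#' @param y Survivor proportion over the interval, in (0, 1\]; `y = 0`
#'   returns 1.
#' @param t Interval length in cycles (> 0).
#' @return Per-cycle event probability.
#' @examples
#' interval_prob_from_survivor_fraction(0.25, 2) # 0.5
#' @export
interval_prob_from_survivor_fraction <- function(y, t) {
  stopifnot(t > 0)
  if (any(y > 1)) stop("survivor fraction cannot exceed 1", call. = FALSE)
  if (any(y < 0)) stop("survivor fraction cannot be negative", call. = FALSE)
  ifelse(y == 0, 1, 1 - y^(1 / t))
}

#' Convert an annual death probability to a per-cycle probability
#'
#' `1 - (1 - annual_prob)^(cycle_days / 365.25)`.
#'
#' @param annual_prob Annual probability in \[0, 1).
#' @param cycle_days Cycle length in days (default 28).
#' @return Per-cycle probability.
#' @export
annual_to_cycle_mortality <- function(annual_prob, cycle_days = 28) {
  stopifnot(all(annual_prob >= 0), all(annual_prob < 1))
  1 - (1 - annual_prob)^(cycle_days / 365.25)
}

# days per month used to place 28-day cycles on the monthly time axis
MONTH_DAYS <- 30.4375

#' Per-cycle background mortality from a life table
#'
#' Looks up the annual death probability at the attained age for each
#' cycle (starting age plus elapsed model time) and converts it to a
#' per-cycle probability. Ages beyond the life table carry the last row
#' forward.
#'
#' @param life_table Tibble with columns `age`, `annual_death_prob`.
#' @param horizon_cycles Number of cycles.
#' @param start_age Age (years) at model start.
#' @param cycle_days Cycle length in days.
#' @return Numeric vector of per-cycle death probabilities, one per cycle.
#' @export
background_mortality <- function(life_table, horizon_cycles, start_age = 64,
                                 cycle_days = 28) {
  stopifnot(all(diff(life_table$age) > 0),
            all(life_table$annual_death_prob >= 0),
            all(life_table$annual_death_prob <= 1))
  cycles <- seq_len(horizon_cycles) - 1L
  attained <- floor(start_age + cycles * cycle_days / 365.25)
  idx <- findInterval(attained, life_table$age)
  idx[idx < 1] <- 1L
  annual <- life_table$annual_death_prob[idx]
  annual <- pmin(annual, 1 - 1e-12)
  annual_to_cycle_mortality(annual, cycle_days)
}

#' Build the per-cycle transition schedule for one arm
#'
#' Decomposes the fitted progression-free-survival and overall-survival
#' curves into per-cycle transition probabilities for the three-state
#' (stable, progressive, dead) model on the cycle grid
#' \eqn{t_c = c \cdot 28 / 30.4375} months:
#'
#' * Progressive-state death is solved so that the implied alive fraction
#'   reproduces `S_OS(t_{c+1})` exactly (the difference of the two cohort
#'   curves), clipped to \[0, 1\]. The OS-matching probability already
#'   embeds all-cause death, so background mortality is not added again in
#'   the progressive state.
#' * Stable-state death takes the background (all-cause) mortality for the
#'   cycle, plus any OS-implied deaths the progressive compartment cannot
#'   absorb — notably in the earliest cycles, when it is still (nearly)
#'   empty but the OS curve already declines. The two published cohort
#'   curves cannot separate pre- from post-progression death, so this
#'   attribution errs toward progression-free mortality, and the cohort
#'   trace reconstructs both curves exactly when background mortality is
#'   zero.
#' * Stable-to-progressive is what remains of the PFS hazard after
#'   stable-state death: `max(0, 1 - S_PFS(t_{c+1}) / S_PFS(t_c) - p_sd)`.
#'
#' `S_OS` is clipped to `max(S_OS, S_PFS)` before the decomposition; the
#' number of clipped grid points and of clipped probabilities is recorded
#' in the `clip_events` attribute.
#'
#' @param pfs_model,os_model Fitted [surv_model()]s for the arm.
#' @param bg Per-cycle background mortality vector (length
#'   `horizon_cycles`), e.g. from [background_mortality()]; scalar 0 for
#'   none.
#' @param horizon_cycles Number of cycles (default 65, i.e. 5 years of
#'   28-day cycles).
#' @param cycle_days Cycle length in days.
#' @param arm Arm label carried into the output.
#' @return A tibble of class `transition_schedule` with columns `arm`,
#'   `cycle` (0-based), `time_months`, `p_sp` (stable to progressive),
#'   `p_sd` (stable to dead), `p_pd` (progressive to dead).
#' @export
build_schedule <- function(pfs_model, os_model, bg = 0, horizon_cycles = 65,
                           cycle_days = 28, arm = "arm") {
  stopifnot(horizon_cycles >= 1)
  if (length(bg) == 1) bg <- rep(bg, horizon_cycles)
  stopifnot(length(bg) == horizon_cycles, all(bg >= 0), all(bg <= 1))

  t_grid <- (0:horizon_cycles) * cycle_days / MONTH_DAYS
  s_pfs <- surv_prob(pfs_model, t_grid)
  s_os <- surv_prob(os_model, t_grid)
  clip_os <- sum(s_os < s_pfs)
  s_os <- pmax(s_os, s_pfs)

  n_clip_p <- 0L
  p_sp <- p_sd <- p_pd <- numeric(horizon_cycles)
  for (c in seq_len(horizon_cycles)) {
    stable <- s_pfs[c]
    prog <- s_os[c] - s_pfs[c]
    deaths <- s_os[c] - s_os[c + 1] # OS-implied deaths this cycle
    psd <- bg[c]
    # deaths the progressive compartment must supply beyond natural
    # mortality in the stable state
    need_pd <- deaths - stable * bg[c]
    if (prog <= 1e-15) {
      ppd <- 0
      spill <- need_pd
    } else {
      ppd <- need_pd / prog
      spill <- max(need_pd - prog, 0)
      if (ppd < 0 || ppd > 1) n_clip_p <- n_clip_p + 1L
      ppd <- min(max(ppd, 0), 1)
    }
    # the progressive pool cannot absorb all OS-implied deaths (notably
    # at early cycles when it is still empty): the remainder is carried
    # by the stable state, so the cohort trace reproduces S_OS exactly
    if (spill > 0 && stable > 0) psd <- psd + spill / stable
    if (psd > 1) {
      n_clip_p <- n_clip_p + 1L
      psd <- 1
    }
    if (stable <= 0) {
      psp <- if (s_pfs[c + 1] > 0) 1 else 0
    } else {
      psp <- 1 - s_pfs[c + 1] / stable - psd
    }
    if (psp < 0 || psp > 1) n_clip_p <- n_clip_p + 1L
    psp <- min(max(psp, 0), 1)
    if (psp + psd > 1) {
      n_clip_p <- n_clip_p + 1L
      psp <- 1 - psd
    }
    p_sp[c] <- psp
    p_sd[c] <- psd
    p_pd[c] <- ppd
  }
  out <- tibble::tibble(
    arm = arm, cycle = 0:(horizon_cycles - 1),
    time_months = t_grid[seq_len(horizon_cycles)],
    p_sp = p_sp, p_sd = p_sd, p_pd = p_pd
  )
  class(out) <- c("transition_schedule", class(out))
  attr(out, "clip_events") <- c(os_below_pfs = clip_os,
                                probabilities = n_clip_p)
  if (clip_os + n_clip_p > 0) {
    message("build_schedule [", arm, "]: clipped ", clip_os,
            " OS<PFS grid point(s), ", n_clip_p, " probability value(s)")
  }
  out
}
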