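#' Fit a parametric survival family to digitized KM coordinates
#'
#' Minimises the sum of squared residuals
#' \eqn{SSR = \sum_i (S_{model}(t_i) - s_i)^2} over the family's parameters
#' by Levenberg-Marquardt nonlinear least squares, multi-started from a
#' data-driven grid of initial values (scale anchored at the empirical
#' median; a spread of shapes), keeping the best final SSR. Least squares
#' on the survival proportion -- rather than a likelihood -- is the natural
#' objective here because digitized curve coordinates carry no at-risk
#' counts.
#'
#' Information criteria use the Gaussian-residual least-squares forms
#' `AIC = n log(SSR/n) + 2k` and `BIC = n log(SSR/n) + k log(n)` with `k`
#' the number of family parameters.
#'
#' @param points A data frame with columns `time_months` (>= 0) and
#'   `survival` (in \[0, 1\]); at least 3 points.
#' @param family A family name from [surv_families()].
#' @return An object of class `surv_fit`: list with `model`
#'   ([surv_model()] or `NULL`), `diagnostics` (tibble: `family`, `ssr`,
#'   `aic`, `bic`, `n_points`, `n_params`, `converged`) and `data`.
#' @examples
#' pts <- tibble::tibble(time_months = 0:24,
#'   survival = surv_prob(surv_model("weibull", c(shape = 1.2, scale = 6)), 0:24))
#' fit <- fit_survival(pts, "weibull")
#' glance(fit)
#' @export
fit_survival <- function(points, family) {
  family <- match.arg(family, surv_families())
  stopifnot(is.data.frame(points),
            all(c("time_months", "survival") %in% names(points)))
  t <- as.numeric(points$time_months)
  s <- as.numeric(points$survival)
  if (length(t) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(t < 0)) stop("times must be >= 0", call. = FALSE)
  if (any(s < 0 | s > 1)) stop("survival must lie in [0, 1]", call. = FALSE)

  n <- length(t)
  k <- length(surv_param_names(family))
  diag_fail <- tibble::tibble(
    family = family, ssr = Inf, aic = Inf, bic = Inf,
    n_points = n, n_params = k, converged = FALSE
  )
  # no decline to fit: every start is a stationary point of nothing useful
  if (all(s >= 1 - 1e-12)) {
    return(structure(list(model = NULL, diagnostics = diag_fail,
                          data = tibble::tibble(time_months = t, survival = s)),
                     class = "surv_fit"))
  }

  resid_fun <- function(theta) {
    m <- theta_to_model(family, theta)
    surv_prob(m, t) - s
  }
  best <- NULL
  for (theta0 in start_grid(family, t, s)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = theta0, fn = resid_fun,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15, gtol = 0)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.finite(ssr) && (is.null(best) || ssr < best$ssr)) {
      best <- list(par = fit$par, ssr = ssr)
    }
  }
  if (is.null(best)) {
    return(structure(list(model = NULL, diagnostics = diag_fail,
                          data = tibble::tibble(time_months = t, survival = s)),
                     class = "surv_fit"))
  }
  model <- theta_to_model(family, best$par)
  ssr <- best$ssr
  ssr_ic <- max(ssr, 1e-300) # keep criteria finite at a perfect fit
  structure(
    list(
      model = model,
      diagnostics = tibble::tibble(
        family = family, ssr = ssr,
        aic = n * log(ssr_ic / n) + 2 * k,
        bic = n * log(ssr_ic / n) + k * log(n),
        n_points = n, n_params = k, converged = TRUE
      ),
      data = tibble::tibble(time_months = t, survival = s)
    ),
    class = "surv_fit"
  )
}

# unconstrained optimisation coordinates: log for positive parameters,
# identity for gompertz shape and lognormal meanlog
theta_to_model <- function(family, theta) {
  p <- switch(family,
    exponential = c(rate = exp(theta[1])),
    weibull     = c(shape = exp(theta[1]), scale = exp(theta[2])),
    gompertz    = c(shape = theta[1], rate = exp(theta[2])),
    loglogistic = c(shape = exp(theta[1]), scale = exp(theta[2])),
    lognormal   = c(meanlog = theta[1], sdlog = exp(theta[2]))
  )
  surv_model(family, p)
}

# empirical median by linear interpolation of the curve at s = 0.5,
# falling back to the last observed time when the curve never crosses it
empirical_median <- function(t, s) {
  below <- which(s <= 0.5)
  if (!length(below)) return(max(t[t > 0], 1))
  i <- below[1]
  if (i == 1 || s[i] == 0.5) return(max(t[i], 1e-6))
  t0 <- t[i - 1]; t1 <- t[i]; s0 <- s[i - 1]; s1 <- s[i]
  max(t0 + (s0 - 0.5) / (s0 - s1) * (t1 - t0), 1e-6)
}

start_grid <- function(family, t, s) {
  med <- empirical_median(t, s)
  shapes <- c(0.5, 1, 2)
  switch(family,
    exponential = lapply(c(0.5, 1, 2), function(f) log(f * log(2) / med)),
    weibull = lapply(shapes, function(k)
      c(log(k), log(med / log(2)^(1 / k)))),
    loglogistic = lapply(shapes, function(b) c(log(b), log(med))),
    lognormal = lapply(c(0.5, 1, 2), function(sd)
      c(log(med), log(sd))),
    gompertz = lapply(c(-0.05, 0.01, 0.05, 0.15), function(eta)
      c(eta, log(max(eta * log(2) / (exp(eta * med) - 1), 1e-8))))
  )
}

#' Fit all five survival families to one curve
#'
#' @inheritParams fit_survival
#' @param families Families to fit (default all five).
#' @return A named list of [fit_survival()] results.
#' @export
fit_survival_families <- function(points, families = surv_families()) {
  fits <- purrr::map(families, ~ fit_survival(points, .x))
  names(fits) <- families
  fits
}

#' Select the extrapolation model from a set of fits
#'
#' Ranks converged fits by AIC; near-ties (|dAIC| < 0.01) are broken by
#' BIC, then SSR, then fewer parameters, then the declared family order.
#' The full ranking table is returned so a reviewer can apply an
#' additional plausibility check (e.g. clinical face validity of the
#' extrapolated tail) before accepting the automatic choice.
#'
#' @param fits A list of `surv_fit` objects (e.g. from
#'   [fit_survival_families()]).
#' @return An object of class `surv_selection`: list with `model` (the
#'   chosen [surv_model()]), `family`, and `ranking` (tibble with one row
#'   per fit, ordered best first, columns `rank`, `family`, `ssr`, `aic`,
#'   `bic`, `n_params`, `converged`, `chosen`, `tie`).
#' @export
select_survival_model <- function(fits) {
  diag <- purrr::map_dfr(fits, "diagnostics")
  diag$family_order <- match(diag$family, surv_families())
  conv <- dplyr::filter(diag, .data$converged)
  if (nrow(conv) == 0) stop("no converged fits to select from", call. = FALSE)

  conv <- dplyr::arrange(conv, .data$aic)
  conv$.grp <- cumsum(c(0, diff(conv$aic) >= 0.01))
  conv <- dplyr::arrange(conv, .data$.grp, .data$bic, .data$ssr,
                         .data$n_params, .data$family_order)
  conv <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(conv, .data$.grp), tie = dplyr::n() > 1))
  conv$.grp <- NULL

  ranking <- dplyr::bind_rows(conv, dplyr::filter(diag, !.data$converged))
  ranking$tie[is.na(ranking$tie)] <- FALSE
  ranking$rank <- seq_len(nrow(ranking))
  ranking$chosen <- ranking$rank == 1
  ranking <- dplyr::select(ranking, "rank", "family", "ssr", "aic", "bic",
                           "n_params", "converged", "chosen", "tie")
  chosen_family <- ranking$family[1]
  structure(
    list(model = fits[[chosen_family]]$model, family = chosen_family,
         ranking = ranking),
    class = "surv_selection"
  )
}

#' @export
print.surv_selection <- function(x, ...) {
  cat("<surv_selection> chosen:", x$family, "\n")
  print(x$ranking)
  invisible(x)
}

#' Fit and select extrapolation models for every arm and endpoint
#'
#' Runs [fit_survival_families()] and [select_survival_model()] for each
#' (arm, endpoint) combination of a long KM-curve table — the four
#' independent fits of the base case.
#'
#' @param curves A tibble as returned by [generate_km_curves()] (columns
#'   `arm`, `endpoint`, `time_months`, `survival`).
#' @param families Families to consider.
#' @return A `trial_fits` object: list with `models` (nested list
#'   `models[[arm]][[endpoint]]` of chosen [surv_model()]s) and `ranking`
#'   (one combined tibble with `arm` and `endpoint` columns).
#' @export
fit_trial_curves <- function(curves, families = surv_families()) {
  combos <- dplyr::distinct(curves, .data$arm, .data$endpoint)
  models <- list()
  ranking <- purrr::pmap_dfr(combos, function(arm, endpoint) {
    pts <- dplyr::filter(curves, .data$arm == !!arm,
                         .data$endpoint == !!endpoint)
    sel <- select_survival_model(fit_survival_families(pts, families))
    models[[arm]][[endpoint]] <<- sel$model
    dplyr::mutate(sel$ranking, arm = arm, endpoint = endpoint,
                  .before = 1)
  })
  structure(list(models = models, ranking = ranking), class = "trial_fits")
}

#' @export
print.trial_fits <- function(x, ...) {
  cat("<trial_fits>\n")
  for (arm in names(x$models)) {
    for (ep in names(x$models[[arm]])) {
      m <- x$models[[arm]][[ep]]
      cat("  ", arm, "/", ep, ": ", m$family, " (",
          paste(names(m$params), signif(m$params, 5), sep = "=",
                collapse = ", "), ")\n", sep = "")
    }
  }
  invisible(x)
}

#' @rdname fit_survival
#' @param x A `surv_fit` object.
#' @param ... Unused.
#' @method tidy surv_fit
#' @export
tidy.surv_fit <- function(x, ...) {
  if (is.null(x$model)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(term = names(x$model$params),
                 estimate = unname(x$model$params))
}

#' @rdname fit_survival
#' @method glance surv_fit
#' @export
glance.surv_fit <- function(x, ...) x$diagnostics
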