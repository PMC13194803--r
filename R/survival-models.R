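#' Parametric survival models
#'
#' A `surv_model` is a named parametric survival family with its parameters,
#' on a monthly time axis. Five families are supported, in the standard
#' parameterisations used for extrapolating oncology Kaplan-Meier data:
#'
#' * `exponential`: \eqn{S(t) = e^{-\lambda t}}, parameter `rate`
#'   (\eqn{\lambda > 0}).
#' * `weibull`: \eqn{S(t) = e^{-(t/\lambda)^k}}, parameters `shape`
#'   (\eqn{k > 0}) and `scale` (\eqn{\lambda > 0}).
#' * `gompertz`: \eqn{S(t) = e^{-(b/\eta)(e^{\eta t} - 1)}}, parameters
#'   `shape` (\eqn{\eta}, any sign) and `rate` (\eqn{b > 0}).
#' * `loglogistic`: \eqn{S(t) = 1 / (1 + (t/\alpha)^\beta)}, parameters
#'   `shape` (\eqn{\beta > 0}) and `scale` (\eqn{\alpha > 0}); the scale is
#'   the median survival time.
#' * `lognormal`: \eqn{S(t) = 1 - \Phi((\ln t - \mu)/\sigma)}, parameters
#'   `meanlog` (\eqn{\mu}) and `sdlog` (\eqn{\sigma > 0}).
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"loglogistic"`, `"lognormal"`.
#' @param params Named numeric vector of family parameters (names as above).
#' @return An object of class `surv_model`.
#' @examples
#' m <- surv_model("loglogistic", c(shape = 2, scale = 5.62))
#' surv_prob(m, c(0, 5.62)) # 1, 0.5
#' @export
surv_model <- function(family, params) {
  family <- match.arg(family, surv_families())
  wanted <- surv_param_names(family)
  if (!all(wanted %in% names(params))) {
    stop("family '", family, "' needs parameters: ",
         paste(wanted, collapse = ", "), call. = FALSE)
  }
  params <- as.numeric(params[wanted])
  names(params) <- wanted
  pos <- switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gompertz    = "rate",
    loglogistic = c("shape", "scale"),
    lognormal   = "sdlog"
  )
  if (any(params[pos] <= 0)) {
    stop("parameters ", paste(pos, collapse = ", "),
         " must be strictly positive for family '", family, "'",
         call. = FALSE)
  }
  structure(list(family = family, params = params, time_unit = "months"),
            class = "surv_model")
}

#' @export
print.surv_model <- function(x, ...) {
  cat("<surv_model> ", x$family, " (",
      paste(names(x$params), signif(x$params, 6), sep = " = ",
            collapse = ", "),
      ") [time in ", x$time_unit, "]\n", sep = "")
  invisible(x)
}

#' @rdname surv_model
#' @export
surv_families <- function() {
  c("exponential", "weibull", "gompertz", "loglogistic", "lognormal")
}

surv_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gompertz    = c("shape", "rate"),
    loglogistic = c("shape", "scale"),
    lognormal   = c("meanlog", "sdlog")
  )
}

#' Evaluate a parametric survival function
#'
#' @param model A [surv_model()].
#' @param t Numeric vector of non-negative times (months).
#' @return Numeric vector of survival probabilities S(t) in \[0, 1\].
#' @export
surv_prob <- function(model, t) {
  stopifnot(inherits(model, "surv_model"))
  if (any(t < 0)) stop("negative times are not allowed", call. = FALSE)
  p <- model$params
  s <- switch(model$family,
    exponential = exp(-p[["rate"]] * t),
    weibull     = exp(-(t / p[["scale"]])^p[["shape"]]),
    gompertz    = {
      eta <- p[["shape"]]; b <- p[["rate"]]
      if (abs(eta) < 1e-12) exp(-b * t)
      else exp(-(b / eta) * (exp(eta * t) - 1))
    },
    loglogistic = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
    lognormal   = {
      s <- numeric(length(t))
      pos <- t > 0
      s[!pos] <- 1
      s[pos] <- stats::pnorm((log(t[pos]) - p[["meanlog"]]) / p[["sdlog"]],
                             lower.tail = FALSE)
      s
    }
  )
  pmin(pmax(as.numeric(s), 0), 1)
}

#' Median survival time of a parametric model
#'
#' Closed forms where they exist; Gompertz by inverting the survivor function.
#' @inheritParams surv_prob
#' @return Median time in months (`Inf` if S never reaches 0.5).
#' @export
surv_median <- function(model) {
  p <- model$params
  switch(model$family,
    exponential = log(2) / p[["rate"]],
    weibull     = p[["scale"]] * log(2)^(1 / p[["shape"]]),
    loglogistic = p[["scale"]],
    lognormal   = exp(p[["meanlog"]]),
    gompertz    = {
      eta <- p[["shape"]]; b <- p[["rate"]]
      if (abs(eta) < 1e-12) return(log(2) / b)
      arg <- 1 + eta * log(2) / b
      if (arg <= 0) Inf else log(arg) / eta
    }
  )
}
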