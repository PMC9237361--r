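# Synthetic Kaplan-Meier machinery: simulated event/censor tables and
# product-limit curves from known parametric laws, standing in for curve
# coordinates digitised from trial publications so the fitting stage is
# testable end to end.

# Draw without disturbing the caller's RNG stream; a seed is mandatory
# (no reliance on global random state).
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Inverse-CDF draw for each family; for the log-logistic,
# t = ((1-u)/(lambda*u))^(1/gamma) with u ~ Uniform(0,1).
quantile_surv <- function(model, u) {
  stopifnot(is_surv_model(model), all(u > 0), all(u <= 1))
  sh <- model$shape; sc <- model$scale
  switch(model$family,
    loglogistic = ((1 - u) / (sc * u))^(1 / sh),
    weibull     = sc * (-log(u))^(1 / sh),
    lognormal   = stats::qlnorm(u, log(sc), sh, lower.tail = FALSE),
    gompertz    = log(1 - (sh / sc) * log(u)) / sh,
    exponential = -log(u) / sc,
    gamma       = stats::qgamma(u, sh, scale = sc, lower.tail = FALSE)
  )
}

#' Simulate event/censor times from a parametric law
#'
#' Inverse-CDF simulation of `n` subjects from a [surv_model()], with
#' optional right censoring. The default censoring scheme emulates an
#' administrative data cutoff with staggered accrual over 24 months: censor
#' times are Uniform(0, `censor_max`). Exponential censoring and no
#' censoring are also available. The seed is mandatory; draws never touch
#' the caller's RNG state.
#'
#' @param model A [surv_model()].
#' @param n Number of subjects (>= 1).
#' @param censoring `"uniform"` (default, administrative cutoff),
#'   `"exponential"`, or `"none"`.
#' @param censor_max Upper bound (months) of uniform censoring.
#' @param censor_rate Rate (per month) of exponential censoring.
#' @param seed Integer seed (required).
#' @return A data frame with columns `time_months` (observed time) and
#'   `event` (1 = event observed, 0 = censored).
#' @examples
#' d <- draw_surv_times(surv_model("loglogistic", 1.59, 0.015), 100, seed = 7)
#' mean(d$event)
#' @export
draw_surv_times <- function(model, n,
                            censoring = c("uniform", "exponential", "none"),
                            censor_max = 24, censor_rate = 0.05,
                            seed) {
  stopifnot(is_surv_model(model), n >= 1)
  censoring <- match.arg(censoring)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (censoring == "uniform" && censor_max <= 0)
    stop("`censor_max` must be positive", call. = FALSE)
  if (censoring == "exponential" && censor_rate <= 0)
    stop("`censor_rate` must be positive", call. = FALSE)
  with_local_seed(seed, {
    u <- stats::runif(n)
    t_event <- quantile_surv(model, u)
    t_cens <- switch(censoring,
      none        = rep(Inf, n),
      uniform     = stats::runif(n, 0, censor_max),
      exponential = stats::rexp(n, censor_rate)
    )
    data.frame(
      time_months = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
  })
}

#' Product-limit (Kaplan-Meier) curve from an event table
#'
#' Wraps [survival::survfit()] and returns the step-function coordinates a
#' curve digitiser would emit: event/censor times, survival, and
#' numbers at risk.
#'
#' @param data Event table with columns `time_months`, `event`.
#' @return A data frame of class `km_curve` with columns `time_months`,
#'   `survival`, `at_risk`, `n_event`.
#' @examples
#' km_curve(data.frame(time_months = c(1, 2, 3), event = c(1, 1, 1)))
#' @export
km_curve <- function(data) {
  data <- validate_event_table(data)
  sf <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = data)
  out <- data.frame(
    time_months = sf$time,
    survival = sf$surv,
    at_risk = sf$n.risk,
    n_event = sf$n.event
  )
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a KM step function at arbitrary times
#'
#' @param curve A [km_curve()] (or data frame with `time_months`, `survival`).
#' @param t Times (months) at which to evaluate; right-continuous steps,
#'   S = 1 before the first event time.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(all(c("time_months", "survival") %in% names(curve)))
  sf <- stats::stepfun(curve$time_months, c(1, curve$survival), right = FALSE)
  sf(t)
}

#' Write / read KM coordinate files
#'
#' Delimited text with columns `time_months`, `survival` (plus `at_risk`
#' when present), matching what a plot digitiser exports.
#'
#' @param curve A [km_curve()] or compatible data frame.
#' @param path File path.
#' @name km_io
NULL

#' @rdname km_io
#' @export
write_km_curve <- function(curve, path) {
  stopifnot(all(c("time_months", "survival") %in% names(curve)))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname km_io
#' @export
read_km_curve <- function(path) {
  out <- utils::read.csv(path)
  if (!all(c("time_months", "survival") %in% names(out)))
    stop("KM file needs columns `time_months` and `survival`", call. = FALSE)
  class(out) <- c("km_curve", "data.frame")
  out
}
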