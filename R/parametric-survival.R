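#' Parametric survival laws
#'
#' A `surv_model` is a two-parameter (one for the exponential) parametric
#' survivor function with time measured in months. The clinical engine of the
#' cohort model is the log-logistic law
#' \deqn{S(t) = \frac{1}{1 + \lambda t^{\gamma}}}{S(t) = 1 / (1 + lambda * t^gamma)}
#' with shape \eqn{\gamma} and scale \eqn{\lambda}; five comparator families
#' (Weibull, log-normal, Gompertz, exponential, gamma) are supported for model
#' selection.
#'
#' Per-family meaning of `shape` and `scale`:
#' \describe{
#'   \item{loglogistic}{`shape` = \eqn{\gamma}, `scale` = \eqn{\lambda};
#'     \eqn{S(t) = 1/(1+\lambda t^\gamma)}.}
#'   \item{weibull}{`shape` = \eqn{a}, `scale` = \eqn{b} (months);
#'     \eqn{S(t) = \exp(-(t/b)^a)}.}
#'   \item{lognormal}{`shape` = \eqn{\sigma} (sdlog), `scale` =
#'     \eqn{e^{\mu}} (the median, months).}
#'   \item{gompertz}{`shape` = \eqn{a} (per month; may be negative, in which
#'     case the hazard decreases and \eqn{S} has a plateau), `scale` =
#'     \eqn{b} > 0 (baseline rate per month);
#'     \eqn{S(t) = \exp(-(b/a)(e^{at}-1))}.}
#'   \item{exponential}{one-parameter family: `scale` holds the rate
#'     \eqn{r} (events per month), `shape` is fixed at 1;
#'     \eqn{S(t) = \exp(-rt)}.}
#'   \item{gamma}{`shape` = \eqn{k}, `scale` = \eqn{\theta} (months), the
#'     standard R gamma scale parameterisation.}
#' }
#'
#' @param family One of `"loglogistic"`, `"weibull"`, `"lognormal"`,
#'   `"gompertz"`, `"exponential"`, `"gamma"`.
#' @param shape Positive shape parameter (any real for Gompertz; ignored and
#'   fixed at 1 for the exponential).
#' @param scale Positive scale parameter (rate, for the exponential).
#'
#' @return An object of class `surv_model`.
#' @examples
#' os <- surv_model("loglogistic", shape = 1.59, scale = 0.015)
#' surv_prob(os, c(0, 12, 120))
#' surv_median(os)
#' @export
surv_model <- function(family = c("loglogistic", "weibull", "lognormal",
                                  "gompertz", "exponential", "gamma"),
                       shape, scale) {
  family <- match.arg(family)
  if (family == "exponential") {
    if (missing(shape)) shape <- 1
    shape <- 1
  }
  stopifnot(is.numeric(shape), length(shape) == 1L, is.finite(shape),
            is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  if (family != "gompertz" && shape <= 0)
    stop("`shape` must be positive for the ", family, " family", call. = FALSE)
  structure(
    list(family = family, shape = as.numeric(shape), scale = as.numeric(scale),
         time_unit = "months"),
    class = "surv_model"
  )
}

#' @export
print.surv_model <- function(x, ...) {
  cat(sprintf("<surv_model> %s (time in months)\n", x$family))
  if (x$family == "exponential") {
    cat(sprintf("  rate = %g /month\n", x$scale))
  } else {
    cat(sprintf("  shape = %g, scale = %g\n", x$shape, x$scale))
  }
  invisible(x)
}

is_surv_model <- function(x) inherits(x, "surv_model")

#' Survivor function of a parametric law
#'
#' Evaluates \eqn{S(t)} at times `t` (months).
#'
#' @param model A [surv_model()].
#' @param t Numeric vector of non-negative times in months.
#' @return Vector of survival probabilities in `[0, 1]`.
#' @export
surv_prob <- function(model, t) {
  stopifnot(is_surv_model(model), is.numeric(t))
  if (any(t < 0)) stop("negative time in `surv_prob()`", call. = FALSE)
  sh <- model$shape; sc <- model$scale
  s <- switch(model$family,
    loglogistic = 1 / (1 + sc * t^sh),
    weibull     = exp(-(t / sc)^sh),
    lognormal   = stats::plnorm(t, meanlog = log(sc), sdlog = sh,
                                lower.tail = FALSE),
    gompertz    = {
      if (abs(sh) < 1e-12) exp(-sc * t)
      else exp(-(sc / sh) * (exp(sh * t) - 1))
    },
    exponential = exp(-sc * t),
    gamma       = stats::pgamma(t, shape = sh, scale = sc, lower.tail = FALSE)
  )
  pmin(pmax(s, 0), 1)
}

#' Hazard function of a parametric law
#'
#' @inheritParams surv_prob
#' @return Instantaneous hazard (per month) at `t`.
#' @keywords internal
surv_hazard <- function(model, t) {
  stopifnot(is_surv_model(model), is.numeric(t), all(t >= 0))
  sh <- model$shape; sc <- model$scale
  switch(model$family,
    loglogistic = sc * sh * t^(sh - 1) / (1 + sc * t^sh),
    weibull     = (sh / sc) * (t / sc)^(sh - 1),
    lognormal   = stats::dlnorm(t, log(sc), sh) /
                    stats::plnorm(t, log(sc), sh, lower.tail = FALSE),
    gompertz    = sc * exp(sh * t),
    exponential = rep_len(sc, length(t)),
    gamma       = stats::dgamma(t, sh, scale = sc) /
                    stats::pgamma(t, sh, scale = sc, lower.tail = FALSE)
  )
}

#' Median survival time
#'
#' The time \eqn{t^*} with \eqn{S(t^*) = 0.5}. For the log-logistic law this
#' is the closed form \eqn{(1/\lambda)^{1/\gamma}}; other families use their
#' standard quantile functions (numeric root for the Gompertz).
#'
#' @param model A [surv_model()].
#' @return Median survival in months (`Inf` for a Gompertz with negative
#'   shape whose survivor plateau lies above 0.5).
#' @examples
#' surv_median(surv_model("loglogistic", 1.59, 0.015)) # about 14 months
#' @export
surv_median <- function(model) {
  stopifnot(is_surv_model(model))
  sh <- model$shape; sc <- model$scale
  switch(model$family,
    loglogistic = (1 / sc)^(1 / sh),
    weibull     = sc * log(2)^(1 / sh),
    lognormal   = sc,
    gompertz    = {
      # S plateaus at exp(scale/shape) for shape < 0
      if (sh < 0 && exp(sc / sh) >= 0.5) return(Inf)
      up <- 1
      while (surv_prob(model, up) > 0.5) up <- up * 2
      stats::uniroot(function(t) surv_prob(model, t) - 0.5,
                     c(0, up), tol = 1e-12)$root
    },
    exponential = log(2) / sc,
    gamma       = stats::qgamma(0.5, sh, scale = sc)
  )
}

#' Conditional per-cycle event probability
#'
#' Probability that a subject event-free at the start of model cycle
#' `cycle_index` experiences the event within that cycle:
#' \eqn{p_i = 1 - S(t_{i+1})/S(t_i)}. This is the transition-probability
#' construction used throughout the cohort engine; the telescoping identity
#' \eqn{\prod_{i<n}(1-p_i) = S(t_n)} holds exactly.
#'
#' @param model A [surv_model()].
#' @param cycle_index Zero-based cycle index (vectorised).
#' @param cycle A [cycle_spec()].
#' @return Event probability in `[0, 1]`; by convention 1 where
#'   \eqn{S(t_i) = 0} (cohort exhausted).
#' @export
cycle_event_prob <- function(model, cycle_index, cycle = cycle_spec()) {
  stopifnot(is_surv_model(model), inherits(cycle, "cycle_spec"))
  if (any(cycle_index < 0)) stop("`cycle_index` must be >= 0", call. = FALSE)
  t0 <- cycle_index * cycle$cycle_months
  t1 <- (cycle_index + 1) * cycle$cycle_months
  s0 <- surv_prob(model, t0)
  s1 <- surv_prob(model, t1)
  ifelse(s0 <= 0, 1, pmin(pmax(1 - s1 / s0, 0), 1))
}
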