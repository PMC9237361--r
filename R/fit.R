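# Conversion between the package's shape/scale slots and flexsurv's
# native parameter vectors, per family.
.flexsurv_dist <- c(loglogistic = "llogis", weibull = "weibull",
                    lognormal = "lnorm", gompertz = "gompertz",
                    exponential = "exp", gamma = "gamma")

.from_flexsurv <- function(family, est) {
  switch(family,
    loglogistic = list(shape = est[["shape"]],
                       scale = est[["scale"]]^(-est[["shape"]])),
    weibull     = list(shape = est[["shape"]], scale = est[["scale"]]),
    lognormal   = list(shape = est[["sdlog"]], scale = exp(est[["meanlog"]])),
    gompertz    = list(shape = est[["shape"]], scale = est[["rate"]]),
    exponential = list(shape = 1, scale = est[["rate"]]),
    gamma       = list(shape = est[["shape"]], scale = 1 / est[["rate"]])
  )
}

#' Fit a parametric survival law to right-censored data
#'
#' Maximum-likelihood estimation (via [flexsurv::flexsurvreg()]) of one of the
#' six supported families on event/censor times, as used to re-model
#' pseudo-individual patient data reconstructed from digitised Kaplan-Meier
#' curves. AIC and BIC follow the usual definitions
#' \eqn{AIC = 2k - 2\ell} and \eqn{BIC = k\ln n - 2\ell} with \eqn{k} free
#' parameters and \eqn{n} observations.
#'
#' @param data A data frame with columns `time_months` (> 0) and `event`
#'   (1 = event, 0 = right-censored).
#' @param family Family name as in [surv_model()].
#' @return A `surv_fit` object: list with `model` (a [surv_model()]),
#'   `loglik`, `aic`, `bic`, `n_obs`, `n_events`, `family`.
#' @examples
#' d <- draw_surv_times(surv_model("loglogistic", 1.59, 0.015),
#'                      n = 200, censoring = "none", seed = 1)
#' fit_parametric(d, "loglogistic")
#' @export
fit_parametric <- function(data, family = c("loglogistic", "weibull",
                                            "lognormal", "gompertz",
                                            "exponential", "gamma")) {
  family <- match.arg(family)
  data <- validate_event_table(data)
  if (nrow(data) < 10)
    stop("need at least 10 observations to fit", call. = FALSE)
  if (sum(data$event) < 1)
    stop("cannot fit: all observations are censored", call. = FALSE)
  fit <- tryCatch(
    flexsurv::flexsurvreg(
      survival::Surv(time_months, event) ~ 1,
      data = data, dist = .flexsurv_dist[[family]]
    ),
    error = function(e) stop("fit for family '", family,
                             "' did not converge: ", conditionMessage(e),
                             call. = FALSE)
  )
  est <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  pars <- .from_flexsurv(family, as.list(est))
  k <- fit$npars
  n <- nrow(data)
  structure(
    list(
      model = surv_model(family, shape = pars$shape, scale = pars$scale),
      loglik = fit$loglik,
      aic = 2 * k - 2 * fit$loglik,
      bic = k * log(n) - 2 * fit$loglik,
      n_obs = n,
      n_events = sum(data$event),
      family = family
    ),
    class = "surv_fit"
  )
}

#' @export
print.surv_fit <- function(x, ...) {
  cat(sprintf("<surv_fit> %s: shape = %.4g, scale = %.4g\n",
              x$family, x$model$shape, x$model$scale))
  cat(sprintf("  loglik = %.3f, AIC = %.3f, BIC = %.3f (n = %d, events = %d)\n",
              x$loglik, x$aic, x$bic, x$n_obs, x$n_events))
  invisible(x)
}

#' Fit all six families to the same data
#'
#' @inheritParams fit_parametric
#' @param families Character vector of families to fit.
#' @return Named list of `surv_fit` objects (families whose optimiser fails
#'   are dropped with a warning).
#' @export
fit_all_families <- function(data, families = names(.flexsurv_dist)) {
  fits <- list()
  for (f in families) {
    res <- tryCatch(fit_parametric(data, f), error = function(e) e)
    if (inherits(res, "error")) {
      warning("family '", f, "' skipped: ", conditionMessage(res),
              call. = FALSE)
    } else {
      fits[[f]] <- res
    }
  }
  if (!length(fits)) stop("no family could be fitted", call. = FALSE)
  fits
}

#' Select the best fit by information criteria
#'
#' Minimal AIC wins; ties are broken by minimal BIC, then by fewer free
#' parameters.
#'
#' @param fits Non-empty list of `surv_fit` objects.
#' @return The selected `surv_fit`.
#' @export
select_best <- function(fits) {
  if (!length(fits)) stop("empty fit list", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "surv_fit")))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  k <- vapply(fits, function(f)
    if (f$family == "exponential") 1L else 2L, integer(1))
  ord <- order(aic, bic, k)
  fits[[ord[1]]]
}

#' Summarise a list of fits as a table
#'
#' @param fits List of `surv_fit` objects.
#' @return A data frame with columns `family`, `shape`, `scale`, `loglik`,
#'   `aic`, `bic`, `n_obs`, suitable for writing with [utils::write.csv()].
#' @export
fit_table <- function(fits) {
  stopifnot(length(fits) > 0)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(family = f$family, shape = f$model$shape,
               scale = f$model$scale, loglik = f$loglik,
               aic = f$aic, bic = f$bic, n_obs = f$n_obs,
               row.names = NULL)
  }))
}

#' Least-squares fit to digitised curve coordinates
#'
#' Secondary fitting mode: instead of reconstructing pseudo-individual data,
#' fit a family directly to digitised survival coordinates by minimising the
#' sum of squared differences between the parametric survivor function and
#' the curve. No likelihood is available in this mode, so no AIC/BIC.
#'
#' @param curve A data frame with columns `time_months` and `survival`
#'   (e.g. a [km_curve()] or a digitiser export).
#' @param family Family name as in [surv_model()].
#' @param start Optional named list with `shape` and `scale` starting values.
#' @return A list with `model` (a [surv_model()]) and `sse` (residual sum of
#'   squares).
#' @export
fit_curve_ls <- function(curve, family = "loglogistic", start = NULL) {
  stopifnot(is.data.frame(curve),
            all(c("time_months", "survival") %in% names(curve)))
  tt <- curve$time_months
  ss <- curve$survival
  keep <- tt > 0 & is.finite(ss)
  tt <- tt[keep]; ss <- ss[keep]
  if (length(tt) < 3) stop("need at least 3 positive-time points", call. = FALSE)
  if (is.null(start)) {
    med <- tt[which.min(abs(ss - 0.5))]
    start <- switch(family,
      loglogistic = list(shape = 1.5, scale = med^(-1.5)),
      weibull     = list(shape = 1.5, scale = med),
      lognormal   = list(shape = 1, scale = med),
      gompertz    = list(shape = 0.05, scale = log(2) / med),
      exponential = list(shape = 1, scale = log(2) / med),
      gamma       = list(shape = 1.5, scale = med / 1.5)
    )
  }
  one_par <- family == "exponential"
  obj <- function(par) {
    p <- exp(par) # positivity via log-parameterisation
    m <- if (one_par) surv_model(family, scale = p[1])
         else surv_model(family, shape = p[1], scale = p[2])
    sum((surv_prob(m, tt) - ss)^2)
  }
  p0 <- if (one_par) log(start$scale) else log(c(start$shape, start$scale))
  opt <- stats::optim(p0, obj, method = if (one_par) "Brent" else "Nelder-Mead",
                      lower = if (one_par) -20 else -Inf,
                      upper = if (one_par) 20 else Inf,
                      control = list(maxit = 2000, reltol = 1e-12))
  p <- exp(opt$par)
  model <- if (one_par) surv_model(family, scale = p[1])
           else surv_model(family, shape = p[1], scale = p[2])
  list(model = model, sse = opt$value)
}

#' Read / write event-time tables
#'
#' Delimited-text interface for event tables: columns `time_months` and
#' `event` (1 = event, 0 = censored).
#'
#' @param path File path.
#' @param data Event table to write.
#' @name event_table_io
NULL

#' @rdname event_table_io
#' @export
read_event_table <- function(path) {
  validate_event_table(utils::read.csv(path))
}

#' @rdname event_table_io
#' @export
write_event_table <- function(data, path) {
  data <- validate_event_table(data)
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

validate_event_table <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("time_months", "event") %in% names(data)))
    stop("event table needs columns `time_months` and `event`", call. = FALSE)
  if (nrow(data) < 1) stop("empty event table", call. = FALSE)
  if (any(data$time_months < 0)) stop("negative times", call. = FALSE)
  if (!all(data$event %in% c(0, 1))) stop("`event` must be 0/1", call. = FALSE)
  data
}
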