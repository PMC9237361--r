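#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the deterministic model with each parameter at its low and high
#' bound (all others at base case) and reports the resulting ICERs, sorted
#' by descending bar width \eqn{|ICER_{high} - ICER_{low}|}.
#'
#' @param config A `cea_config`.
#' @param keys Parameters to vary; default: every configuration parameter
#'   carrying a `low`/`high` range.
#' @return Data frame of class `owsa_result`: `parameter`, `base`, `low`,
#'   `high`, `icer_low`, `icer_high`, `width`, plus attribute
#'   `base_icer`.
#' @examples
#' ow <- run_owsa(default_config(), keys = c("utility_pd", "bsa_m2"))
#' @export
run_owsa <- function(config = default_config(), keys = NULL) {
  stopifnot(inherits(config, "cea_config"))
  has_range <- vapply(config$parameters, function(p)
    !is.null(p$low) && !is.null(p$high), logical(1))
  if (is.null(keys)) keys <- names(config$parameters)[has_range]
  unknown <- setdiff(keys, names(config$parameters))
  if (length(unknown))
    stop("unknown configuration parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  no_range <- keys[!has_range[keys]]
  if (length(no_range))
    stop("no sensitivity range for: ", paste(no_range, collapse = ", "),
         call. = FALSE)
  base_icer <- run_base_case(config)$icer
  rows <- lapply(keys, function(k) {
    p <- config$parameters[[k]]
    icer_lo <- run_base_case(config_update(config, stats::setNames(list(p$low), k)))$icer
    icer_hi <- run_base_case(config_update(config, stats::setNames(list(p$high), k)))$icer
    data.frame(parameter = k, base = p$value, low = p$low, high = p$high,
               icer_low = icer_lo, icer_high = icer_hi,
               width = abs(icer_hi - icer_lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  class(out) <- c("owsa_result", "data.frame")
  out
}

# --- PSA sampling -----------------------------------------------------------

# Method-of-moments hyper-parameters with sd = (high - low) / (2 * 1.96).
# gamma: costs; beta: probabilities/utilities on [0,1]; beta_abs:
# disutilities sampled on |value| and negated; beta_range: beta rescaled to
# [low, high] for beta-labelled parameters that cannot live on [0,1]
# (follow-up cost, body surface area, discount rate).
psa_draw_parameter <- function(p, n) {
  mean <- p$value
  sd <- (p$high - p$low) / (2 * 1.96)
  if (sd == 0) return(rep(mean, n))
  switch(p$psa,
    gamma = {
      shape <- (mean / sd)^2
      stats::rgamma(n, shape = shape, rate = mean / sd^2)
    },
    beta = rbeta_mom(n, mean, sd),
    beta_abs = -rbeta_mom(n, abs(mean), sd),
    beta_range = {
      m <- (mean - p$low) / (p$high - p$low)
      s <- sd / (p$high - p$low)
      p$low + (p$high - p$low) * rbeta_mom(n, m, s)
    },
    stop("unknown psa family: ", p$psa, call. = FALSE)
  )
}

# Beta draws on [0,1] matched to (mean, sd); an sd too large for the mean is
# clipped to the largest feasible value (with a message).
rbeta_mom <- function(n, mean, sd) {
  stopifnot(mean > 0, mean < 1)
  max_sd <- sqrt(mean * (1 - mean))
  if (sd >= max_sd) {
    message(sprintf(
      "beta moment match infeasible (mean %.3f, sd %.3f); sd clipped", mean, sd))
    sd <- 0.99 * max_sd
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  stats::rbeta(n, mean * nu, (1 - mean) * nu)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo simulation: every configuration parameter with an assigned
#' sampling family (`psa` field) is drawn from its moment-matched
#' distribution (gamma for costs, beta for probabilities, utilities and
#' disutility magnitudes, range-scaled beta for the remaining
#' beta-labelled parameters), the deterministic model is re-run per draw,
#' and incremental outcomes are recorded. Survival-curve parameters carry
#' no distribution and are held fixed. Draws are reproducible under
#' `seed` and do not disturb the caller's RNG.
#'
#' @param config A `cea_config`.
#' @param n_draws Number of Monte-Carlo draws (default 10,000).
#' @param seed Integer seed (required).
#' @param wtp_grid WTP grid (USD/QALY) for the acceptability summary;
#'   default 0 to 4x the configured WTP in 101 steps.
#' @return A `psa_result`: list with `draws` (data frame: one row per draw
#'   with sampled parameter values, `delta_cost`, `delta_qaly`, `icer`,
#'   `inmb`), `ceac` (data frame `wtp`, `prob_ce`), and `summary` (mean
#'   incrementals and probability cost-effective at the configured WTP).
#' @examples
#' psa <- run_psa(default_config(), n_draws = 50, seed = 1)
#' psa$summary
#' @export
run_psa <- function(config = default_config(), n_draws = 10000, seed,
                    wtp_grid = NULL) {
  stopifnot(inherits(config, "cea_config"), n_draws >= 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  wtp <- config_value(config, "wtp_per_qaly")
  if (is.null(wtp_grid)) wtp_grid <- seq(0, 4 * wtp, length.out = 101)
  sampled <- names(config$parameters)[
    vapply(config$parameters, function(p) !is.null(p$psa), logical(1))]
  par_draws <- with_local_seed(seed, {
    out <- lapply(sampled, function(k)
      psa_draw_parameter(config$parameters[[k]], n_draws))
    names(out) <- sampled
    as.data.frame(out)
  })
  # The trace depends only on the curves (fixed in PSA) and the cycle grid,
  # so build the traces once and re-accrue per draw.
  outcomes <- matrix(NA_real_, n_draws, 2,
                     dimnames = list(NULL, c("delta_cost", "delta_qaly")))
  for (i in seq_len(n_draws)) {
    cfg_i <- config_update(config, as.list(par_draws[i, , drop = FALSE]))
    res_i <- run_base_case(cfg_i)
    outcomes[i, ] <- c(res_i$delta_cost, res_i$delta_qaly)
  }
  draws <- cbind(par_draws, as.data.frame(outcomes))
  draws$icer <- ifelse(draws$delta_qaly == 0, NA_real_,
                       draws$delta_cost / draws$delta_qaly)
  draws$inmb <- nmb(draws$delta_qaly, draws$delta_cost, wtp)
  ceac_tab <- ceac(draws, wtp_grid)
  structure(
    list(
      draws = draws,
      ceac = ceac_tab,
      summary = data.frame(
        mean_delta_cost = mean(draws$delta_cost),
        mean_delta_qaly = mean(draws$delta_qaly),
        prob_ce_at_wtp = mean(draws$inmb > 0),
        wtp = wtp,
        n_draws = n_draws
      )
    ),
    class = "psa_result"
  )
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with positive incremental net monetary benefit at
#' each willingness-to-pay value.
#'
#' @param draws PSA draws (a `psa_result` or its `draws` data frame with
#'   `delta_cost` and `delta_qaly`).
#' @param wtp_grid Non-empty numeric vector of WTP values (USD/QALY).
#' @return Data frame with columns `wtp`, `prob_ce`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (inherits(draws, "psa_result")) draws <- draws$draws
  stopifnot(is.data.frame(draws), nrow(draws) >= 1,
            all(c("delta_cost", "delta_qaly") %in% names(draws)))
  if (length(wtp_grid) == 0) stop("empty WTP grid", call. = FALSE)
  prob <- vapply(wtp_grid, function(w)
    mean(nmb(draws$delta_qaly, draws$delta_cost, w) > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_ce = prob)
}

#' Pembrolizumab price threshold analysis
#'
#' Bisection on the pembrolizumab unit price (USD/mg) for the price at
#' which the base-case ICER equals a target willingness-to-pay, to within
#' 0.01 USD/QALY. The ICER is monotone increasing in the price (a
#' property-tested invariant), so the root is unique when bracketed.
#'
#' @param target Target ICER (USD/QALY), e.g. the WTP threshold.
#' @param config A `cea_config`.
#' @param bracket Price search interval, USD/mg.
#' @return List with `price` (USD/mg), `icer` (achieved ICER at that
#'   price), and `converged`.
#' @export
threshold_price <- function(target, config = default_config(),
                            bracket = c(0, 100)) {
  stopifnot(inherits(config, "cea_config"), length(bracket) == 2)
  icer_at <- function(price)
    run_base_case(config_update(config, cost_pembrolizumab_mg = price))$icer
  f_lo <- icer_at(bracket[1]) - target
  f_hi <- icer_at(bracket[2]) - target
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0)
    return(list(price = NA_real_, icer = NA_real_, converged = FALSE))
  lo <- bracket[1]; hi <- bracket[2]
  repeat {
    mid <- (lo + hi) / 2
    f_mid <- icer_at(mid) - target
    if (abs(f_mid) < 0.01) break
    if (f_mid * f_lo < 0) hi <- mid else { lo <- mid; f_lo <- f_mid }
    if (hi - lo < 1e-12) break
  }
  list(price = mid, icer = f_mid + target, converged = abs(f_mid) < 0.01)
}

#' Pembrolizumab treatment-duration threshold analysis
#'
#' Scans cycle caps 1 to 35 and returns the largest cap whose base-case
#' ICER does not exceed the willingness-to-pay (0 if none does). The ICER
#' is non-decreasing in the cap at a positive price.
#'
#' @param config A `cea_config`.
#' @param price Pembrolizumab unit price (USD/mg); default the configured
#'   base-case price.
#' @param wtp Threshold (USD/QALY); default the configured WTP.
#' @return List with `max_cycles` (0-35), `icer` at that cap (`NA` when 0),
#'   and `table` (cap vs ICER over the scan).
#' @export
threshold_cycles <- function(config = default_config(), price = NULL,
                             wtp = NULL) {
  stopifnot(inherits(config, "cea_config"))
  if (!is.null(price))
    config <- config_update(config, cost_pembrolizumab_mg = price)
  if (is.null(wtp)) wtp <- config_value(config, "wtp_per_qaly")
  caps <- 1:35
  icers <- vapply(caps, function(k)
    run_base_case(config_update(config, max_cycles_pembrolizumab = k))$icer,
    numeric(1))
  ok <- caps[icers <= wtp]
  best <- if (length(ok)) max(ok) else 0L
  list(max_cycles = best,
       icer = if (best > 0) icers[caps == best] else NA_real_,
       table = data.frame(max_cycles = caps, icer = icers))
}
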