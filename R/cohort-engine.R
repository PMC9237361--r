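#' Model cycle specification
#'
#' Time bookkeeping for the cohort model: a 21-day cycle over a 10-year
#' horizon gives `round(10 * 365.25 / 21) = 174` cycles. Time is carried in
#' months of 30.4375 days, so one cycle is 0.690 months; the printed
#' log-logistic parameters reproduce the trial medians only on this scale.
#'
#' @param cycle_days Cycle length in days (default 21, the q3w dosing
#'   interval).
#' @param horizon_years Model horizon in years (default 10).
#' @return A `cycle_spec` object with fields `cycle_days`, `horizon_years`,
#'   `days_per_month` (30.4375), `days_per_year` (365.25), `cycle_months`,
#'   `cycle_years`, `n_cycles`, and `boundaries` (cycle-start times in
#'   months, length `n_cycles + 1`).
#' @export
cycle_spec <- function(cycle_days = 21, horizon_years = 10) {
  stopifnot(cycle_days > 0, horizon_years > 0)
  days_per_month <- 30.4375
  days_per_year <- 365.25
  n_cycles <- round(horizon_years * days_per_year / cycle_days)
  cycle_months <- cycle_days / days_per_month
  structure(
    list(
      cycle_days = cycle_days,
      horizon_years = horizon_years,
      days_per_month = days_per_month,
      days_per_year = days_per_year,
      cycle_months = cycle_months,
      cycle_years = cycle_days / days_per_year,
      n_cycles = n_cycles,
      boundaries = (0:n_cycles) * cycle_months
    ),
    class = "cycle_spec"
  )
}

#' Economic parameters
#'
#' Discounting, willingness-to-pay, utilities and shared cost inputs. The
#' defaults are the base-case values of the Chinese-payer analysis: 5%
#' annual discounting, a WTP of 3x 2021 GDP per capita ($37,663.26/QALY),
#' utilities 0.741 (progression-free) and 0.581 (progressive disease),
#' grade >= 3 anaemia and neutropenia treated as acute one-off events, and
#' a body surface area of 1.72 m2 for per-m2 dosing.
#'
#' @param annual_discount Annual discount rate (supported range 0-0.08).
#' @param wtp_per_qaly Willingness-to-pay threshold, USD per QALY.
#' @param utility_pfd,utility_pd Health-state utilities in `[0, 1]`.
#' @param ae Named list of adverse events shared across strategies; each is
#'   `list(cost = USD, disutility = non-positive utility decrement)`.
#' @param followup_cost_per_cycle Routine follow-up cost, USD per model
#'   cycle, applied in both alive states.
#' @param bsa_m2 Body surface area for per-m2 dosing, m2.
#' @param half_cycle Logical; apply half-cycle correction (default `TRUE`).
#' @param disutility_duration_years Duration over which an adverse-event
#'   disutility is experienced; default one model cycle (21 days) in years.
#' @return An `econ_params` object.
#' @export
econ_params <- function(annual_discount = 0.05,
                        wtp_per_qaly = 37663.26,
                        utility_pfd = 0.741,
                        utility_pd = 0.581,
                        ae = list(
                          anemia = list(cost = 73.68, disutility = -0.074),
                          neutropenia = list(cost = 67.56, disutility = -0.090)
                        ),
                        followup_cost_per_cycle = 51.5,
                        bsa_m2 = 1.72,
                        half_cycle = TRUE,
                        disutility_duration_years = 21 / 365.25) {
  stopifnot(annual_discount >= 0, annual_discount <= 0.08,
            utility_pfd >= 0, utility_pfd <= 1,
            utility_pd >= 0, utility_pd <= 1,
            followup_cost_per_cycle >= 0, bsa_m2 > 0,
            disutility_duration_years >= 0)
  for (ev in ae) {
    stopifnot(ev$cost >= 0, ev$disutility <= 0, abs(ev$disutility) <= 1)
  }
  structure(
    list(annual_discount = annual_discount, wtp_per_qaly = wtp_per_qaly,
         utility_pfd = utility_pfd, utility_pd = utility_pd, ae = ae,
         followup_cost_per_cycle = followup_cost_per_cycle, bsa_m2 = bsa_m2,
         half_cycle = isTRUE(half_cycle),
         disutility_duration_years = disutility_duration_years),
    class = "econ_params"
  )
}

#' Discount factor at a time point
#'
#' \eqn{1 / (1 + r)^{t/12}} for time `t_months` and annual rate `r`.
#'
#' @param t_months Time in months (vectorised, >= 0).
#' @param params An [econ_params()] (or a bare annual rate).
#' @return Discount factors in `(0, 1]`.
#' @export
discount_factor <- function(t_months, params) {
  r <- if (inherits(params, "econ_params")) params$annual_discount else params
  stopifnot(all(t_months >= 0), r >= 0)
  1 / (1 + r)^(t_months / 12)
}

#' Build the three-state partitioned-survival trace
#'
#' State membership at every cycle boundary, derived directly from the OS
#' and PFS curves (area-under-curve partitioned survival): progression-free
#' \eqn{PFD(t) = \min(PFS(t), OS(t))}, death \eqn{D(t) = 1 - OS(t)}, and
#' progressive disease \eqn{PD(t) = OS(t) - PFD(t)}. Whenever the fitted
#' PFS curve crosses above OS it is clamped to OS (the crossing total is
#' recorded in the `clamped` attribute).
#'
#' @param os_model,pfs_model [surv_model()] laws for overall and
#'   progression-free survival, both in months.
#' @param cycle A [cycle_spec()].
#' @return A `cohort_trace`: data frame with columns `cycle` (0-based
#'   boundary index), `t_months`, `pfd`, `pd`, `death`; rows sum to 1.
#' @export
build_trace <- function(os_model, pfs_model, cycle = cycle_spec()) {
  stopifnot(is_surv_model(os_model), is_surv_model(pfs_model),
            inherits(cycle, "cycle_spec"))
  t <- cycle$boundaries
  os <- surv_prob(os_model, t)
  pfs <- surv_prob(pfs_model, t)
  if (any(!is.finite(os)) || any(!is.finite(pfs)))
    stop("non-finite survival values in trace construction", call. = FALSE)
  clamped <- sum(pmax(pfs - os, 0))
  pfd <- pmin(pfs, os)
  out <- data.frame(
    cycle = seq_along(t) - 1L,
    t_months = t,
    pfd = pfd,
    pd = os - pfd,
    death = 1 - os
  )
  attr(out, "clamped") <- clamped
  attr(out, "cycle_spec") <- cycle
  class(out) <- c("cohort_trace", "data.frame")
  out
}

# Per-cycle state occupancy used for accrual: trapezoid (start/end average)
# under half-cycle correction, cycle-start membership otherwise. Returns an
# n_cycles x 3 matrix (pfd, pd, death) plus the matching discount times.
trace_occupancy <- function(trace, half_cycle) {
  m <- as.matrix(trace[, c("pfd", "pd", "death")])
  n <- nrow(m) - 1L
  if (half_cycle) {
    occ <- (m[-1L, , drop = FALSE] + m[-(n + 1L), , drop = FALSE]) / 2
    t_disc <- (trace$t_months[-1L] + trace$t_months[-(n + 1L)]) / 2
  } else {
    occ <- m[-(n + 1L), , drop = FALSE]
    t_disc <- trace$t_months[-(n + 1L)]
  }
  list(occupancy = occ, t_disc = t_disc, n_cycles = n)
}

#' Accrue a per-cycle value stream over a trace
#'
#' Total \eqn{\sum_i \sum_s m_{is} v_{is} d_i}: occupancy times value,
#' optionally discounted at the cycle's (mid-point, under half-cycle
#' correction) time. Life-years use a value of one cycle length in years
#' for the alive states; QALYs use utility times cycle length.
#'
#' @param trace A [build_trace()] result.
#' @param values Either an `n_cycles x 3` matrix of per-cycle values for
#'   states (pfd, pd, death), or a length-3 vector recycled across cycles.
#' @param params An [econ_params()].
#' @param discounted Apply discounting (default `TRUE`).
#' @return Scalar total.
#' @export
accrue <- function(trace, values, params, discounted = TRUE) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(params, "econ_params"))
  occ <- trace_occupancy(trace, params$half_cycle)
  if (is.null(dim(values))) {
    stopifnot(length(values) == 3L)
    values <- matrix(values, nrow = occ$n_cycles, ncol = 3L, byrow = TRUE)
  }
  if (!all(dim(values) == c(occ$n_cycles, 3L)))
    stop("`values` must be n_cycles x 3 (pfd, pd, death)", call. = FALSE)
  d <- if (discounted) discount_factor(occ$t_disc, params) else 1
  sum(occ$occupancy * values * d)
}

#' Life-years and QALYs of a trace
#'
#' @param trace A [build_trace()] result.
#' @param params An [econ_params()].
#' @param discounted Apply discounting.
#' @return Named vector `c(ly, qaly)`; `qaly` excludes any adverse-event
#'   decrement (applied at strategy level).
#' @export
trace_outcomes <- function(trace, params, discounted = TRUE) {
  cyc <- attr(trace, "cycle_spec")
  cy <- cyc$cycle_years
  ly <- accrue(trace, c(cy, cy, 0), params, discounted)
  qaly <- accrue(trace, c(params$utility_pfd * cy, params$utility_pd * cy, 0),
                 params, discounted)
  c(ly = ly, qaly = qaly)
}

#' Export a trace with per-cycle accruals
#'
#' @param trace A [build_trace()] result.
#' @param params An [econ_params()].
#' @param cost_values Optional `n_cycles x 3` per-cycle cost matrix (see
#'   [strategy_cost_values()]); when supplied, per-cycle discounted cost
#'   accruals are included.
#' @param path Optional file path; when given, written as CSV.
#' @return Data frame with one row per model cycle: `cycle`, `t_months`,
#'   state occupancies, and discounted per-cycle `qaly` (and `cost`)
#'   accruals.
#' @export
trace_export <- function(trace, params, cost_values = NULL, path = NULL) {
  occ <- trace_occupancy(trace, params$half_cycle)
  cyc <- attr(trace, "cycle_spec")
  d <- discount_factor(occ$t_disc, params)
  u <- c(params$utility_pfd, params$utility_pd, 0) * cyc$cycle_years
  out <- data.frame(
    cycle = seq_len(occ$n_cycles) - 1L,
    t_months = cyc$boundaries[-length(cyc$boundaries)],
    pfd = trace$pfd[-nrow(trace)],
    pd = trace$pd[-nrow(trace)],
    death = trace$death[-nrow(trace)],
    qaly_disc = as.vector(occ$occupancy %*% u) * d
  )
  if (!is.null(cost_values))
    out$cost_disc <- rowSums(occ$occupancy * cost_values) * d
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
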