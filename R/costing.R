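#' Drug regimen
#'
#' One drug line of a treatment strategy: dose basis (flat mg or mg per m2
#' of body surface area), administrations per 21-day model cycle, unit cost
#' per mg, an optional cap on the number of model cycles in which it is
#' given, and the health state in which it accrues.
#'
#' @param name Drug name.
#' @param dose Dose in mg (flat) or mg/m2 (per-m2 basis).
#' @param dose_basis `"flat_mg"` or `"per_m2_mg"`.
#' @param admins_per_cycle Administrations per model cycle (may be
#'   fractional for schedules that do not divide the cycle, e.g. a q2w drug
#'   in a 21-day cycle contributes 1.5).
#' @param unit_cost USD per mg.
#' @param max_cycles Cap on treated model cycles (`Inf` = until leaving the
#'   state).
#' @param state State in which the drug accrues: `"pfd"` or `"pd"`.
#' @return A `drug_regimen` object.
#' @examples
#' drug_regimen("pembrolizumab", 200, "flat_mg", 1, 25.98, max_cycles = 35)
#' @export
drug_regimen <- function(name, dose,
                         dose_basis = c("flat_mg", "per_m2_mg"),
                         admins_per_cycle = 1, unit_cost,
                         max_cycles = Inf, state = c("pfd", "pd")) {
  dose_basis <- match.arg(dose_basis)
  state <- match.arg(state)
  stopifnot(dose > 0, admins_per_cycle > 0, unit_cost >= 0, max_cycles >= 0)
  structure(
    list(name = name, dose = dose, dose_basis = dose_basis,
         admins_per_cycle = admins_per_cycle, unit_cost = unit_cost,
         max_cycles = max_cycles, state = state),
    class = "drug_regimen"
  )
}

#' Drug cost per model cycle
#'
#' `dose_mg * admins_per_cycle * unit_cost`, with `dose_mg = dose` for flat
#' dosing or `dose * bsa_m2` for per-m2 dosing.
#'
#' @param reg A [drug_regimen()].
#' @param params An [econ_params()] carrying `bsa_m2`.
#' @return USD per model cycle.
#' @examples
#' p <- econ_params()
#' drug_cost_per_cycle(drug_regimen("pembrolizumab", 200, "flat_mg",
#'                                  1, 25.98), p) # 5196
#' @export
drug_cost_per_cycle <- function(reg, params) {
  stopifnot(inherits(reg, "drug_regimen"), inherits(params, "econ_params"))
  dose_mg <- switch(reg$dose_basis,
    flat_mg = reg$dose,
    per_m2_mg = {
      if (is.null(params$bsa_m2) || !is.finite(params$bsa_m2))
        stop("per-m2 dosing needs `bsa_m2`", call. = FALSE)
      reg$dose * params$bsa_m2
    }
  )
  dose_mg * reg$admins_per_cycle * reg$unit_cost
}

#' Treatment strategy
#'
#' A treatment arm: first-line regimens (accruing in the progression-free
#' state, each up to its cycle cap), grade >= 3 adverse-event incidences,
#' and a weighted mix of second-line regimens given for the whole of the
#' progressive-disease occupancy. Adverse-event unit costs and
#' disutilities are shared across strategies and live in [econ_params()];
#' only the incidences are arm-specific.
#'
#' @param name Strategy name.
#' @param first_line List of [drug_regimen()]s with `state = "pfd"`.
#' @param ae_incidence Named numeric vector of adverse-event probabilities
#'   in `[0, 1]`; names must match the events in [econ_params()]'s `ae`.
#' @param second_line List of [drug_regimen()]s with `state = "pd"`.
#' @param second_line_weights Numeric weights (>= 0, summing to 1) over
#'   `second_line`.
#' @return A `strategy_config` object.
#' @export
strategy_config <- function(name, first_line, ae_incidence,
                            second_line, second_line_weights) {
  stopifnot(length(second_line) == length(second_line_weights),
            all(second_line_weights >= 0))
  if (abs(sum(second_line_weights) - 1) > 1e-12)
    stop("second-line weights must sum to 1", call. = FALSE)
  stopifnot(all(vapply(first_line, inherits, logical(1), "drug_regimen")),
            all(vapply(second_line, inherits, logical(1), "drug_regimen")),
            all(ae_incidence >= 0), all(ae_incidence <= 1))
  names(first_line) <- vapply(first_line, `[[`, character(1), "name")
  names(second_line) <- vapply(second_line, `[[`, character(1), "name")
  structure(
    list(name = name, first_line = first_line, ae_incidence = ae_incidence,
         second_line = second_line,
         second_line_weights = second_line_weights),
    class = "strategy_config"
  )
}

#' Per-cycle first-line drug cost stream
#'
#' For each model cycle, the sum of active first-line regimens' per-cycle
#' costs; a regimen is active in cycle `i` (0-based) iff `i < max_cycles`.
#' Accrues against progression-free occupancy only.
#'
#' @param strategy A [strategy_config()].
#' @param params An [econ_params()].
#' @param cycle A [cycle_spec()].
#' @return Numeric vector of length `n_cycles` (USD per cycle, undiscounted,
#'   per fully occupied state).
#' @export
first_line_cost_stream <- function(strategy, params, cycle = cycle_spec()) {
  stopifnot(inherits(strategy, "strategy_config"))
  stream <- numeric(cycle$n_cycles)
  idx <- seq_len(cycle$n_cycles) - 1L
  for (reg in strategy$first_line) {
    active <- idx < reg$max_cycles
    stream[active] <- stream[active] + drug_cost_per_cycle(reg, params)
  }
  stream
}

#' Second-line drug cost per model cycle
#'
#' Weighted mean of the second-line regimens' per-cycle costs (the 50/50
#' docetaxel/irinotecan mix in the default configuration); accrues against
#' the whole progressive-disease occupancy.
#'
#' @inheritParams first_line_cost_stream
#' @return USD per model cycle.
#' @export
second_line_cost_per_cycle <- function(strategy, params) {
  stopifnot(inherits(strategy, "strategy_config"))
  costs <- vapply(strategy$second_line, drug_cost_per_cycle, numeric(1),
                  params = params)
  sum(strategy$second_line_weights * costs)
}

#' One-time adverse-event burden
#'
#' Expected cost and QALY decrement of grade >= 3 adverse events, applied
#' once at model entry (acute events): cost \eqn{\sum_e p_e c_e} and QALY
#' decrement \eqn{\sum_e p_e |u_e| \cdot d} with `d` the disutility
#' duration in years.
#'
#' @param strategy A [strategy_config()].
#' @param params An [econ_params()] with shared `ae` costs/disutilities.
#' @return Named vector `c(cost, qaly_decrement)` (both >= 0).
#' @export
ae_onetime_burden <- function(strategy, params) {
  stopifnot(inherits(strategy, "strategy_config"),
            inherits(params, "econ_params"))
  events <- names(strategy$ae_incidence)
  if (!all(events %in% names(params$ae)))
    stop("adverse events in strategy not defined in econ_params: ",
         paste(setdiff(events, names(params$ae)), collapse = ", "),
         call. = FALSE)
  cost <- 0; dec <- 0
  for (ev in events) {
    p <- strategy$ae_incidence[[ev]]
    cost <- cost + p * params$ae[[ev]]$cost
    dec <- dec + p * abs(params$ae[[ev]]$disutility) *
      params$disutility_duration_years
  }
  c(cost = cost, qaly_decrement = dec)
}

#' Full per-cycle cost matrix for a strategy
#'
#' Combines the first-line stream (progression-free state), second-line mix
#' and follow-up (both alive states) into the `n_cycles x 3` value matrix
#' consumed by [accrue()]. The one-time adverse-event burden is *not*
#' included (see [ae_onetime_burden()]).
#'
#' @inheritParams first_line_cost_stream
#' @return `n_cycles x 3` matrix (columns pfd, pd, death).
#' @export
strategy_cost_values <- function(strategy, params, cycle = cycle_spec()) {
  fl <- first_line_cost_stream(strategy, params, cycle)
  sl <- second_line_cost_per_cycle(strategy, params)
  fu <- params$followup_cost_per_cycle
  cbind(
    pfd = fl + fu,
    pd = rep(sl + fu, cycle$n_cycles),
    death = numeric(cycle$n_cycles)
  )
}
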