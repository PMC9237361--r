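#' Incremental cost-effectiveness ratio with dominance flags
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental effectiveness (QALYs).
#' @return List with `icer` (USD/QALY, `NA` when not defined) and `flag`:
#'   `"icer"`, `"dominant"` (cheaper and more effective), `"dominated"`
#'   (costlier and less effective), or `"undefined"` (zero QALY
#'   difference).
#' @examples
#' icer(100, 2)        # 50 per QALY
#' icer(-10, 0.5)      # dominant
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0)
    return(list(icer = NA_real_, flag = "undefined"))
  if (delta_cost < 0 && delta_qaly > 0)
    return(list(icer = delta_cost / delta_qaly, flag = "dominant"))
  if (delta_cost > 0 && delta_qaly < 0)
    return(list(icer = delta_cost / delta_qaly, flag = "dominated"))
  list(icer = delta_cost / delta_qaly, flag = "icer")
}

#' Net monetary benefit
#'
#' \eqn{NMB = WTP \cdot QALY - cost}. On incrementals, \eqn{iNMB > 0}
#' exactly when the ICER falls below the WTP (for positive QALY gains).
#'
#' @param qaly Effectiveness (QALYs).
#' @param cost Cost (USD).
#' @param wtp Willingness-to-pay (USD/QALY).
#' @return USD (vectorised).
#' @export
nmb <- function(qaly, cost, wtp) wtp * qaly - cost

# Totals for a single arm: discounted cost, discounted/undiscounted LY,
# discounted QALY (net of the one-time adverse-event decrement, which is
# applied at model entry, i.e. undiscounted).
arm_totals <- function(strategy, curves, econ, cycle) {
  trace <- build_trace(curves$os, curves$pfs, cycle)
  cost_values <- strategy_cost_values(strategy, econ, cycle)
  ae <- ae_onetime_burden(strategy, econ)
  out_d <- trace_outcomes(trace, econ, discounted = TRUE)
  out_u <- trace_outcomes(trace, econ, discounted = FALSE)
  list(
    strategy = strategy$name,
    cost = accrue(trace, cost_values, econ, discounted = TRUE) + ae[["cost"]],
    ly = out_d[["ly"]],
    ly_undiscounted = out_u[["ly"]],
    qaly = out_d[["qaly"]] - ae[["qaly_decrement"]],
    trace = trace
  )
}

#' Run the base-case cost-effectiveness analysis
#'
#' Deterministic two-arm run: builds each arm's partitioned-survival trace
#' from its OS/PFS laws, accrues discounted costs (first-line drugs under
#' their cycle caps, second-line mix over progressive disease, follow-up in
#' both alive states, one-off adverse-event burden at entry), life-years
#' and QALYs, and forms the incremental results. The ICER is computed from
#' unrounded totals; rounding happens only at presentation.
#'
#' @param config A `cea_config` (default: [default_config()]), or a
#'   pre-assembled model list from [build_model()].
#' @return A `cea_result`: list with `arms` (per-arm data frame: `cost`,
#'   `ly`, `ly_undiscounted`, `qaly`), `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `icer`, `icer_flag`, `inmb`, `wtp`, `cost_effective`,
#'   `traces`.
#' @examples
#' res <- run_base_case(default_config())
#' res$icer
#' @export
run_base_case <- function(config = default_config()) {
  model <- if (inherits(config, "cea_config")) build_model(config) else config
  stopifnot(is.list(model),
            all(c("cycle", "econ", "strategies", "curves") %in% names(model)))
  if (!setequal(names(model$strategies), names(model$curves)))
    stop("strategy/curve assignment mismatch: strategies ",
         paste(names(model$strategies), collapse = ", "), " vs curves ",
         paste(names(model$curves), collapse = ", "), call. = FALSE)
  arms <- lapply(names(model$strategies), function(nm) {
    arm_totals(model$strategies[[nm]], model$curves[[nm]],
               model$econ, model$cycle)
  })
  names(arms) <- names(model$strategies)
  iv <- arms[[model$intervention]]
  cp <- arms[[model$comparator]]
  delta_cost <- iv$cost - cp$cost
  delta_qaly <- iv$qaly - cp$qaly
  ic <- icer(delta_cost, delta_qaly)
  inmb <- nmb(delta_qaly, delta_cost, model$wtp)
  structure(
    list(
      arms = do.call(rbind, lapply(arms, function(a)
        data.frame(strategy = a$strategy, cost = a$cost, ly = a$ly,
                   ly_undiscounted = a$ly_undiscounted, qaly = a$qaly,
                   row.names = NULL))),
      delta_cost = delta_cost,
      delta_qaly = delta_qaly,
      delta_ly = iv$ly - cp$ly,
      icer = ic$icer,
      icer_flag = ic$flag,
      inmb = inmb,
      wtp = model$wtp,
      cost_effective = inmb > 0,
      traces = lapply(arms, `[[`, "trace")
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness results (discounted)\n")
  tab <- x$arms
  tab$cost <- sprintf("%.2f", tab$cost)
  tab$ly <- sprintf("%.3f", tab$ly)
  tab$ly_undiscounted <- sprintf("%.3f", tab$ly_undiscounted)
  tab$qaly <- sprintf("%.3f", tab$qaly)
  print(tab, row.names = FALSE)
  cat(sprintf("Incremental cost: %.2f USD | incremental QALYs: %.4f\n",
              x$delta_cost, x$delta_qaly))
  if (x$icer_flag == "icer") {
    cat(sprintf("ICER: %.2f USD/QALY (WTP %.2f) -> %scost-effective\n",
                x$icer, x$wtp, if (x$cost_effective) "" else "NOT "))
  } else {
    cat(sprintf("ICER: %s (WTP %.2f)\n", x$icer_flag, x$wtp))
  }
  invisible(x)
}

#' Serialise a CEA result
#'
#' @param result A `cea_result`.
#' @param path Output file; `.json` writes a JSON summary, anything else a
#'   results-table CSV (per-arm totals followed by incrementals).
#' @return `path`, invisibly.
#' @export
write_cea_result <- function(result, path) {
  stopifnot(inherits(result, "cea_result"))
  if (grepl("\\.json$", path)) {
    out <- list(
      arms = result$arms,
      delta_cost = result$delta_cost,
      delta_qaly = result$delta_qaly,
      delta_ly = result$delta_ly,
      icer = result$icer,
      icer_flag = result$icer_flag,
      inmb = result$inmb,
      wtp = result$wtp,
      cost_effective = result$cost_effective
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    tab <- result$arms
    pad <- rep(NA, nrow(tab) - 1L)
    tab$incremental_cost <- c(result$delta_cost, pad)
    tab$incremental_qaly <- c(result$delta_qaly, pad)
    tab$icer <- c(result$icer, pad)
    utils::write.csv(tab, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
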