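test_that("cycle bookkeeping: 21-day cycles over 10 years give 174 cycles", {
  cyc <- cycle_spec()
  expect_equal(cyc$n_cycles, 174)
  expect_equal(cyc$cycle_months, 21 / 30.4375)
  expect_true(all(diff(cyc$boundaries) > 0))
  expect_length(cyc$boundaries, 175)
})

test_that("partitioned-survival trace is a proper three-state cohort", {
  cv <- default_curves()
  arms <- list(list(cv$os_pembro, cv$pfs_pembro),
               list(cv$os_chemo, cv$pfs_chemo))
  for (a in arms) {
    tr <- build_trace(a[[1]], a[[2]])
    expect_equal(rowSums(tr[, c("pfd", "pd", "death")]), rep(1, nrow(tr)),
                 tolerance = 1e-10)
    expect_true(all(diff(tr$death) >= -1e-12))   # death absorbing
    expect_true(all(diff(tr$pfd) <= 1e-12))      # no return to PFD
    expect_true(all(as.matrix(tr[, 3:5]) >= -1e-12 &
                    as.matrix(tr[, 3:5]) <= 1 + 1e-12))
    expect_equal(unlist(tr[1, c("pfd", "pd", "death")], use.names = FALSE),
                 c(1, 0, 0))
  }
  # chemotherapy arm is nearly exhausted at the 10-year horizon
  tr <- build_trace(cv$os_chemo, cv$pfs_chemo)
  expect_gt(tr$death[nrow(tr)], 0.9)
})

test_that("PD occupancy matches calculus for exponential OS and PFS", {
  r <- 0.05
  tr <- build_trace(surv_model("exponential", scale = r),
                    surv_model("exponential", scale = 2 * r))
  expect_equal(tr$pd, exp(-r * tr$t_months) - exp(-2 * r * tr$t_months),
               tolerance = 1e-12)
  # PD is maximised at t = ln(2)/r
  t_star <- tr$t_months[which.max(tr$pd)]
  expect_equal(t_star, log(2) / r, tolerance = 0.05)
})

test_that("PFS above OS is clamped and recorded", {
  # a PFS law heavier-tailed than OS forces PFD = OS beyond the crossing
  tr <- build_trace(surv_model("exponential", scale = 0.2),
                    surv_model("exponential", scale = 0.05))
  expect_true(all(tr$pd >= 0))
  expect_gt(attr(tr, "clamped"), 0)
})

test_that("discounting follows 1/(1+r)^(t/12)", {
  p <- econ_params()
  expect_equal(discount_factor(0, p), 1)
  expect_equal(discount_factor(12, p), 1 / 1.05)
  expect_equal(discount_factor(c(6, 120), 0), c(1, 1))
  expect_error(discount_factor(-1, p))
})

test_that("accrual identities hold", {
  p_nohc <- econ_params(half_cycle = FALSE)
  cyc <- cycle_spec()
  # trace pinned at 100% PFD: undiscounted LY equals the horizon
  flat <- build_trace(surv_model("weibull", 1, 1e9),
                      surv_model("weibull", 1, 1e9))
  expect_equal(trace_outcomes(flat, p_nohc, discounted = FALSE)[["ly"]],
               174 * 21 / 365.25, tolerance = 1e-6)
  # the death state never pays alive-state values
  expect_equal(accrue(flat, c(0, 0, 1), p_nohc), 0, tolerance = 1e-5)
  # near-instant death: only the entry cycle's occupancy contributes
  dead <- build_trace(surv_model("weibull", 8, 1e-6),
                      surv_model("weibull", 8, 1e-6))
  expect_equal(accrue(dead, c(1, 1, 0), p_nohc), 1, tolerance = 1e-9)
  expect_error(accrue(flat, matrix(1, 3, 3), p_nohc), "n_cycles")
})

test_that("discounted QALYs match the geometric-series closed form", {
  # exponential OS, PFS = OS (no PD), utility u, no half-cycle correction:
  # QALY = u * cy * sum_i x^i with x = exp(-r*c) / (1+rate)^(c/12)
  r <- 0.06; u <- 0.741; rate <- 0.05
  p <- econ_params(annual_discount = rate, utility_pfd = u,
                   half_cycle = FALSE)
  cyc <- cycle_spec()
  m <- surv_model("exponential", scale = r)
  tr <- build_trace(m, m, cyc)
  x <- exp(-r * cyc$cycle_months) * (1 + rate)^(-cyc$cycle_months / 12)
  closed <- u * cyc$cycle_years * (1 - x^cyc$n_cycles) / (1 - x)
  expect_equal(trace_outcomes(tr, p)[["qaly"]], closed, tolerance = 1e-8)
})

test_that("discounting and utilities only shrink totals", {
  cv <- default_curves()
  tr <- build_trace(cv$os_pembro, cv$pfs_pembro)
  p <- econ_params()
  out_d <- trace_outcomes(tr, p, discounted = TRUE)
  out_u <- trace_outcomes(tr, p, discounted = FALSE)
  expect_lt(out_d[["ly"]], out_u[["ly"]])
  expect_true(out_d[["qaly"]] <= out_d[["ly"]])
  # zero rate: discounted equals undiscounted
  p0 <- econ_params(annual_discount = 0)
  expect_equal(trace_outcomes(tr, p0, discounted = TRUE),
               trace_outcomes(tr, p0, discounted = FALSE))
})

test_that("discretisation is converged and half-cycle shift is bounded", {
  cv <- default_curves()
  p <- econ_params(half_cycle = FALSE)
  ly21 <- trace_outcomes(build_trace(cv$os_pembro, cv$pfs_pembro,
                                     cycle_spec(cycle_days = 21)),
                         p, discounted = FALSE)[["ly"]]
  ly10 <- trace_outcomes(build_trace(cv$os_pembro, cv$pfs_pembro,
                                     cycle_spec(cycle_days = 10.5)),
                         p, discounted = FALSE)[["ly"]]
  expect_lt(abs(ly21 - ly10) / ly10, 0.01)
  # half-cycle correction moves accruals by less than one cycle's value
  p_hc <- econ_params(half_cycle = TRUE)
  tr <- build_trace(cv$os_pembro, cv$pfs_pembro)
  d_ly <- abs(trace_outcomes(tr, p_hc, FALSE)[["ly"]] -
              trace_outcomes(tr, p, FALSE)[["ly"]])
  expect_lt(d_ly, cycle_spec()$cycle_years)
})

test_that("trace export carries per-cycle discounted accruals", {
  cv <- default_curves()
  p <- econ_params()
  tr <- build_trace(cv$os_chemo, cv$pfs_chemo)
  cfg <- default_config()
  model <- build_model(cfg)
  costs <- strategy_cost_values(model$strategies$chemo, model$econ,
                                model$cycle)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  out <- trace_export(tr, p, cost_values = costs, path = path)
  expect_equal(nrow(out), 174)
  expect_named(out, c("cycle", "t_months", "pfd", "pd", "death",
                      "qaly_disc", "cost_disc"))
  expect_equal(sum(out$qaly_disc), trace_outcomes(tr, p)[["qaly"]])
  expect_true(file.exists(path))
})
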