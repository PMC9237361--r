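test_that("OWSA recovers the base-case ICER when the range collapses", {
  cfg <- default_config()
  cfg$parameters$utility_pd$low <- cfg$parameters$utility_pd$value
  cfg$parameters$utility_pd$high <- cfg$parameters$utility_pd$value
  ow <- run_owsa(cfg, keys = "utility_pd")
  base_icer <- run_base_case(cfg)$icer
  expect_identical(ow$icer_low, base_icer)
  expect_identical(ow$icer_high, base_icer)
  expect_identical(ow$width, 0)
  expect_identical(attr(ow, "base_icer"), base_icer)
})

test_that("OWSA bar widths equal independently recomputed ICER differences", {
  cfg <- default_config()
  ow <- run_owsa(cfg, keys = c("cost_pembrolizumab_mg", "utility_pd",
                               "bsa_m2"))
  # oracle: two direct base-case runs per parameter
  lo <- run_base_case(config_update(cfg, cost_pembrolizumab_mg = 12.99))$icer
  hi <- run_base_case(config_update(cfg, cost_pembrolizumab_mg = 25.98))$icer
  row <- ow[ow$parameter == "cost_pembrolizumab_mg", ]
  expect_equal(row$icer_low, lo)
  expect_equal(row$icer_high, hi)
  expect_equal(row$width, abs(hi - lo))
  # rows sorted by descending width
  expect_true(all(diff(ow$width) <= 0))
  expect_error(run_owsa(cfg, keys = "no_such_parameter"), "unknown")
})

test_that("the pembrolizumab price and cycle cap dominate the tornado", {
  ow <- run_owsa(default_config())
  top2 <- ow$parameter[1:2]
  expect_true("cost_pembrolizumab_mg" %in% top2)
  expect_true("max_cycles_pembrolizumab" %in% top2)
  # a parameter affecting neither arm's streams yields a zero-width bar:
  # the WTP itself is not varied, so use cisplatin with equal caps and a
  # zero price
  cfg0 <- config_update(default_config(), cost_cisplatin_mg = 0)
  cfg0$parameters$cost_cisplatin_mg$low <- 0
  cfg0$parameters$cost_cisplatin_mg$high <- 0
  ow0 <- run_owsa(cfg0, keys = "cost_cisplatin_mg")
  expect_identical(ow0$width, 0)
})

test_that("PSA sampling distributions are moment-matched", {
  cfg <- default_config()
  draw <- function(key, n = 10000) {
    with_seed_draws <- pembropsm:::with_local_seed(42,
      pembropsm:::psa_draw_parameter(cfg$parameters[[key]], n))
    with_seed_draws
  }
  u <- draw("utility_pfd")
  expect_equal(mean(u), 0.741, tolerance = 0.01)
  expect_true(all(u >= 0 & u <= 1))
  d <- draw("disutility_anemia")
  expect_true(all(d <= 0 & d >= -1))
  expect_equal(mean(d), -0.074, tolerance = 0.02)
  g <- draw("cost_pembrolizumab_mg")
  expect_true(all(g >= 0))
  expect_equal(mean(g), 25.98, tolerance = 0.01)
  expect_equal(sd(g), (25.98 - 12.99) / (2 * 1.96), tolerance = 0.05)
  # range-scaled beta stays inside its stated bounds
  r <- draw("annual_discount")
  expect_true(all(r >= 0 & r <= 0.08))
  expect_equal(mean(r), 0.05, tolerance = 0.02)
})

test_that("degenerate PSA (all ranges collapsed) reproduces the base case", {
  cfg <- default_config()
  for (k in names(cfg$parameters)) {
    if (!is.null(cfg$parameters[[k]]$psa)) {
      cfg$parameters[[k]]$low <- cfg$parameters[[k]]$value
      cfg$parameters[[k]]$high <- cfg$parameters[[k]]$value
    }
  }
  psa <- run_psa(cfg, n_draws = 20, seed = 3)
  base <- run_base_case(cfg)
  expect_equal(psa$summary$mean_delta_cost, base$delta_cost)
  expect_equal(psa$summary$mean_delta_qaly, base$delta_qaly)
  expect_true(psa$summary$prob_ce_at_wtp %in% c(0, 1))
})

test_that("PSA draws are reproducible and internally consistent", {
  cfg <- default_config()
  p1 <- run_psa(cfg, n_draws = 100, seed = 5)
  p2 <- run_psa(cfg, n_draws = 100, seed = 5)
  expect_identical(p1$draws, p2$draws)
  expect_equal(p1$draws$inmb,
               p1$summary$wtp * p1$draws$delta_qaly - p1$draws$delta_cost)
  expect_error(run_psa(cfg, n_draws = 10), "seed")
})

test_that("CEAC is the fraction of draws below the WTP line", {
  cfg <- default_config()
  psa <- run_psa(cfg, n_draws = 400, seed = 6)
  wtp <- psa$summary$wtp
  # geometric oracle: scatter points under the line delta_cost = wtp*delta_q
  below_line <- mean(psa$draws$delta_cost < wtp * psa$draws$delta_qaly)
  expect_equal(ceac(psa, wtp)$prob_ce, below_line)
  expect_equal(psa$summary$prob_ce_at_wtp, below_line)
  # CEAC at WTP = 0 is the fraction of cost-saving draws
  expect_equal(ceac(psa, 0)$prob_ce, mean(psa$draws$delta_cost < 0))
  # monotone when all QALY gains are positive
  expect_true(all(psa$draws$delta_qaly > 0))
  grid <- seq(0, 10 * wtp, length.out = 50)
  expect_true(all(diff(ceac(psa, grid)$prob_ce) >= 0))
})

test_that("a single draw gives a CEAC step at its own ICER", {
  one <- data.frame(delta_cost = 100, delta_qaly = 0.01)  # ICER 10,000
  expect_equal(ceac(one, c(5000, 9999, 10001, 2e4))$prob_ce, c(0, 0, 1, 1))
  expect_error(ceac(one, numeric()), "empty")
})

test_that("decision by ICER-vs-WTP equals the sign of incremental NMB", {
  psa <- run_psa(default_config(), n_draws = 1000, seed = 8)
  d <- psa$draws
  decision_icer <- d$delta_qaly > 0 & d$icer < psa$summary$wtp
  expect_identical(decision_icer, d$inmb > 0)
})

test_that("price threshold inverts the price-to-ICER map", {
  cfg <- default_config()
  base <- run_base_case(cfg)
  # fixed point: the current ICER maps back to the current price
  fp <- threshold_price(base$icer, cfg)
  expect_true(fp$converged)
  expect_equal(fp$price, 25.98, tolerance = 1e-4)
  # self-consistency at an arbitrary target
  th <- threshold_price(100000, cfg)
  expect_true(th$converged)
  redone <- run_base_case(config_update(cfg, cost_pembrolizumab_mg = th$price))
  expect_lt(abs(redone$icer - 100000), 0.01)
  # no crossing inside the bracket is flagged, not an error
  miss <- threshold_price(1e9, cfg, bracket = c(0, 30))
  expect_false(miss$converged)
})

test_that("cycle-cap threshold is verified by direct runs at k and k+1", {
  cfg <- default_config()
  wtp <- config_value(cfg, "wtp_per_qaly")
  th <- threshold_cycles(cfg)
  k <- th$max_cycles
  expect_true(k >= 1 && k <= 35)
  expect_lte(run_base_case(
    config_update(cfg, max_cycles_pembrolizumab = k))$icer, wtp)
  if (k < 35)
    expect_gt(run_base_case(
      config_update(cfg, max_cycles_pembrolizumab = k + 1))$icer, wtp)
  # free drug: every cap is affordable
  expect_equal(threshold_cycles(cfg, price = 0)$max_cycles, 35L)
})

test_that("sensitivity figures build without error", {
  cfg <- default_config()
  ow <- run_owsa(cfg, keys = c("cost_pembrolizumab_mg", "utility_pd"))
  psa <- run_psa(cfg, n_draws = 60, seed = 9)
  expect_s3_class(plot_tornado(ow), "ggplot")
  expect_s3_class(plot_ceac(psa, wtp = psa$summary$wtp), "ggplot")
  expect_s3_class(plot_psa_scatter(psa), "ggplot")
})
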