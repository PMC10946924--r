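test_that("degenerate spreads reproduce central values; draws are reproducible", {
  p <- default_parameters()
  p0 <- p
  p0$psa$sd[] <- 0
  d <- sample_draw(p0, seed = 1, index = 5)
  for (nm in p$psa$name)
    expect_identical(d[[nm]], p[[nm]], label = nm)
  d1 <- sample_draw(p, seed = 9, index = 3)
  d2 <- sample_draw(p, seed = 9, index = 3)
  for (nm in p$psa$name)
    expect_identical(d1[[nm]], d2[[nm]], label = nm)
  d3 <- sample_draw(p, seed = 9, index = 4)
  expect_false(identical(d1$cost_checkup, d3$cost_checkup))
})

test_that("sampled distributions are moment-matched and respect support", {
  p <- default_parameters()
  n <- 4000
  dw <- vapply(seq_len(n), function(i)
    sample_draw(p, seed = 11, index = i)$dw_caries, numeric(1))
  se <- 0.004 / sqrt(n)
  expect_lt(abs(mean(dw) - 0.010), 3 * se)
  expect_true(all(dw > 0 & dw < 1))
  slopes <- vapply(seq_len(500), function(i)
    sample_draw(p, seed = 12, index = i)$dmft_slope_per_10g, numeric(1))
  expect_true(all(slopes >= 0))  # zero-truncated normal
  costs <- vapply(seq_len(500), function(i)
    sample_draw(p, seed = 13, index = i)$cost_denture_pair, numeric(1))
  expect_true(all(costs > 0))
  expect_lt(abs(mean(costs) - 2798.08) / 2798.08, 0.05)
  # an SD outside the beta support is a configuration error
  pbad <- default_parameters()
  pbad$psa$sd[pbad$psa$name == "dw_caries"] <- 0.5
  expect_error(sample_draw(pbad, 1, 1), "sampling configuration")
})

test_that("incremental analysis applies the savings sign convention", {
  inp <- fixture_inputs()
  st_i <- run_population("intervention", inp$params, inp$schedule,
                         inp$profiles, inp$population, horizon = 10)
  st_c <- run_population("no_intervention", inp$params, inp$schedule,
                         inp$profiles, inp$population, horizon = 10)
  r_i <- arm_result(st_i, inp$params, inp$profiles)
  r_c <- arm_result(st_c, inp$params, inp$profiles)
  inc <- incremental_analysis(r_i, r_c, wtp = 50000)
  tot <- inc[inc$group == "total", ]
  expect_gt(tot$teeth_averted, 0)
  expect_gt(tot$dalys_averted, 0)
  expect_equal(tot$nmb, 50000 * tot$dalys_averted + tot$savings_societal)
  if (tot$savings_societal > 0) expect_equal(tot$decision, "dominant")
})

test_that("the wtp boundary gives zero net monetary benefit", {
  mk <- function(soc, daly) {
    tot <- data.frame(group = "total", societal = soc, healthcare = soc,
                      teeth = 0, dalys = daly, societal_undisc = soc,
                      healthcare_undisc = soc, teeth_undisc = 0,
                      dalys_undisc = daly, stringsAsFactors = FALSE)
    structure(list(arm = "x", horizon = 10, groups = "total",
                   totals = tot), class = "arm_result")
  }
  # intervention costs 50,000 more and averts exactly 1 DALY
  inc <- incremental_analysis(mk(50000, -1), mk(0, 0), wtp = 50000)
  expect_equal(inc$savings_societal, -50000)
  expect_equal(inc$dalys_averted, 1)
  expect_equal(inc$icer, 50000)
  expect_equal(inc$nmb, 0)
  # a costly intervention with no effect is never cost-effective
  inc0 <- incremental_analysis(mk(1000, 0), mk(0, 0), wtp = 50000)
  expect_lt(inc0$nmb, 0)
  expect_equal(inc0$decision, "dominated-or-undefined")
})

test_that("probability cost-effective equals the NMB indicator mean", {
  set.seed(1)
  draws <- data.frame(savings_societal = rnorm(500, 0, 1e5),
                      dalys_averted = rnorm(500, 1, 2))
  out <- probability_cost_effective(draws, wtp = 50000)
  brute <- sum(50000 * draws$dalys_averted + draws$savings_societal > 0) / 500
  expect_identical(unname(out$probability), brute)
  # symmetric NMB distribution sits near one half
  sym <- data.frame(savings_societal = c(-(1:100), 1:100),
                    dalys_averted = 0)
  expect_equal(unname(probability_cost_effective(sym, 50000)$probability),
               0.5)
  # CEAC is non-decreasing in WTP when all draws avert DALYs
  pos <- data.frame(savings_societal = rnorm(300, -1e4, 2e4),
                    dalys_averted = runif(300, 0.1, 2))
  cc <- probability_cost_effective(pos, 50000)$ceac
  expect_true(all(diff(cc$probability) >= 0))
  expect_true(all(c(0, 50000) %in% cc$wtp))
})

test_that("equity summary reports Q1/Q5 gradients and sentinels", {
  inc <- data.frame(group = as.character(1:5),
                    dalys_averted = c(30.8, 24.2, 18.0, 17.9, 10.2),
                    teeth_averted = c(5, 4, 3, 3, 1),
                    savings_societal = c(50, 40, 30, 30, 10))
  eq <- equity_summary(inc)
  expect_equal(unname(eq$ratios["dalys_averted"]), 30.8 / 10.2)
  expect_equal(unname(eq$ratios["dalys_averted"]), 3.02, tolerance = 1e-2)
  inc$dalys_averted <- rep(2, 5)
  inc$teeth_averted <- rep(3, 5)
  inc$savings_societal <- rep(4, 5)
  expect_true(all(equity_summary(inc)$ratios == 1))
  inc$dalys_averted[5] <- 0
  expect_true(is.na(equity_summary(inc)$ratios["dalys_averted"]))
})

test_that("the fitted model object carries coherent summaries and methods", {
  fit <- fit_small()
  expect_s3_class(fit, "ssb_cea")
  expect_equal(sort(unique(fit$draws$group)),
               sort(c(as.character(1:5), "total")))
  expect_equal(nrow(fit$draws), 100 * 6)
  # probability equals the draw-level indicator mean
  tot <- fit$draws[fit$draws$group == "total", ]
  expect_equal(unname(fit$probability["total"]), mean(tot$nmb > 0))
  expect_true(all(fit$probability >= 0 & fit$probability <= 1))
  # uncertainty intervals bracket the means
  s <- fit$summary
  expect_true(all(s$lo <= s$mean & s$mean <= s$hi))
  cf <- coef(fit)
  expect_named(cf, c("savings_societal", "savings_healthcare",
                     "teeth_averted", "dalys_averted", "nmb",
                     "probability_cost_effective"))
  expect_output(print(fit), "cost-effectiveness")
  expect_output(print(summary(fit)), "Equity")
  sim <- simulate(fit, nsim = 5, seed = 3,
                  params = fixture_inputs()$params,
                  schedule = fixture_inputs()$schedule,
                  profiles = fixture_inputs()$profiles,
                  population = fixture_inputs()$population)
  expect_equal(nrow(sim), 5 * 6)
})

test_that("a free effective intervention has threshold zero; bracketing holds", {
  inp <- fixture_inputs()
  pfree <- default_parameters(intervention_cost_year1 = 0,
                              intervention_cost_subsequent = 0)
  pfree$psa$sd[] <- 0
  th <- threshold_effectiveness(pfree, inp$schedule, inp$profiles,
                                inp$population, horizon = 5, n_draws = 5,
                                seed = 1)
  expect_equal(th, 0)
  # an intervention with cost but zero effect is never cost-effective
  pnull <- default_parameters(net_consumption_reduction = 0)
  pnull$psa$sd[] <- 0
  th2 <- threshold_effectiveness(pnull, inp$schedule, inp$profiles,
                                 inp$population, horizon = 5, n_draws = 5,
                                 seed = 1)
  expect_true(is.na(th2))
  expect_equal(attr(th2, "status"), "never")
})
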