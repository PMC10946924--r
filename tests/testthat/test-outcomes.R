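test_that("decayed teeth scale with caries severity", {
  expect_equal(decayed_teeth(100, 1.64), 164)
  expect_equal(decayed_teeth(0, 1.64), 0)
  expect_equal(decayed_teeth(1, 1), 1)
  expect_error(decayed_teeth(-1, 1.64), "non-negative")
})

test_that("caries episode YLD uses age-specific symptom durations", {
  p <- default_parameters()
  expect_equal(yld_caries_episode(30, p), 0.010 * 55 / 365)
  expect_equal(yld_caries_episode(30, p), 1.507e-3, tolerance = 1e-3)
  expect_equal(yld_caries_episode(10, p), 0.010 * 28 / 365)
  expect_equal(yld_caries_episode(16, p), yld_caries_episode(2, p))
  expect_equal(yld_caries_episode(17, p), yld_caries_episode(80, p))
  expect_equal(yld_caries_episode(30, default_parameters(dw_caries = 0)), 0)
})

test_that("edentulism YLD is the constant disability weight times time", {
  expect_equal(yld_edentulism(1, 0.067), 0.067)
  expect_equal(yld_edentulism(0, 0.067), 0)
  expect_equal(yld_edentulism(10, 0.067), 0.67)
})

test_that("episode costs build up from published fee components", {
  p <- default_parameters()
  expect_equal(episode_costs(1.64, 30, p, "healthcare"),
               54.69 + 1.64 * 189.61)
  expect_equal(episode_costs(1.64, 30, p, "healthcare"), 365.65,
               tolerance = 1e-4)
  expect_equal(episode_costs(1.64, 30, p, "societal"),
               54.69 + 1.64 * 189.61 + 20.71 + 49.22 * 2)
  expect_equal(episode_costs(1.64, 30, p, "societal"), 484.80,
               tolerance = 1e-4)
  # zero restored teeth still incur the check-up under per-tooth scaling
  expect_equal(episode_costs(0, 30, p, "healthcare"), 54.69)
  # denture episode: pair of dentures plus three visits of time and travel
  expect_equal(episode_costs(0, 70, p, "healthcare", type = "denture"),
               2798.08)
  expect_equal(episode_costs(0, 70, p, "societal", type = "denture"),
               2798.08 + 3 * 20.71 + 49.22 * (3 * 60 + 60) / 60)
  pv <- default_parameters(denture_minutes_mode = "per_visit")
  expect_equal(episode_costs(0, 70, pv, "societal", type = "denture"),
               2798.08 + 3 * 20.71 + 49.22 * (3 * 60 + 3 * 60) / 60)
  expect_error(episode_costs(1, 30, p, "actuarial"), "perspective")
})

test_that("care seeking gates treatment and toothache", {
  sched <- fixture_inputs()$schedule
  sched$p_toothache <- 0.3
  sched$p_attend <- 0.5
  flows <- data.frame(age = c(10, 40), sex = "female",
                      new_caries = c(1, 2), new_edentulous = c(0, 0.5))
  out <- apply_care_seeking(flows, sched)
  expect_equal(out$treated_caries, c(1, 2) * (0.3 + 0.7 * 0.5))
  expect_equal(out$toothache_cases, c(0.3, 0.6))
  expect_equal(out$denture_treated, c(0, 0.5) * 0.5)
  sched$p_toothache <- 1
  expect_equal(apply_care_seeking(flows, sched)$treated_caries, c(1, 2))
  sched$p_toothache <- 0; sched$p_attend <- 0
  expect_equal(apply_care_seeking(flows, sched)$treated_caries, c(0, 0))
})

test_that("discounting exempts year 1 and discounts later years", {
  expect_equal(discount(100, 0.03), 100)
  expect_equal(discount(c(0, 100), 0.03), 100 / 1.03)
  expect_equal(discount(c(0, 100), 0.03), 97.087, tolerance = 1e-4)
  v <- runif(20, 0, 100)
  expect_equal(discount(v, 0), sum(v))
  expect_equal(discount(v, 0.03),
               sum(v / 1.03^(0:19)), tolerance = 1e-12)
})

test_that("intervention cost stream follows the two-level schedule", {
  p <- default_parameters()
  expect_equal(intervention_cost_stream(10, p),
               c(5.8e6, rep(4.47e6, 9)))
  expect_equal(intervention_cost_stream(10, p, arm = "no_intervention"),
               rep(0, 10))
  expect_equal(intervention_cost_stream(10, p, share = 0.2),
               c(1.16e6, rep(0.894e6, 9)))
  expect_equal(intervention_cost_stream(1, p), 5.8e6)
})

test_that("societal costs decompose exactly into healthcare plus time and travel", {
  inp <- fixture_inputs()
  st <- run_population("intervention", inp$params, inp$schedule,
                       inp$profiles, inp$population, horizon = 10)
  res <- arm_result(st, inp$params, inp$profiles)
  expect_identical(res$cycle$societal,
                   res$cycle$healthcare + res$cycle$time_travel)
  expect_true(all(res$cycle$healthcare <= res$cycle$societal))
  expect_true(all(res$totals$societal >= 0))
})

test_that("accruals are linear in population and discounting only shrinks", {
  inp <- fixture_inputs()
  st1 <- run_population("intervention", inp$params, inp$schedule,
                        inp$profiles, inp$population, horizon = 10)
  pop2 <- inp$population
  pop2$count <- pop2$count * 2
  st2 <- run_population("intervention", inp$params, inp$schedule,
                        inp$profiles, pop2, horizon = 10)
  r1 <- arm_result(st1, inp$params, inp$profiles)
  r2 <- arm_result(st2, inp$params, inp$profiles)
  # intervention cost is population-independent; health accruals double
  expect_equal(r2$cycle$teeth, 2 * r1$cycle$teeth, tolerance = 1e-12)
  expect_equal(r2$cycle$dalys, 2 * r1$cycle$dalys, tolerance = 1e-12)
  expect_true(all(r1$totals$societal <= r1$totals$societal_undisc))
  expect_true(all(r1$totals$dalys <= r1$totals$dalys_undisc))
  p0 <- default_parameters(discount_rate = 0)
  r0 <- arm_result(st1, p0, inp$profiles)
  expect_equal(r0$totals$societal, r0$totals$societal_undisc)
})

test_that("DALY arm difference decomposes into averted episodes and person-years", {
  inp <- fixture_inputs()
  p <- inp$params
  s_int <- run_population("intervention", p, inp$schedule, inp$profiles,
                          inp$population, horizon = 10)
  s_ctl <- run_population("no_intervention", p, inp$schedule, inp$profiles,
                          inp$population, horizon = 10)
  r_int <- arm_result(s_int, p, inp$profiles)
  r_ctl <- arm_result(s_ctl, p, inp$profiles)
  d_daly <- r_ctl$totals$dalys_undisc - r_int$totals$dalys_undisc
  yld_c <- p$dw_caries * p$caries_duration_child_days / 365
  yld_a <- p$dw_caries * p$caries_duration_adult_days / 365
  recon <- rowSums(s_ctl$toothache_child - s_int$toothache_child) * yld_c +
    rowSums(s_ctl$toothache_adult - s_int$toothache_adult) * yld_a +
    p$dw_edentulism * rowSums(s_ctl$edent_py - s_int$edent_py)
  expect_equal(d_daly, unname(recon), tolerance = 1e-9)
})
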