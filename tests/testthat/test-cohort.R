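test_that("discount factors follow the after-first-cycle convention", {
  spec <- list(rate = 0.05, start_cycle = 2)
  expect_equal(discount_factor(1, spec), 1)
  expect_equal(discount_factor(2, spec), 1 / 1.05)
  expect_equal(discount_factor(5, spec), 1.05^-4)
  expect_equal(discount_factor(7, list(rate = 0, start_cycle = 2)), 1)
  expect_error(discount_factor(3, list(rate = -0.01, start_cycle = 2)), ">= 0")
})

test_that("a one-cycle all-death row forces the accrual convention", {
  tab <- uniform_table(cv_death = 1)
  cfg <- tiny_config(tab, horizon = 1)
  res <- run_cohort(list(tab), cfg, "PLACEBO")
  # cycle-start convention: occupants at cycle start earn the full cycle
  expect_equal(res$ly_undisc, 1)
  expect_equal(res$deaths_per_1000, 1000)
  expect_equal(res$qaly_undisc, 0.720) # start state II utility
  # under cycle-end accrual nobody survives to earn anything
  cfg_end <- cfg
  cfg_end$accrual <- "cycle-end"
  res_end <- run_cohort(list(tab), cfg_end, "PLACEBO")
  expect_equal(res_end$ly_undisc, 0)
})

test_that("a two-cycle hand-propagated trace matches exactly", {
  tab <- uniform_table(toII_noh = 0.7, toII_h = 0.1, cv_death = 0.2)
  cfg <- tiny_config(tab, horizon = 2, rate = 0)
  res <- run_cohort(rep(list(tab), 2), cfg, "PLACEBO")
  # hand trace: cycle 1 occupancy 1 in II; survivors 0.8; cycle 2 adds 0.8
  expect_equal(res$ly_undisc, 1.8, tolerance = 1e-12)
  expect_equal(res$hospitalizations_per_1000, 180, tolerance = 1e-9)
  expect_equal(res$deaths_per_1000, 360, tolerance = 1e-9)
  expect_equal(res$qaly_undisc, 1.8 * 0.720, tolerance = 1e-12)
  expect_trace_conserved(res)
})

test_that("all-ones utilities make QALYs equal life-years", {
  cfg <- default_parameters()
  cfg$utilities <- c(I = 1, II = 1, III = 1, IV = 1)
  res <- run_arms(cfg)$UCG
  expect_equal(res$qaly_disc, res$ly_disc, tolerance = 1e-12)
  expect_equal(res$qaly_undisc, res$ly_undisc, tolerance = 1e-12)
})

test_that("arm-results invariants hold on the default configuration", {
  arms <- run_arms(default_parameters(), arms = c("EG", "UCG", "PLACEBO"))
  for (res in arms) {
    expect_lte(res$ly_disc, res$ly_undisc)
    expect_lte(res$qaly_disc, res$qaly_undisc)
    expect_lte(res$cost_disc, res$cost_undisc)
    expect_lte(res$qaly_disc, res$ly_disc)
    expect_lte(res$ly_undisc, 10)
    expect_trace_conserved(res)
  }
})

test_that("with no treatment effect the arms differ only in drug costs", {
  cfg <- default_parameters()
  cfg$hrs <- hazard_ratio_set(
    hf_hosp = c(1, 1, 1), cv_death = c(1, 1, 1), all_cause_death = c(1, 1, 1)
  )
  cfg$mix <- c(I = 0, II = 0, III = 0, IV = 0)
  arms <- run_arms(cfg, arms = c("EG", "UCG"))
  expect_equal(arms$EG$trace, arms$UCG$trace, tolerance = 1e-12)
  expect_equal(arms$EG$ly_disc, arms$UCG$ly_disc, tolerance = 1e-12)
  expect_equal(arms$EG$hospitalizations_per_1000,
    arms$UCG$hospitalizations_per_1000,
    tolerance = 1e-9
  )
  # cost difference is exactly the eplerenone drug + monitoring stream
  drug_gap <- sum(arms$EG$accrual$drug_cost - arms$UCG$accrual$drug_cost)
  expect_equal(arms$EG$cost_undisc - arms$UCG$cost_undisc, drug_gap,
    tolerance = 1e-9
  )
  expect_gt(drug_gap, 0)
})

test_that("eplerenone monitoring follows the first-cycle convention", {
  cfg <- default_parameters()
  arms <- run_arms(cfg, arms = "EG")
  acc <- arms$EG$accrual
  # cycle 1: full cohort alive, drug cost = 1374 + 35.60 per person
  expect_equal(acc$drug_cost[1], 1374 + 35.60, tolerance = 1e-9)
  # cycle 2: (1374 + 71.20) x living occupancy at cycle-2 start
  alive2 <- sum(arms$EG$trace[2, nyha_states(living = TRUE)])
  expect_equal(acc$drug_cost[2], (1374 + 71.20) * alive2, tolerance = 1e-9)
  # combined-year-1 switch adds the annual monitoring to cycle 1
  cfg2 <- cfg
  cfg2$monitor_year1_combined <- TRUE
  acc2 <- run_arms(cfg2, arms = "EG")$EG$accrual
  expect_equal(acc2$drug_cost[1], 1374 + 35.60 + 71.20, tolerance = 1e-9)
  expect_equal(acc2$drug_cost[-1], acc$drug_cost[-1], tolerance = 1e-12)
})

test_that("usual-care drug costs accrue only to the spironolactone fraction", {
  tab <- uniform_table(toII_noh = 1) # nobody moves or dies
  cfg <- tiny_config(tab, horizon = 1, rate = 0)
  res <- run_cohort(build_arm_tables(cfg, "UCG"), cfg, "UCG")
  expect_equal(res$accrual$drug_cost[1], 0.437 * (45.29 + 71.20),
    tolerance = 1e-9
  )
})
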