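base_hrs <- hazard_ratio_set(
  hf_hosp = c(0.58, 0.47, 0.70),
  cv_death = c(0.76, 0.61, 0.94),
  all_cause_death = c(0.76, 0.62, 0.93)
)

test_that("hazard-ratio transformation matches the hand-arithmetic oracle", {
  row <- make_row("II",
    toII_noh = 0.55, toII_h = 0.20, toIII_noh = 0.10, toIII_h = 0.05,
    cv_death = 0.06, noncv_death = 0.04
  )
  out <- apply_hazard_ratios(row, base_hrs, mode = "cv-only")
  # frozen hand arithmetic: hosp entries x 0.58 with freed mass to the same
  # destination's no-hosp entry; cv_death x 0.76 = 0.0456; the 0.0144 freed
  # death mass scales the living entries by 0.9144/0.9 = 1.016
  expect_equal(out[["toII_h"]], 0.117856, tolerance = 1e-12)
  expect_equal(out[["toII_noh"]], 0.644144, tolerance = 1e-12)
  expect_equal(out[["toIII_h"]], 0.029464, tolerance = 1e-12)
  expect_equal(out[["toIII_noh"]], 0.122936, tolerance = 1e-12)
  expect_equal(out[["cv_death"]], 0.0456, tolerance = 1e-12)
  expect_equal(out[["noncv_death"]], 0.04, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)
})

test_that("hazard-ratio limits behave: identity at 1, full effect at ~0", {
  row <- make_row("II",
    toII_noh = 0.5, toII_h = 0.2, toIII_noh = 0.1,
    cv_death = 0.12, noncv_death = 0.08
  )
  id <- apply_hazard_ratios(row, base_hrs,
    hr_values = c(hf_hosp = 1, cv_death = 1, all_cause_death = 1)
  )
  expect_equal(as.numeric(id), as.numeric(row), tolerance = 1e-15)

  # hf_hosp -> 0 moves all hospitalization mass to no-hospitalization
  lim <- apply_hazard_ratios(row, base_hrs,
    hr_values = c(hf_hosp = 1e-15, cv_death = 1, all_cause_death = 1)
  )
  expect_equal(lim[["toII_h"]], 0, tolerance = 1e-12)
  expect_equal(lim[["toII_noh"]], 0.7, tolerance = 1e-12)
})

test_that("all-cause-split mode preserves the CV/non-CV death shares", {
  row <- make_row("III",
    toIII_noh = 0.6, toIII_h = 0.1, cv_death = 0.21, noncv_death = 0.09
  )
  out <- apply_hazard_ratios(row, base_hrs, mode = "all-cause-split")
  total <- out[["cv_death"]] + out[["noncv_death"]]
  expect_equal(total, 0.30 * 0.76, tolerance = 1e-12)
  expect_equal(out[["cv_death"]] / total, 0.7, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)
})

test_that("treatment transformation preserves row invariants over random rows", {
  set.seed(42)
  for (i in 1:50) {
    row <- random_row()
    hrv <- c(
      hf_hosp = stats::runif(1, 0.05, 1),
      cv_death = stats::runif(1, 0.05, 1),
      all_cause_death = stats::runif(1, 0.05, 1)
    )
    for (mode in c("cv-only", "all-cause-split")) {
      out <- apply_hazard_ratios(row, base_hrs, mode = mode, hr_values = hrv)
      expect_equal(sum(out), 1, tolerance = 1e-12)
      expect_true(all(out >= 0 & out <= 1))
    }
  }
})

test_that("a harmful hazard ratio that exhausts a probability is an
          infeasibility error naming the entry", {
  # nearly all mass in hospitalization: hr > 1 drives the paired
  # no-hospitalization entry negative
  row <- make_row("II", toII_noh = 0.01, toII_h = 0.89, cv_death = 0.1)
  expect_error(
    apply_hazard_ratios(row, base_hrs,
      hr_values = c(hf_hosp = 1.4, cv_death = 1, all_cause_death = 1)
    ),
    "toII_noh.*infeasible"
  )
})

test_that("lower hazard ratios never increase the targeted probabilities", {
  set.seed(7)
  for (i in 1:20) {
    row <- random_row()
    h1 <- apply_hazard_ratios(row, base_hrs,
      hr_values = c(hf_hosp = 0.9, cv_death = 0.9)
    )
    h2 <- apply_hazard_ratios(row, base_hrs,
      hr_values = c(hf_hosp = 0.5, cv_death = 0.9)
    )
    expect_true(all(h2[hfcea:::HOSP_COLS] <= h1[hfcea:::HOSP_COLS] + 1e-15))
    c1 <- apply_hazard_ratios(row, base_hrs, hr_values = c(cv_death = 0.9))
    c2 <- apply_hazard_ratios(row, base_hrs, hr_values = c(cv_death = 0.5))
    expect_lte(c2[["cv_death"]], c1[["cv_death"]] + 1e-15)
  }
})

test_that("usual-care blending is the entry-wise convex combination", {
  placebo <- make_row("II",
    toII_noh = 0.6, toII_h = 0.2, cv_death = 0.15, noncv_death = 0.05
  )
  treated <- apply_hazard_ratios(placebo, base_hrs)
  expect_equal(
    as.numeric(blend_usual_care(placebo, treated, 0)),
    as.numeric(placebo)
  )
  expect_equal(
    as.numeric(blend_usual_care(placebo, treated, 1)),
    as.numeric(treated)
  )
  f <- 0.437
  expect_equal(
    as.numeric(blend_usual_care(placebo, treated, f)),
    f * as.numeric(treated) + (1 - f) * as.numeric(placebo),
    tolerance = 1e-15
  )
  expect_error(blend_usual_care(placebo, treated, 1.2), "\\[0, 1\\]")

  # affine in the fraction: blend at f, g combine as expected
  set.seed(99)
  for (i in 1:10) {
    f <- stats::runif(1)
    g <- stats::runif(1)
    direct <- blend_usual_care(placebo, treated, f * g)
    nested <- blend_usual_care(placebo, blend_usual_care(placebo, treated, f), g)
    expect_equal(as.numeric(nested), as.numeric(direct), tolerance = 1e-12)
  }
})

test_that("age-trend scaling matches hand arithmetic and its identities", {
  row <- make_row("II",
    toII_noh = 0.54, toII_h = 0.18, toIII_noh = 0.12, toIII_h = 0.06,
    cv_death = 0.05, noncv_death = 0.05
  )
  # multiplier 1.2: deaths 0.06/0.06, living rescaled by 0.88/0.90
  tr <- age_trend(baseline_age = 68, ages = c(68, 70), multipliers = c(1, 1.2))
  out <- apply_age_trend(row, 70, tr)
  expect_equal(out[["cv_death"]], 0.06, tolerance = 1e-12)
  expect_equal(out[["noncv_death"]], 0.06, tolerance = 1e-12)
  expect_equal(out[["toII_noh"]], 0.54 * 0.88 / 0.90, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)

  # identities: baseline age, and flat trend at any age
  expect_equal(as.numeric(apply_age_trend(row, 68, tr)), as.numeric(row))
  expect_equal(as.numeric(apply_age_trend(row, 95, flat_trend())),
    as.numeric(row),
    tolerance = 1e-15
  )

  # extreme multiplier: death mass caps at 1, living goes to 0
  tr_big <- age_trend(baseline_age = 68, ages = c(68, 69), multipliers = c(1, 50))
  out_big <- apply_age_trend(row, 69, tr_big)
  expect_equal(sum(out_big[hfcea:::DEATH_COLS]), 1, tolerance = 1e-12)
  expect_equal(sum(out_big[hfcea:::LIVING_COLS]), 0)
})

test_that("arm tables follow the mixture endpoints and the hazard ratios", {
  cfg <- default_parameters()

  cfg0 <- cfg
  cfg0$mix <- c(I = 0, II = 0, III = 0, IV = 0)
  expect_identical(
    lapply(build_arm_tables(cfg0, "UCG"), unclass),
    lapply(build_arm_tables(cfg0, "PLACEBO"), unclass)
  )
  cfg1 <- cfg
  cfg1$mix <- c(I = 1, II = 1, III = 1, IV = 1)
  expect_identical(
    lapply(build_arm_tables(cfg1, "UCG"), unclass),
    lapply(build_arm_tables(cfg1, "EG"), unclass)
  )

  # at cycle 1 (age 68, trend multiplier 1) the eplerenone hospitalization
  # entries are 0.58 x the placebo entries, up to the row's uniform living
  # rescale that absorbs the death mass freed by the CV-death hazard ratio
  eg1 <- build_arm_tables(cfg, "EG")[[1]]
  pl1 <- build_arm_tables(cfg, "PLACEBO")[[1]]
  for (cls in nyha_states(living = TRUE)) {
    scale <- sum(eg1[cls, hfcea:::LIVING_COLS]) /
      (1 - 0.76 * pl1[cls, "cv_death"] - pl1[cls, "noncv_death"])
    expect_equal(scale, 1, tolerance = 1e-12) # rescale fills the freed mass
    living_ratio <- sum(eg1[cls, hfcea:::LIVING_COLS]) /
      sum(pl1[cls, hfcea:::LIVING_COLS])
    # the hospitalization share of each destination obeys the 0.58 multiplier
    expect_equal(
      unname(eg1[cls, hfcea:::HOSP_COLS]),
      unname(0.58 * pl1[cls, hfcea:::HOSP_COLS] /
        sum(pl1[cls, hfcea:::LIVING_COLS]) * sum(eg1[cls, hfcea:::LIVING_COLS])),
      tolerance = 1e-12
    )
    expect_lt(max(abs(living_ratio - 1)), 0.05) # rescale is a small correction
  }
})

test_that("the trend/treatment order flag changes usual-care results but not
          invariants", {
  cfg <- default_parameters()
  cfg2 <- cfg
  cfg2$trend_order <- "treatment-first"
  # pure multiplicative effects commute, so the eplerenone arm is identical
  # under either order; the usual-care mixture is nonlinear in the death
  # mass, so there the order genuinely matters
  e1 <- build_arm_tables(cfg, "EG")
  e2 <- build_arm_tables(cfg2, "EG")
  expect_equal(unclass(e1[[5]]), unclass(e2[[5]]), tolerance = 1e-12)
  t1 <- build_arm_tables(cfg, "UCG")
  t2 <- build_arm_tables(cfg2, "UCG")
  expect_false(isTRUE(all.equal(unclass(t1[[5]]), unclass(t2[[5]]))))
  for (tab in c(t1, t2, e1, e2)) {
    expect_silent(validate_transition_table(tab, tol = 1e-9))
  }
})
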