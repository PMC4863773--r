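test_that("parameter paths read and write every supported input", {
  cfg <- default_parameters()
  expect_equal(get_param(cfg, "utility.II"), 0.720)
  expect_equal(get_param(cfg, "hr.hf_hosp"), 0.58)
  expect_equal(get_param(cfg, "cost.background.III"), 226)
  expect_equal(get_param(cfg, "cost.hf_hosp_event"), 7136)
  expect_equal(get_param(cfg, "discount.rate"), 0.05)
  expect_equal(get_param(cfg, "tp.II.cv_death"), cfg$table["II", "cv_death"])

  cfg2 <- set_param(cfg, "utility.II", 0.5)
  expect_equal(cfg2$utilities[["II"]], 0.5)
  # setting the admission cost re-derives the per-death unit
  cfg3 <- set_param(cfg, "cost.cvd_death_admission", 4000)
  expect_equal(cfg3$costs$death_event_unit, 2000)
  expect_equal(cfg3$costs$cv_death_unit, 2000)
  expect_error(get_param(cfg, "nosuch.path"), "unknown parameter path")
})

test_that("DSA brackets the base case and orders by range", {
  cfg <- default_parameters()
  base <- icer(run_arms(cfg)$UCG, run_arms(cfg)$EG)

  # a spec varying a parameter to its own base at both bounds reproduces the
  # base-case ICER at both bounds
  specs <- data.frame(
    path = "utility.II", base = 0.720, low = 0.720, high = 0.720,
    stringsAsFactors = FALSE
  )
  out <- run_dsa(cfg, specs)
  expect_equal(out$icer_qaly_low, base$icer_per_qaly, tolerance = 1e-10)
  expect_equal(out$icer_qaly_high, base$icer_per_qaly, tolerance = 1e-10)

  # utility of class II +/-50%: the two ICERs bracket the base case
  specs2 <- data.frame(
    path = "utility.II", base = 0.720, low = 0.36, high = 1.0,
    stringsAsFactors = FALSE
  )
  out2 <- run_dsa(cfg, specs2)
  expect_lt(
    min(out2$icer_qaly_low, out2$icer_qaly_high),
    base$icer_per_qaly
  )
  expect_gt(
    max(out2$icer_qaly_low, out2$icer_qaly_high),
    base$icer_per_qaly
  )
  # lower utility -> fewer QALYs gained -> higher cost per QALY
  expect_gt(out2$icer_qaly_low, out2$icer_qaly_high)

  # full default table is ordered by descending ICER-per-QALY range width
  full <- run_dsa(cfg)
  expect_true(all(diff(full$range_qaly[!is.na(full$range_qaly)]) <= 1e-9))
  expect_true("hr.cv_death" %in% full$path)

  # hazard ratios at their upper confidence limits weaken cost-effectiveness
  hrrow <- full[full$path == "hr.cv_death", ]
  expect_gt(hrrow$icer_qaly_high, base$icer_per_qaly)
})

test_that("DSA rejects specs violating low <= base <= high", {
  cfg <- default_parameters()
  bad <- data.frame(
    path = "utility.II", base = 0.720, low = 0.9, high = 1.0,
    stringsAsFactors = FALSE
  )
  expect_error(run_dsa(cfg, bad), "low <= base <= high")
})

test_that("triangular sampler matches its distribution's moments and support", {
  set.seed(5)
  x <- rtriangular(20000, 1, 2, 5)
  expect_true(all(x >= 1 & x <= 5))
  # mean (min+mode+max)/3 within 3 SE; var = (a^2+b^2+c^2-ab-ac-bc)/18
  se <- sqrt((1 + 4 + 25 - 2 - 5 - 10) / 18 / 20000)
  expect_lt(abs(mean(x) - 8 / 3), 3 * se)
  expect_equal(rtriangular(3, 2, 2, 2), c(2, 2, 2))
})

test_that("PSA distribution families follow the published mapping", {
  cfg <- default_parameters()
  dists <- build_psa_distributions(cfg)
  fam <- vapply(dists, `[[`, "", "family")
  path <- vapply(dists, `[[`, "", "path")
  expect_true(all(fam[startsWith(path, "utility.")] == "beta"))
  expect_true(all(fam[startsWith(path, "cost.")] == "uniform"))
  expect_true(all(fam[startsWith(path, "tp.")] == "triangular"))
  # treatment drug/monitoring costs are fixed: no distribution exists
  expect_false(any(grepl("eplerenone|monitor|spiro", path)))
  # uniform cost ranges are +/-50% of base
  d <- dists[[which(path == "cost.hf_hosp_event")]]
  expect_equal(c(d$min, d$max), c(3568, 10704))
  # beta distributions are moment-matched to the base utility
  du <- dists[[which(path == "utility.II")]]
  expect_equal(du$shape1 / (du$shape1 + du$shape2), 0.720, tolerance = 1e-9)
  # triangular mode sits at the base transition probability
  dt <- dists[[which(path == "tp.II.cv_death")]]
  expect_equal(dt$mode, cfg$table["II", "cv_death"])
})

test_that("sampled parameter means converge to their configured means", {
  cfg <- default_parameters()
  dists <- build_psa_distributions(cfg)
  path <- vapply(dists, `[[`, "", "path")
  set.seed(11)
  check_mean <- function(d, expected, sd_one) {
    x <- replicate(10000, hfcea:::sample_distribution(d))
    expect_lt(abs(mean(x) - expected), 3 * sd_one / sqrt(10000))
  }
  du <- dists[[which(path == "utility.III")]]
  check_mean(du, 0.590, sqrt(
    du$shape1 * du$shape2 /
      ((du$shape1 + du$shape2)^2 * (du$shape1 + du$shape2 + 1))
  ))
  dc <- dists[[which(path == "cost.hf_hosp_event")]]
  check_mean(dc, 7136, (dc$max - dc$min) / sqrt(12))
  dt <- dists[[which(path == "tp.II.toII_h")]]
  check_mean(
    dt, (dt$min + dt$mode + dt$max) / 3,
    sqrt((dt$min^2 + dt$mode^2 + dt$max^2 - dt$min * dt$mode -
      dt$min * dt$max - dt$mode * dt$max) / 18)
  )
})

test_that("PSA is reproducible, conserves probability, and reports quadrants", {
  cfg <- default_parameters()
  cfg$horizon <- 5L # keep the test fast; properties are horizon-free
  p1 <- run_psa(cfg, n_iter = 40, seed = 123)
  p2 <- run_psa(cfg, n_iter = 40, seed = 123)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$ceac, p2$ceac)
  expect_equal(p1$n_failed, 0L)
  expect_true(all(p1$ceac$fraction >= 0 & p1$ceac$fraction <= 1))
  expect_equal(sum(p1$quadrants), 1)
  p3 <- run_psa(cfg, n_iter = 40, seed = 124)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("sampled transition tables always validate after renormalization", {
  cfg <- default_parameters()
  dists <- build_psa_distributions(cfg)
  set.seed(21)
  for (k in 1:25) {
    vals <- vapply(dists, hfcea:::sample_distribution, 0)
    cfg_k <- hfcea:::apply_samples(cfg, dists, vals)
    expect_silent(validate_transition_table(cfg_k$table, tol = 1e-9))
    expect_true(all(cfg_k$utilities >= 0 & cfg_k$utilities <= 1))
  }
})
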