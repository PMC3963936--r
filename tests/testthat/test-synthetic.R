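test_that("generators are pure functions of config and seed", {
  expect_identical(synth_cohort(cohort_config(seed = 7)),
                   synth_cohort(cohort_config(seed = 7)))
  expect_false(identical(synth_cohort(cohort_config(seed = 7)),
                         synth_cohort(cohort_config(seed = 8))))
  d <- c(10, 15, 25, 28, 30)
  expect_identical(synth_stunning(stunning_config(seed = 7), d),
                   synth_stunning(stunning_config(seed = 7), d))
  expect_identical(synth_qpcr(seed = 7), synth_qpcr(seed = 7))
  expect_identical(synth_recovery(stunning_config(seed = 7)),
                   synth_recovery(stunning_config(seed = 7)))
  # byte-identical CSV round
  f1 <- tempfile(); f2 <- tempfile()
  write_table_csv(synth_cohort(cohort_config(seed = 7)), f1)
  write_table_csv(synth_cohort(cohort_config(seed = 7)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate noise yields identical animals and identical doses", {
  cfg <- cohort_config(groups = data.frame(injected_MBq = 150, n = 5L,
                                           pid_mean = 2.63, pid_sd = 0),
                       lambda_eff_gsd = 1, measurement_cv = 0, seed = 1)
  tac <- synth_cohort(cfg)
  doses <- tac_to_doses(tac)
  expect_equal(length(unique(round(doses$dose_Gy, 12))), 1L)
  expect_equal(unique(tac$true_pid), 2.63)
})

test_that("group %ID means match the configured cohort structure", {
  tac <- synth_cohort(cohort_config(seed = 20140324))
  g150 <- tac[tac$injected_MBq == 150 & tac$time_h == 1, ]
  expect_equal(nrow(g150), 29L)
  pid <- percent_id(g150$activity_MBq, 150)
  se <- 0.47 / sqrt(29)
  # measurement noise (5% CV) adds little to the 2 SE band
  expect_lt(abs(mean(pid) - 2.63), 2 * se + 0.05)
})

test_that("pipeline estimates converge to configured truth as n grows", {
  cfg <- cohort_config(groups = data.frame(injected_MBq = 150, n = 200L,
                                           pid_mean = 2.63, pid_sd = 0.47),
                       seed = 909)
  tac <- synth_cohort(cfg)
  doses <- tac_to_doses(tac)
  # %ID at the peak sample
  pid_hat <- percent_id(doses$peak_activity_MBq, 150)
  expect_lt(abs(mean(pid_hat) - 2.63), 3 * 0.47 / sqrt(200) + 3 * 0.05 * 2.63 / sqrt(200))
  # median of fitted washout rates near the log-normal median
  lam_hat <- median(doses$lambda_eff_per_h)
  expect_lt(abs(lam_hat - 0.256), 3 * 0.256 * log(1.15) / sqrt(200))
  # fitted rates track the per-animal truth; with two post-peak samples and
  # 5% measurement noise the fit SE on lambda (~sqrt(2)*0.05/4h = 0.018/h) is
  # about half the population spread (0.256*log(1.15) = 0.036/h), bounding
  # the attainable correlation near 1/sqrt(1 + 0.25) ~ 0.9
  truth <- tac$true_lambda_eff[tac$time_h == 1]
  expect_gt(cor(doses$lambda_eff_per_h, truth), 0.85)
})

test_that("stunning generator reproduces configured group means at zero noise", {
  doses <- c(5, 10, 15, 20, 24, 28, 32, 35)
  rec <- synth_stunning(stunning_config(change_sd = 0, seed = 1), doses)
  below <- rec$percent_change[rec$initial_dose_Gy < 22]
  above <- rec$percent_change[rec$initial_dose_Gy > 22]
  expect_equal(below, rep(-3.95, length(below)), tolerance = 1e-12)
  expect_equal(above, rep(-17.5, length(above)), tolerance = 1e-12)
  expect_error(synth_stunning(stunning_config(), numeric(0)), "non-empty")
})

test_that("all-below-threshold doses produce no significant split", {
  hits <- 0L
  for (r in 1:40) {
    cfg <- stunning_config(seed = 500000L + r)
    rec <- synth_stunning(cfg, with_seed(600000L + r, runif(20, 2, 20)))
    if (threshold_scan(rec)$significant) hits <- hits + 1L
  }
  # with every dose below 22 Gy all animals share one distribution; allow the
  # uncorrected multi-candidate scan its inflated but bounded false-positive rate
  expect_lte(hits / 40, 0.5)
})

test_that("qPCR generator encodes fold changes in expectation", {
  q0 <- synth_qpcr(sd = 0, seed = 3)
  e <- tapply(relative_expression(q0$ct_target, q0$ct_reference), q0$group, mean)
  expect_equal(unname(e["control"] / e["gy20"]), 2.5)
  expect_equal(unname(e["control"] / e["gy30"]), 12)
  expect_equal(unname(e["control"] / e["gy5"]), 1)
  # power: 12-fold at dCt noise 0.5 detected in nearly all replicates
  sig <- 0L
  for (r in 1:100) {
    q <- synth_qpcr(sd = 0.5, seed = 700000L + r)
    dct <- q$ct_target - q$ct_reference
    p <- t.test(dct[q$group == "control"], dct[q$group == "gy30"])$p.value
    if (p < 0.05) sig <- sig + 1L
  }
  expect_gte(sig, 95)
})

test_that("invalid configurations list every offender", {
  err <- tryCatch(cohort_config(measurement_cv = -1, lambda_eff_median = -2),
                  error = conditionMessage)
  expect_match(err, "measurement_cv")
  expect_match(err, "lambda_eff_median")
  expect_error(stunning_config(mean_change_below = -20, mean_change_above = -3),
               "stunning scenario")
})
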