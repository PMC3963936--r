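test_that("physical decay arithmetic matches the half-life definition", {
  expect_equal(decay(150, 0), 150)
  expect_equal(decay(150, 6.0067), 75)
  # three days of decay is ~12 half-lives, leaving 0.04 MBq of 150
  expect_equal(round(decay(150, 72), 2), 0.04)
  expect_equal(72 / 6.0067, 12, tolerance = 0.002)
  expect_error(decay(150, 72, half_life_h = 0), "half_life")
  expect_error(decay(150, -1), "elapsed")
})

test_that("decay then decay_correct over the same interval is the identity", {
  for (el in c(0.1, 1, 7.3, 24, 72)) {
    expect_equal(decay_correct(decay(150, el), el), 150, tolerance = 1e-12)
  }
})

test_that("noiseless mono-exponential washout is recovered exactly", {
  a <- 3.5 * exp(-0.4 * c(0, 2, 6))
  s <- data.frame(time_h = c(1, 3, 7), activity_MBq = a)
  fit <- fit_tac(s)
  expect_equal(fit$lambda_eff_per_h, 0.4, tolerance = 1e-9)
  expect_equal(fit$peak_time_h, 1)
  expect_equal(fit$peak_activity_MBq, 3.5)
  expect_equal(fit$uptake_slope_MBq_h, 3.5)
  expect_lt(fit$rss, 1e-18)
})

test_that("fit idempotence: refitting the fitted curve recovers parameters", {
  s <- data.frame(time_h = c(1, 3, 7),
                  activity_MBq = c(3.5, 3.5 * exp(-0.7), 3.5 * exp(-2.31)))
  fit <- fit_tac(s)
  s2 <- data.frame(time_h = c(1, 2, 4, 8, 16),
                   activity_MBq = predict(fit, c(1, 2, 4, 8, 16)))
  fit2 <- fit_tac(s2)
  expect_equal(fit2$lambda_eff_per_h, fit$lambda_eff_per_h, tolerance = 1e-12)
  expect_equal(fit2$peak_activity_MBq, fit$peak_activity_MBq, tolerance = 1e-12)
})

test_that("washout faster than 0.33/h brings the curve below 10% of peak by 8 h", {
  for (lam in c(0.33, 0.4, 0.6)) {
    s <- data.frame(time_h = c(1, 3, 7),
                    activity_MBq = 3.5 * exp(-lam * c(0, 2, 6)))
    fit <- fit_tac(s)
    expect_lt(predict(fit, 8), 0.1 * fit$peak_activity_MBq)
  }
})

test_that("fit preconditions and error paths", {
  expect_error(fit_tac(data.frame(time_h = c(1, 3), activity_MBq = c(3, 2))),
               "post-peak")
  expect_error(fit_tac(data.frame(time_h = c(1, 3, 7),
                                  activity_MBq = c(3, 2, 0))),
               "log-linear washout")
  expect_error(fit_tac(data.frame(time_h = c(1, 1, 7),
                                  activity_MBq = c(3, 2, 1))),
               "strictly increasing")
  # washout slower than physical decay warns but does not fail
  s <- data.frame(time_h = c(1, 3, 7), activity_MBq = 3.5 * exp(-0.05 * c(0, 2, 6)))
  expect_warning(fit_tac(s), "physical decay")
})

test_that("free peak mode places the peak at the maximal sample", {
  s <- data.frame(time_h = c(0.5, 1, 3, 7),
                  activity_MBq = c(2, 3.5, 1.6, 0.3))
  fit <- fit_tac(s, peak_time_mode = "free")
  expect_equal(fit$peak_time_h, 1)
  fitf <- fit_tac(s, peak_time_mode = "fixed")
  expect_equal(fitf$peak_time_h, 0.5)
})

test_that("closed-form cumulated activity agrees with quadrature over random draws", {
  set.seed(424)
  max_rel <- 0
  for (i in 1:1000) {
    a <- runif(1, 0.1, 8); tp <- runif(1, 0.3, 2); lam <- runif(1, 0.12, 1.2)
    fit <- structure(list(peak_time_h = tp, peak_activity_MBq = a,
                          uptake_slope_MBq_h = a / tp, lambda_eff_per_h = lam,
                          rss = 0, n_washout = 2L), class = "tac_fit")
    ca <- cumulated_activity(fit, 24)$value_Bq_s
    max_rel <- max(max_rel, abs(ca / oracle_cumulated_Bq_s(fit, 24) - 1))
  }
  expect_lt(max_rel, 1e-6)
})

test_that("cumulated activity limits and monotonicity", {
  mk <- function(a, lam, tp = 1) structure(
    list(peak_time_h = tp, peak_activity_MBq = a, uptake_slope_MBq_h = a / tp,
         lambda_eff_per_h = lam, rss = 0, n_washout = 2L), class = "tac_fit")
  # linear in peak activity; vanishing peak gives vanishing integral
  expect_lt(cumulated_activity(mk(1e-12, 0.4))$value_Bq_s, 0.1)
  expect_equal(cumulated_activity(mk(2, 0.4))$value_Bq_s,
               2 * cumulated_activity(mk(1, 0.4))$value_Bq_s)
  # infinite washout leaves only the uptake triangle A*tp/2
  expect_equal(cumulated_activity(mk(1, 1e6))$value_Bq_s, 0.5 * 1e6 * 3600,
               tolerance = 1e-4)
  # strictly increasing in peak, strictly decreasing in washout rate
  expect_gt(cumulated_activity(mk(2, 0.4))$value_Bq_s,
            cumulated_activity(mk(1, 0.4))$value_Bq_s)
  expect_lt(cumulated_activity(mk(1, 0.8))$value_Bq_s,
            cumulated_activity(mk(1, 0.4))$value_Bq_s)
  expect_error(cumulated_activity(mk(1, 0.4, tp = 2), t_end_h = 2), "peak")
})

test_that("percent injected dose with and without decay correction", {
  expect_equal(percent_id(3.945, 150), 2.63)
  expect_equal(percent_id(0, 150), 0)
  raw <- percent_id(2, 100, elapsed_h = 1)
  corr <- percent_id(2, 100, elapsed_h = 1, decay_correct = TRUE)
  expect_equal(corr / raw, 2^(1 / 6.0067))
  expect_error(percent_id(1, 0), "injected")
})
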