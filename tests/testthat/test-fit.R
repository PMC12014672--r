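test_that("standard initialization follows the quarter/full-duration rule", {
  p60 <- initial_params(60)
  expect_equal(unlist(p60),
               c(I = 1, a1 = 0.5, a2 = -0.5, t_mid1 = 15, t_mid2 = 75))
  p90 <- initial_params(90)
  expect_equal(unlist(p90),
               c(I = 1, a1 = 0.5, a2 = -0.5, t_mid1 = 22.5, t_mid2 = 112.5))
  expect_warning(p120 <- initial_params(120), "designed durations")
  expect_equal(c(p120$t_mid1, p120$t_mid2), c(30, 150))
  expect_error(initial_params(-5), class = "scskinetics_invalid_input")
})

test_that("noiseless forward-simulated series are recovered essentially exactly", {
  truth <- sigmoid_params(1.2, 0.4, -0.3, 20, 80)
  fit <- fit_double_sigmoid(make_ntc(truth, grid9), t_stim = 90)
  rel <- abs(unlist(fit$params) - unlist(truth)) / abs(unlist(truth))
  expect_lt(max(rel), 1e-3)
  expect_lt(fit$dev_pct, 0.1)
  expect_true(fit$converged)
  expect_false(fit$inverted)
})

test_that("flat and inverted responses are fitted and flagged, not errors", {
  # no response at all: SSR = 0, deviation undefined, excluded by QC
  ntc0 <- structure(list(times = grid7, f_target = rep(0, 7), baseline_pwt = 6),
                    class = "pwt_normalized")
  fit0 <- fit_double_sigmoid(ntc0, t_stim = 60)
  expect_true(is.na(fit0$dev_pct))
  expect_lt(abs(fit0$params$I), 0.1)
  qc0 <- apply_exclusion(fit0)
  expect_true(qc0$excluded)

  # response running the wrong way (allodynia worsens): negative scale
  inv_truth <- sigmoid_params(-0.5, 0.4, -0.3, 20, 80)
  fit_inv <- fit_double_sigmoid(make_ntc(inv_truth, grid9), t_stim = 90)
  expect_lt(fit_inv$params$I, 0)
  qc <- apply_exclusion(fit_inv)
  expect_true(qc$excluded)
  expect_true(qc$negative_scale)
  expect_false(qc$small_scale)
})

test_that("the fit never ends above the cost of the stated initialization", {
  set.seed(11)
  for (r in 1:25) {
    truth <- sigmoid_params(runif(1, 0.3, 1.5), runif(1, 0.1, 1),
                            -runif(1, 0.1, 1), runif(1, 5, 40),
                            runif(1, 50, 110))
    tgt <- double_sigmoid(grid9, truth) + rnorm(9, 0, 0.2)
    ntc <- structure(list(times = grid9, f_target = tgt, baseline_pwt = 6),
                     class = "pwt_normalized")
    fit <- fit_double_sigmoid(ntc, t_stim = 90)
    ssd_init <- sum((double_sigmoid(grid9, initial_params(90)) - tgt)^2)
    expect_lte(fit$ssd, ssd_init + 1e-12)
  }
})

test_that("rescaling the raw thresholds leaves the whole fit invariant", {
  pwt <- c(6.2, 7.1, 11.4, 12.0, 11.2, 8.4, 6.0)
  f1 <- fit_pwt(pwt_timecourse(pwt, t_stim = 60))
  # dyadic scaling: bit-identical everything
  f2 <- fit_pwt(pwt_timecourse(2 * pwt, t_stim = 60))
  expect_identical(unlist(f2$params), unlist(f1$params))
  expect_identical(c(f2$slope1, f2$slope2, f2$fwhm_norm),
                   c(f1$slope1, f1$slope2, f1$fwhm_norm))
  expect_identical(f2$qc$excluded, f1$qc$excluded)
  # arbitrary positive scaling: equal to floating-point rounding
  f3 <- fit_pwt(pwt_timecourse(3 * pwt, t_stim = 60))
  expect_equal(unlist(f3$params), unlist(f1$params), tolerance = 1e-6)
  expect_identical(f3$qc$excluded, f1$qc$excluded)
})

test_that("underdetermined series are refused", {
  ntc <- structure(list(times = c(0, 15, 30, 45, 60),
                        f_target = c(0, .5, 1, 1, .5), baseline_pwt = 6),
                   class = "pwt_normalized")
  expect_error(fit_double_sigmoid(ntc, t_stim = 30),
               class = "scskinetics_underdetermined_fit")
})

test_that("exclusion rules reproduce the deviation and scale criteria", {
  qc <- apply_exclusion(60, I = 1)
  expect_true(qc$excluded && qc$high_deviation)
  expect_false(qc$small_scale || qc$negative_scale)

  qc <- apply_exclusion(10, I = 0.05)
  expect_true(qc$excluded && qc$small_scale)
  expect_false(qc$high_deviation || qc$negative_scale)

  qc <- apply_exclusion(20, I = 0.5)
  expect_false(qc$excluded)
  expect_false(qc$high_deviation || qc$small_scale || qc$negative_scale)

  qc <- apply_exclusion(10, I = -0.3)
  expect_true(qc$excluded && qc$negative_scale && !qc$small_scale)

  # thresholds are parameters, not constants baked into the logic
  qc <- apply_exclusion(40, I = 1, dev_max = 30)
  expect_true(qc$high_deviation)
  expect_error(apply_exclusion(10), class = "scskinetics_invalid_input")
})

test_that("fit_pwt methods agree across input representations", {
  pwt <- c(6, 6.8, 10.9, 11.5, 11.2, 8.1, 6.4)
  tc <- pwt_timecourse(pwt, t_stim = 60, animal_id = "r9", pattern = "tonic")
  f_tc <- fit_pwt(tc)
  df <- data.frame(time_min = grid7, pwt_g = pwt)
  f_df <- fit_pwt(df)
  expect_identical(unlist(f_tc$params), unlist(f_df$params))
  f_num <- fit_pwt(pwt)
  expect_identical(unlist(f_tc$params), unlist(f_num$params))
  expect_error(fit_pwt(data.frame(t = grid7, y = pwt)),
               class = "scskinetics_schema")
})

test_that("fit object methods behave like a standard model object", {
  pwt <- c(6, 6.8, 10.9, 11.5, 11.2, 8.1, 6.4)
  fit <- fit_pwt(pwt_timecourse(pwt, t_stim = 60))
  expect_named(coef(fit), c("I", "a1", "a2", "t_mid1", "t_mid2"))
  expect_equal(deviance(fit), fit$ssd)
  expect_equal(fitted(fit) + residuals(fit), fit$f_target, tolerance = 1e-12)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, newdata = fit$times), fitted(fit), tolerance = 1e-12)
  expect_equal(predict(fit, newdata = data.frame(time_min = 30)),
               double_sigmoid(30, fit$params))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(7, 3))
  expect_identical(simulate(fit, nsim = 3, seed = 1), sims)
  expect_output(print(summary(fit)), "slope1")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
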