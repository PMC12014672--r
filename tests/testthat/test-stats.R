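test_that("pattern summaries equal a brute-force recomputation", {
  st <- simulate_study(simulation_config(n_animals = 8, seed = 21))
  fits <- fit_study(st)
  sm <- summarize_patterns(fits, st)
  for (p in unique(fits$pattern)) {
    ret <- fits[fits$pattern == p & !fits$excluded, ]
    row <- sm$metrics[sm$metrics$pattern == p, ]
    expect_equal(row$n_retained, nrow(ret))
    expect_equal(row$slope1_mean, mean(ret$slope1))
    expect_equal(row$slope1_sem, sd(ret$slope1) / sqrt(nrow(ret)))
    expect_equal(row$fwhm_mean, mean(ret$fwhm_norm))
    expect_equal(row$dev_pct_all_mean, mean(fits$dev_pct[fits$pattern == p]))
    # raw threshold summaries
    sub <- st$data[st$data$pattern == p & st$data$time_min == 30, ]
    prow <- sm$pwt[sm$pwt$pattern == p & sm$pwt$time_min == 30, ]
    expect_equal(prow$pwt_mean, mean(sub$pwt_g))
    expect_equal(prow$pwt_sem, sd(sub$pwt_g) / sqrt(nrow(sub)))
  }
})

test_that("summary SEM matches the textbook formula on tiny fixtures", {
  fits <- data.frame(
    animal_id = c("a", "b"), pattern = "tonic", cohort = 1, t_stim_min = 60,
    I = 1, a1 = .5, a2 = -.5, t_mid1 = 15, t_mid2 = 75, ssd = 0, ssr = 1,
    dev_pct = c(5, 5), slope1 = c(.1, .1), slope2 = c(-.1, -.1),
    fwhm_norm = c(0.8, 1.0), converged = TRUE, inverted = FALSE, n_points = 7,
    excluded = FALSE, high_deviation = FALSE, small_scale = FALSE,
    negative_scale = FALSE, stringsAsFactors = FALSE)
  m <- summarize_patterns(fits)$metrics
  expect_equal(m$fwhm_mean, 0.9)
  expect_equal(m$fwhm_sem, 0.1)
  expect_equal(m$slope1_sem, 0)
})

test_that("timepoint-vs-baseline comparisons detect a strong reversal", {
  cfg <- simulation_config(n_animals = 20, cohort = rep(c(1, 2), 10),
                           noise_sd = 0.5, seed = 77)
  # a single strong-response pattern for all sessions
  cfg$patterns$max_reversal_g <- 5
  st <- simulate_study(cfg)
  res <- timepoint_vs_baseline(st, "tonic")
  expect_equal(res$time_min, c(15, 30, 45, 60))
  expect_true(all(res$significant))
  expect_true(all(res$estimate > 0))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$n == 20))
})

test_that("degenerate and undersized comparisons are handled as contracts say", {
  df <- data.frame(animal_id = rep(c("a", "b", "c"), each = 7),
                   pattern = "tonic", cohort = 1, t_stim_min = 60,
                   time_min = rep(grid7, 3), pwt_g = 6,
                   stringsAsFactors = FALSE)
  res <- timepoint_vs_baseline(df, "tonic")
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$p_value)))

  df2 <- df[df$animal_id %in% c("a", "b"), ]
  expect_error(timepoint_vs_baseline(df2, "tonic"),
               class = "scskinetics_insufficient_data")
  expect_error(timepoint_vs_baseline(df, "amplitude"),
               class = "scskinetics_invalid_input")
})

test_that("TDP-vs-tonic comparisons pair within animal and drop missing sessions", {
  st <- simulate_study(simulation_config(n_animals = 6, seed = 31))
  # remove one animal's tonic session entirely
  drop_id <- unique(st$data$animal_id)[1]
  st$data <- st$data[!(st$data$animal_id == drop_id &
                         st$data$pattern == "tonic"), ]
  res <- pattern_vs_tonic(st, t = 30)
  expect_setequal(res$pattern, setdiff(default_pattern_params()$pattern, "tonic"))
  expect_true(all(res$n == 5))

  # hand-checkable pairing: estimate equals mean within-animal difference
  df <- tiny_study_df()
  df <- rbind(df, within(df[df$animal_id == "r1", ], animal_id <- "r3"))
  res2 <- pattern_vs_tonic(df, t = 30)
  amp <- df[df$pattern == "amplitude" & df$time_min == 30, ]
  ton <- df[df$pattern == "tonic" & df$time_min == 30, ]
  expect_equal(res2$estimate,
               mean(amp$pwt_g[match(ton$animal_id, amp$animal_id)] - ton$pwt_g))
})

test_that("extended-period tests find tonic decline but not TDP decline", {
  st <- simulate_study(simulation_config(n_animals = 15, cohort = 2, seed = 55))
  ton <- extended_period_test(st, "tonic")
  expect_equal(ton$time_min, c(75, 90))
  d90 <- ton[ton$time_min == 90, ]
  expect_true(d90$significant)
  expect_lt(d90$estimate, 0)

  pw <- extended_period_test(st, "pulse_width")
  d90p <- pw[pw$time_min == 90, ]
  expect_false(isTRUE(d90p$significant) && d90p$estimate < 0)

  expect_error(extended_period_test(
    simulate_study(simulation_config(n_animals = 4, cohort = 1, seed = 3)),
    "tonic"), class = "scskinetics_insufficient_data")
  st1 <- simulate_study(simulation_config(n_animals = 1, cohort = 2, seed = 3))
  expect_error(extended_period_test(st1, "tonic"),
               class = "scskinetics_insufficient_data")
})

test_that("slope contrasts pair retained fits and report unavailable cells", {
  st <- simulate_study(simulation_config(n_animals = 10, seed = 61))
  fits <- fit_study(st)
  res <- slope_contrasts(fits)
  expect_setequal(unique(res$metric), c("slope1", "slope2"))
  expect_true(all(res$p_value[res$available] >= 0 &
                    res$p_value[res$available] <= 1))

  # manual check of one paired contrast
  ret <- fits[!fits$excluded, ]
  a <- ret[ret$pattern == "amplitude", ]
  b <- ret[ret$pattern == "tonic", ]
  common <- intersect(a$animal_id, b$animal_id)
  d <- a$slope1[match(common, a$animal_id)] - b$slope1[match(common, b$animal_id)]
  row <- res[res$pattern == "amplitude" & res$metric == "slope1", ]
  expect_equal(row$estimate, mean(d))
  expect_equal(row$n, length(common))

  # wiping out one pattern by QC yields an unavailable row, not an error
  fits2 <- fits
  fits2$excluded[fits2$pattern == "rate"] <- TRUE
  res2 <- slope_contrasts(fits2)
  expect_false(any(res2$available[res2$pattern == "rate"]))
  expect_true(all(is.na(res2$p_value[res2$pattern == "rate"])))
})

test_that("omnibus layer returns finite tests without gating the cells", {
  st <- simulate_study(simulation_config(n_animals = 8, seed = 71))
  fits <- fit_study(st)
  om <- omnibus_tests(st, fits)
  expect_setequal(om$pwt_anova$effect, c("pattern", "time_f", "pattern:time_f"))
  expect_true(all(is.finite(om$pwt_anova$statistic)))
  expect_true(all(om$pwt_anova$p_value >= 0 & om$pwt_anova$p_value <= 1))
  expect_equal(om$slope_models$metric, c("slope1", "slope2"))
  expect_true(all(is.finite(om$slope_models$statistic)))
})
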