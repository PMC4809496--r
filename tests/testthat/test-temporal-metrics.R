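test_that("robust trend recovers noiseless lines exactly", {
  t <- irregular_times(60)
  fit <- fit_rlm_trend(make_ts(t, 2 + 0.5 * (t - 1999)))
  expect_equal(fit$rlm_intercept, 2, tolerance = 1e-9)
  expect_equal(fit$rlm_slope, 0.5, tolerance = 1e-9)

  flat <- fit_rlm_trend(make_ts(t, rep(3, length(t))))
  expect_equal(flat$rlm_slope, 0, tolerance = 1e-12)
  expect_error(fit_rlm_trend(make_ts(t[1:3], t[1:3])), "at least 4")
})

test_that("robust trend resists a 10% outlier fraction better than OLS", {
  n_fail_rlm <- 0; n_ols_worse <- 0
  for (s in 1:20) {
    withr::with_seed(s, {
      t <- sort(runif(200, 1999, 2015))
      y <- 0.4 + 0.02 * (t - 1999) + rnorm(200, sd = 0.01)
      out <- sample(200, 20)
      y[out] <- y[out] - 0.5
    })
    rob <- fit_rlm_trend(make_ts(t, y))$rlm_slope
    ols <- unname(coef(lm(y ~ I(t - 1999)))[2])
    if (abs(rob - 0.02) >= 0.002) n_fail_rlm <- n_fail_rlm + 1
    if (abs(ols - 0.02) > abs(rob - 0.02)) n_ols_worse <- n_ols_worse + 1
  }
  expect_lte(n_fail_rlm, 1)
  expect_gte(n_ols_worse, 18)
})

test_that("season-trend fit recovers noiseless parameters to machine level", {
  t <- irregular_times(120, seed = 4)
  y <- 1 + 0.2 * (t - 1999) + 0.3 * sin(2 * pi * t + 0.5)
  fit <- fit_season_trend(make_ts(t, y), t0 = 1999)
  expect_equal(fit$alpha, 1, tolerance = 1e-6)
  expect_equal(fit$beta, 0.2, tolerance = 1e-6)
  expect_equal(fit$gamma, 0.3, tolerance = 1e-6)
  expect_equal(fit$delta, 0.5, tolerance = 1e-6)

  # degenerate amplitude: pure line has gamma ~ 0
  line <- fit_season_trend(make_ts(t, 2 + 0.1 * (t - 1999)))
  expect_lt(line$gamma, 1e-9)

  expect_error(fit_season_trend(make_ts(t[1:5], y[1:5])), "at least 8")
  tshort <- seq(2000.0, 2000.9, length.out = 20)
  expect_error(fit_season_trend(make_ts(tshort, sin(2 * pi * tshort))),
               "one year")
})

test_that("robust fits equal OLS on noiseless inputs", {
  t <- irregular_times(90, seed = 9)
  y <- 0.5 - 0.01 * (t - 1999) + 0.05 * sin(2 * pi * t - 1)
  fit <- fit_season_trend(make_ts(t, y))
  X <- cbind(1, t - 1999, sin(2 * pi * t), cos(2 * pi * t))
  ols <- qr.solve(X, y)
  expect_equal(fit$alpha, unname(ols[1]), tolerance = 1e-8)
  expect_equal(fit$beta, unname(ols[2]), tolerance = 1e-8)
  expect_equal(fit$gamma, sqrt(ols[3]^2 + ols[4]^2), tolerance = 1e-8)
})

test_that("tidiers and prediction are consistent", {
  t <- irregular_times(100, seed = 11)
  y <- 0.3 + 0.05 * sin(2 * pi * t + 1)
  fit <- fit_season_trend(make_ts(t, y))
  td <- tidy(fit)
  expect_identical(td$term, c("alpha", "beta", "gamma", "delta"))
  expect_equal(glance(fit)$gamma, td$estimate[3])
  expect_equal(predict(fit), y, tolerance = 1e-6)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("break scan finds abrupt drops and stays quiet on stable series", {
  hits <- 0; located <- 0
  for (s in 1:15) {
    sm <- sampling_model(noise_sd = 0.02, outlier_prob = 0, dropout_prob = 0.3,
                         seed = s)
    pr <- trajectory_params(alpha1 = 0.4, gamma1 = 0.03,
                            alpha2 = 0.4 - 5 * 0.02, gamma2 = 0.03,
                            break_time = 2007.5, change_class = "DEF")
    ts <- generate_timeseries(pr, sm)
    br <- detect_single_break(ts)
    if (isTRUE(br$has_break)) {
      hits <- hits + 1
      truth_idx <- which(ts$time >= 2007.5)[1]
      if (abs(br$break_index - truth_idx) <= 5) located <- located + 1
    }
  }
  expect_gte(located, 13)

  false_pos <- 0
  for (s in 1:15) {
    sm <- sampling_model(noise_sd = 0.02, outlier_prob = 0, dropout_prob = 0.3,
                         seed = 100 + s)
    pr <- trajectory_params(alpha1 = 0.4, gamma1 = 0.03)
    if (isTRUE(detect_single_break(generate_timeseries(pr, sm))$has_break)) {
      false_pos <- false_pos + 1
    }
  }
  expect_lte(false_pos, 3)
})

test_that("short series yield a degenerate no-break result", {
  t <- irregular_times(10, seed = 5)
  br <- detect_single_break(make_ts(t, rnorm(10)))
  expect_false(br$has_break)
  expect_true(br$degenerate)
  expect_true(is.na(br$bic1))
})

test_that("metric vectors duplicate segment 2 when no break and split when broken", {
  sm <- sampling_model(noise_sd = 0.01, outlier_prob = 0, seed = 14)
  stable <- generate_timeseries(
    trajectory_params(alpha1 = 0.35, gamma1 = 0.03), sm)
  m <- extract_metrics(list(NIR = stable))
  expect_identical(m$NIR_gamma2, m$NIR_gamma1)
  expect_identical(m$NIR_beta2, m$NIR_beta1)

  def <- generate_timeseries(
    trajectory_params(alpha1 = 0.35, gamma1 = 0.03, alpha2 = 0.2,
                      gamma2 = 0.015, break_time = 2008,
                      change_class = "DEF"), sm)
  md <- extract_metrics(list(NIR = def))
  # segment fits differ beyond noise: amplitude halves across the break
  expect_gt(abs(md$NIR_gamma1 - md$NIR_gamma2), 0.005)
})

test_that("a 14-band input yields 84 metrics in canonical band-major order", {
  sm <- sampling_model(noise_sd = 0.01, seed = 20)
  ts <- generate_timeseries(trajectory_params(alpha1 = 0.3, gamma1 = 0.02), sm)
  series <- setNames(replicate(14, ts, simplify = FALSE), lts_bands())
  m <- extract_metrics(series)
  expect_identical(ncol(m), 84L)
  expect_identical(names(m)[1:6], paste0("B_", lts_metrics()))
  expect_identical(names(m), metric_columns(lts_bands()))
})

test_that("an empty or short band series is reported and set to missing", {
  sm <- sampling_model(noise_sd = 0.01, seed = 25)
  good <- generate_timeseries(trajectory_params(alpha1 = 0.3), sm)
  short <- good[1:3, ]
  expect_message(
    m <- extract_metrics(list(NIR = good, SWIR2 = short)),
    "SWIR2"
  )
  expect_true(all(is.na(m[paste0("SWIR2_", lts_metrics())])))
  expect_false(anyNA(m[paste0("NIR_", lts_metrics())]))
})

test_that("corrupting 10% of observations barely moves the robust slope", {
  # robustness contract: corruption shifts the fitted slope by less than
  # 3x the shift seen between two clean noise draws
  base_shift <- c(); corr_shift <- c()
  for (s in 1:10) {
    withr::with_seed(s, {
      t <- sort(runif(200, 1999, 2015))
      y1 <- 0.4 + 0.01 * (t - 1999) + rnorm(200, sd = 0.01)
      y2 <- 0.4 + 0.01 * (t - 1999) + rnorm(200, sd = 0.01)
      yc <- y1; idx <- sample(200, 20); yc[idx] <- yc[idx] - 0.3
    })
    s1 <- fit_rlm_trend(make_ts(t, y1))$rlm_slope
    s2 <- fit_rlm_trend(make_ts(t, y2))$rlm_slope
    sc_ <- fit_rlm_trend(make_ts(t, yc))$rlm_slope
    base_shift <- c(base_shift, abs(s2 - s1))
    corr_shift <- c(corr_shift, abs(sc_ - s1))
  }
  expect_lt(mean(corr_shift), 3 * mean(base_shift) + 1e-4)
})
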