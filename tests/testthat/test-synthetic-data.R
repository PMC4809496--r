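test_that("noiseless generation reproduces the season-trend curve exactly", {
  pr <- trajectory_params(alpha1 = 0.3, beta1 = 0.01, gamma1 = 0.05,
                          delta1 = 1.2)
  sm <- sampling_model(noise_sd = 0, outlier_prob = 0, dropout_prob = 0.2,
                       seed = 7)
  ts <- generate_timeseries(pr, sm)
  expect_true(all(diff(ts$time) > 0))
  expect_equal(ts$value, eval_trajectory(pr, ts$time), tolerance = 1e-12)
})

test_that("generators are deterministic under a fixed seed", {
  pr <- trajectory_params(alpha1 = 0.3, gamma1 = 0.04)
  sm <- sampling_model(seed = 99)
  expect_identical(generate_timeseries(pr, sm), generate_timeseries(pr, sm))

  sc1 <- generate_scene(6, 6, n_dates = 30, sampling = sampling_model(seed = 5))
  sc2 <- generate_scene(6, 6, n_dates = 30, sampling = sampling_model(seed = 5))
  expect_identical(sc1$truth_class, sc2$truth_class)
  expect_identical(sc1$bands, sc2$bands)

  r1 <- generate_reports(sc1, 15, seed = 3)
  r2 <- generate_reports(sc1, 15, seed = 3)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("sample variance of a seasonal series matches gamma^2/2 + sigma^2", {
  # Closed form: a sinusoid of amplitude g sampled uniformly over whole
  # cycles has variance g^2/2; independent Gaussian noise adds sigma^2.
  g <- 0.3; s <- 0.01
  pr <- trajectory_params(alpha1 = 0.5, beta1 = 0, gamma1 = g)
  sm <- sampling_model(start_time = 1999, end_time = 2015, mean_revisit = 16,
                       dropout_prob = 0.15, outlier_prob = 0, noise_sd = s,
                       seed = 42)
  ts <- generate_timeseries(pr, sm)
  expect_gt(nrow(ts), 250)
  expected <- g^2 / 2 + s^2
  expect_lt(abs(var(ts$value) - expected) / expected, 0.2)
})

test_that("sub-annual windows are rejected", {
  expect_error(
    generate_timeseries(trajectory_params(alpha1 = 0.1),
                        sampling_model(start_time = 2000, end_time = 2000.5)),
    "one year"
  )
})

test_that("degenerate class mixtures and scene truth behave as declared", {
  sc <- generate_scene(5, 5, n_dates = 24, class_fractions = c(NOCH = 1),
                       sampling = sampling_model(seed = 2))
  expect_true(all(sc$truth_class == "NOCH"))
  expect_error(
    generate_scene(2, 2, n_dates = 24,
                   class_fractions = c(DEF = 0.05, NOCH = 0.95),
                   sampling = sampling_model(seed = 2)),
    "zero pixels"
  )
})

test_that("deforested pixels drop in post-break NIR and classes order in SWIR2", {
  sc <- generate_scene(14, 14, n_dates = 50,
                       sampling = sampling_model(seed = 17, noise_sd = 0.01))
  tp <- sc$truth_params
  def <- tp[tp$change_class == "DEF", ]
  drops <- vapply(seq_len(nrow(def)), function(i) {
    nir <- sc$bands$NIR[def$row[i], def$col[i], ]
    pre <- mean(nir[sc$dates < def$break_time[i]])
    post <- mean(nir[sc$dates >= def$break_time[i]])
    post < pre
  }, logical(1))
  expect_gte(mean(drops), 0.95)

  # post-change SWIR2 population ordering NOCH < DEG < DEF
  late <- sc$dates >= max(sc$dates) - 2
  mean_swir2 <- function(cls) {
    px <- tp[tp$change_class == cls, ]
    mean(vapply(seq_len(nrow(px)), function(i) {
      mean(sc$bands$SWIR2[px$row[i], px$col[i], late])
    }, numeric(1)))
  }
  expect_lt(mean_swir2("NOCH"), mean_swir2("DEG"))
  expect_lt(mean_swir2("DEG"), mean_swir2("DEF"))
})

test_that("report streams honour labels, phases and noise rates", {
  sc <- small_scene()
  rep0 <- generate_reports(sc, 30, label_noise = 0, seed = 8)
  truth <- sc$truth_class[cbind(rep0$row, rep0$col)]
  expect_identical(rep0$label, truth)
  expect_identical(rep0$true_class, truth)
  expect_false(is.unsorted(rep0$timestamp))

  # partition: phase counts sum to n_reports for arbitrary boundaries
  for (b in list(c(2003, 2010), c(1999.5, 2014.9), c(2007, 2007.1))) {
    r <- generate_reports(sc, 25, phase_boundaries = b, seed = 9)
    expect_identical(nrow(r), 25L)
    expect_identical(sum(table(factor(r$phase, c("A", "B", "C")))), 25L)
  }

  # binomial check on the label-noise rate
  big <- generate_scene(24, 24, n_dates = 30,
                        class_fractions = c(DEF = 0.45, DEG = 0.45, NOCH = 0.1),
                        sampling = sampling_model(seed = 77))
  rn <- generate_reports(big, 500, label_noise = 0.2, seed = 10,
                         noch_fraction = 0.1)
  disagree <- mean(rn$label != rn$true_class)
  expect_lt(abs(disagree - 0.2), 0.04)
})

test_that("report demand beyond available disturbed pixels errors", {
  sc <- generate_scene(4, 4, n_dates = 24,
                       class_fractions = c(DEF = 0.25, DEG = 0.25, NOCH = 0.5),
                       sampling = sampling_model(seed = 12))
  expect_error(generate_reports(sc, 100, seed = 1, noch_fraction = 0),
               "exceeds")
})

test_that("accessibility-biased sampling skews report locations; uniform does not", {
  big <- generate_scene(20, 20, n_dates = 24,
                        class_fractions = c(DEF = 0.5, DEG = 0.5),
                        sampling = sampling_model(seed = 55))
  biased <- generate_reports(big, 150, seed = 4, noch_fraction = 0)
  expect_gt(mean(biased$col), 10.5)  # gradient favours high columns
})
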