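# Small shared training set: well-separated synthetic classes.
train_small <- local({
  tr <- NULL
  function() {
    if (is.null(tr)) tr <<- simulate_training_set(40, n_dates = 40, seed = 303)
    tr
  }
})

test_that("training reports OOB errors and is seed-deterministic", {
  tr <- train_small()
  m1 <- train_change_model(tr, n_trees = 300, seed = 5)
  m2 <- train_change_model(tr, n_trees = 300, seed = 5)
  expect_identical(oob_report(m1), oob_report(m2))
  rep <- oob_report(m1)
  expect_true(rep$overall_error >= 0 && rep$overall_error <= 1)
  expect_identical(sort(names(rep$class_errors)), sort(c("DEF", "DEG", "NOCH")))
  # confusion row sums equal class sample counts
  expect_equal(unname(rowSums(rep$confusion)),
               unname(as.vector(table(tr$label))))
  expect_s3_class(glance(m1), "tbl_df")
})

test_that("degenerate training inputs error informatively", {
  tr <- train_small()
  one_class <- dplyr::filter(tr, label == "DEF")
  expect_error(train_change_model(one_class, n_trees = 50, seed = 1),
               "2 classes")
  tiny <- dplyr::bind_rows(head(dplyr::filter(tr, label == "DEF"), 3),
                           head(dplyr::filter(tr, label == "NOCH"), 30))
  expect_error(train_change_model(tiny, n_trees = 50, seed = 1),
               "fewer than 10")
})

test_that("probabilities are vote fractions summing to one", {
  tr <- train_small()
  m <- train_change_model(tr, n_trees = 300, seed = 5)
  p <- predict_change_prob(m, tr)
  expect_identical(nrow(p), nrow(tr))
  expect_lt(max(abs(rowSums(as.matrix(p)) - 1)), 1e-12)
  # deep-in-cluster self-consistency: modal class equals the label
  modal <- m$classes[max.col(as.matrix(p))]
  expect_gt(mean(modal == tr$label), 0.95)
  # empty input -> empty output
  p0 <- predict_change_prob(m, tr[0, ])
  expect_identical(nrow(p0), 0L)
  expect_error(predict_change_prob(m, tr[, 1:4]), "missing covariate")
})

test_that("covariate reduction subsets columns and preserves rows", {
  tr <- train_small()
  red <- reduce_covariates(tr, reduced_covariate_set())
  expect_identical(nrow(red), nrow(tr))
  expect_identical(sum(!names(red) %in% c("label", "row", "col")), 14L)
  expect_identical(reduce_covariates(tr, metric_columns(c("SWIR2", "TCW", "G"))),
                   tr[c("row", "col", "label",
                        metric_columns(c("SWIR2", "TCW", "G")))])
  expect_error(reduce_covariates(tr, "XYZ_gamma1"), "unknown column")
  expect_error(reduce_covariates(tr, character()), "at least one")
})

test_that("normalized-rank scores honour the analytic extremes", {
  n <- 14; N <- 50
  withr::with_seed(1, {
    ranks <- t(replicate(N, sample(1:(n - 1))))
  })
  ranks <- cbind(ranks[, 1:(n - 2)], top = n, bottom = ranks[, n - 1])
  ranks[, "bottom"] <- 1
  colnames(ranks) <- c(paste0("b", 1:(n - 2)), "top", "bottom")
  # re-rank middle columns to keep each row a permutation of 1..n
  for (i in 1:N) {
    mid <- ranks[i, 1:(n - 2)]
    ranks[i, 1:(n - 2)] <- rank(mid) + 1
  }
  s <- importance_scores(ranks)
  expect_identical(unname(s["top"]), 1)
  expect_identical(unname(s["bottom"]), 0)
  # n=3, N=2, ranks (3, 1) -> 0.5
  expect_equal(unname(importance_scores(
    matrix(c(3, 1, 1, 3, 2, 2), nrow = 2))[1]), 0.5)
})

test_that("score computation equals a direct double-loop oracle", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      n <- sample(3:14, 1); N <- sample(5:40, 1)
      ranks <- t(replicate(N, sample(n)))
      s <- importance_scores(ranks)
      oracle <- numeric(n)
      for (j in 1:n) {
        acc <- 0
        for (i in 1:N) acc <- acc + (ranks[i, j] - 1) / (n - 1)
        oracle[j] <- acc / N
      }
      expect_equal(unname(s), oracle, tolerance = 1e-12)
      expect_true(all(s >= 0 & s <= 1))
    }
  })
  expect_error(importance_scores(matrix(1, 5, 1)), "at least 2")
  expect_error(importance_scores(matrix(c(1, 5), 1, 2)), "1..n")
})

test_that("single-band scoring ranks the informative band highest", {
  tr <- train_small()
  # G's RLM metrics separate classes worse than SWIR2's full set on this
  # generator; check rank accounting rather than a specific ordering
  st <- score_band_importance(tr, bands = c("SWIR2", "TCW", "G"),
                              n_iter = 3, n_trees = 100, seed = 2)
  expect_s3_class(st, "importance_score_table")
  expect_true(all(st$scores$score >= 0 & st$scores$score <= 1))
  for (cr in names(st$ranks)) {
    for (i in seq_len(nrow(st$ranks[[cr]]))) {
      expect_identical(unname(sort(st$ranks[[cr]][i, ])), 1:3)
    }
  }
  expect_identical(sort(unique(st$scores$criterion)),
                   sort(c("OVERALL", "DEF", "DEG", "NOCH")))
  expect_s3_class(tidy(st), "tbl_df")
  expect_error(score_band_importance(tr, bands = "SWIR2", n_iter = 1),
               "at least 2 bands")
})

test_that("rank ties break deterministically by canonical band order", {
  # equal accuracies: the band earlier in canonical order wins the top rank
  r <- ltschange:::rank_accuracies(c(0.8, 0.8, 0.5), band_order = c(1, 2, 3))
  expect_identical(r, c(3L, 2L, 1L))
})

test_that("phased updating trains on A, validates on B, then fuses A+B for C", {
  sc <- generate_scene(16, 16, n_dates = 40,
                       sampling = sampling_model(seed = 71))
  rep <- generate_reports(sc, 150, label_noise = 0,
                          phase_boundaries = c(2007.5, 2011.5), seed = 72)
  met <- scene_metrics(sc, unique(rep[c("row", "col")]),
                       bands = c("SWIR2", "TCW", "G"))
  iu <- iterative_update(rep, met, n_trees = 200, seed = 3)
  expect_identical(sort(unique(iu$validation$phase_model)),
                   c("operational", "training"))
  expect_lt(unname(iu$sizes["A"]), unname(iu$sizes["A"] + iu$sizes["B"]))
  expect_true(all(abs(rowSums(as.matrix(
    iu$validation[paste0("P_", iu$models$training$classes)])) - 1) < 1e-12))
  expect_s3_class(glance(iu), "tbl_df")
  expect_s3_class(plot_phase_probabilities(iu), "ggplot")

  no_b <- dplyr::filter(rep, phase != "B")
  expect_error(iterative_update(no_b, met), "period B is empty")
  no_c <- dplyr::filter(rep, phase != "C")
  expect_warning(iterative_update(no_c, met, n_trees = 100, seed = 1),
                 "period C")
})
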