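# Columns of a training tibble that are metadata, never covariates.
META_COLS <- c("label", "true_class", "report_id", "timestamp", "phase",
               "row", "col", "lon", "lat", "location_id",
               "canopy_cover_pct", "disturbance_evidence", "forest_status",
               "provisional_label", "final_label")

covariate_cols <- function(data) setdiff(names(data), META_COLS)

#' Train the random-forest change classifier
#'
#' Fits a bootstrap-aggregated classification forest predicting change class
#' (`DEF`, `DEG`, `NOCH`) from spectral-temporal metric columns, and reports
#' the internal out-of-bag (OOB) error: each sample is judged by the trees
#' whose bootstrap excluded it. Rows with missing covariates are dropped
#' with a message (forests require complete rows).
#'
#' @param data A tibble with a `label` column (character or factor over the
#'   change classes) and one numeric column per covariate; recognised
#'   metadata columns (`report_id`, `timestamp`, `phase`, coordinates, ...)
#'   are ignored.
#' @param n_trees Number of trees (default 7000, the full-model setting;
#'   smaller counts are appropriate for repeated scoring runs).
#' @param seed Integer seed; identical seeds give identical forests.
#' @param ... Passed to [randomForest::randomForest()].
#' @return An object of class `change_model`: the fitted ensemble plus an
#'   OOB report. Use [glance()] for the error summary and
#'   [oob_report()] for the full confusion matrix.
#' @export
train_change_model <- function(data, n_trees = 7000, seed = 1L, ...) {
  if (!"label" %in% names(data)) abort("`data` must have a `label` column.")
  covs <- covariate_cols(data)
  if (length(covs) == 0) abort("no covariate columns found.")
  x <- as.data.frame(data[covs])
  ok <- complete.cases(x)
  if (any(!ok)) {
    inform(sprintf("dropping %d rows with missing covariates.", sum(!ok)))
    x <- x[ok, , drop = FALSE]
  }
  y <- factor(as.character(data$label)[ok])
  if (nlevels(y) < 2) abort("training data must contain at least 2 classes.")
  tab <- table(y)
  if (any(tab < 10)) {
    abort(paste0("fewer than 10 samples for class: ",
                 names(tab)[which(tab < 10)[1]]))
  }
  rf <- withr_seed(seed, {
    randomForest::randomForest(x = x, y = y, ntree = n_trees, ...)
  })
  conf <- rf$confusion[, levels(y), drop = FALSE]
  class_errors <- rf$confusion[, "class.error"]
  overall <- unname(rf$err.rate[n_trees, "OOB"])
  structure(
    list(forest = rf, schema = covs, n_trees = n_trees, seed = seed,
         classes = levels(y),
         oob = list(overall_error = overall,
                    class_errors = class_errors,
                    confusion = conf)),
    class = "change_model"
  )
}

#' @export
print.change_model <- function(x, ...) {
  cat(sprintf("<change_model> %d trees, %d covariates, classes: %s\n",
              x$n_trees, length(x$schema), paste(x$classes, collapse = ", ")))
  cat(sprintf("OOB error: %.1f%% (%s)\n", 100 * x$oob$overall_error,
              paste(sprintf("%s %.1f%%", names(x$oob$class_errors),
                            100 * x$oob$class_errors), collapse = ", ")))
  invisible(x)
}

#' @export
glance.change_model <- function(x, ...) {
  out <- tibble(n_trees = x$n_trees, n_covariates = length(x$schema),
                overall_oob_error = x$oob$overall_error)
  for (cl in names(x$oob$class_errors)) {
    out[[paste0("oob_error_", cl)]] <- unname(x$oob$class_errors[[cl]])
  }
  out
}

#' Out-of-bag error report of a fitted change model
#'
#' @param model A `change_model`.
#' @return A list with `overall_error`, `class_errors` and the `confusion`
#'   matrix (rows = reference class, columns = OOB-predicted class; row sums
#'   equal per-class sample counts).
#' @export
oob_report <- function(model) {
  stopifnot(inherits(model, "change_model"))
  model$oob
}

#' Predict vote-fraction class probabilities
#'
#' Class probabilities are the fraction of trees voting for each class, the
#' quantity used both for phase validation and probability mapping. Rows sum
#' to 1 exactly.
#'
#' @param model A `change_model`.
#' @param newdata A tibble containing every covariate column of the model's
#'   schema (extra columns are ignored).
#' @return A tibble with one probability column per class, named `P_<class>`.
#' @export
predict_change_prob <- function(model, newdata) {
  stopifnot(inherits(model, "change_model"))
  missing_col <- setdiff(model$schema, names(newdata))
  if (length(missing_col)) {
    abort(paste0("missing covariate column: ", missing_col[1]))
  }
  if (nrow(newdata) == 0) {
    out <- lapply(model$classes, function(cl) numeric(0))
    names(out) <- paste0("P_", model$classes)
    return(as_tibble(out))
  }
  p <- predict(model$forest, as.data.frame(newdata[model$schema]),
               type = "prob")
  out <- as_tibble(as.data.frame(p))
  names(out) <- paste0("P_", colnames(p))
  out
}

#' Subset the covariate columns of a training set
#'
#' Returns a copy of `data` keeping metadata columns and only the requested
#' covariates, e.g. the reduced mapping set of [reduced_covariate_set()].
#'
#' @param data A training tibble.
#' @param keep Character vector of covariate column names to retain.
#' @return The column-subset tibble (rows, labels and metadata preserved).
#' @export
reduce_covariates <- function(data, keep) {
  if (length(keep) == 0) abort("`keep` must name at least one covariate.")
  unknown <- setdiff(keep, names(data))
  if (length(unknown)) abort(paste0("unknown column: ", unknown[1]))
  meta <- intersect(names(data), META_COLS)
  data[c(meta, keep)]
}

#' Phased iterative model updating
#'
#' Runs the two-phase protocol for absorbing a continuous local-expert data
#' stream. Training phase: a forest is fit on reports from period A and
#' validated by predicting class probabilities for period-B locations,
#' grouped by their reference label. Operational phase: the forest is refit
#' on A and B together and validated on period C. The returned probability
#' distributions are the boxplot data for judging whether accumulating
#' reports sharpens the classifier.
#'
#' @param reports A report tibble (e.g. from [generate_reports()]) with
#'   `location_id` or `row`/`col` identifying the pixel, a `phase` column
#'   (`"A"`, `"B"`, `"C"`) and a `label` column.
#' @param metrics A tibble of metric columns keyed by the same identifier
#'   (`location_id` or `row`+`col`), one row per location.
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed.
#' @return An object of class `iterative_update`: list with `models`
#'   (training and operational `change_model`s) and `validation`, a tibble
#'   of per-location predicted probabilities with columns `phase_model`
#'   (`"training"`/`"operational"`), `ref_label`, `P_<class>` and
#'   `P_correct` (probability assigned to the reference class).
#' @export
iterative_update <- function(reports, metrics, n_trees = 500, seed = 1L) {
  key <- if ("location_id" %in% names(reports) &&
             "location_id" %in% names(metrics)) "location_id" else c("row", "col")
  if (!all(key %in% names(reports)) || !all(key %in% names(metrics))) {
    abort("`reports` and `metrics` must share `location_id` or `row`/`col` keys.")
  }
  if (!"phase" %in% names(reports)) abort("`reports` must have a `phase` column.")
  joined <- dplyr::inner_join(reports, metrics, by = key)
  a <- dplyr::filter(joined, .data$phase == "A")
  b <- dplyr::filter(joined, .data$phase == "B")
  cc <- dplyr::filter(joined, .data$phase == "C")
  if (nrow(a) == 0) abort("period A is empty.")
  if (nrow(b) == 0) abort("period B is empty.")
  validate <- function(model, newdata, tag) {
    p <- predict_change_prob(model, newdata)
    p$ref_label <- as.character(newdata$label)
    p$phase_model <- tag
    pc <- paste0("P_", p$ref_label)
    p$P_correct <- vapply(seq_len(nrow(p)), function(i) {
      if (pc[i] %in% names(p)) p[[pc[i]]][i] else NA_real_
    }, numeric(1))
    p
  }
  m_train <- train_change_model(a, n_trees = n_trees, seed = seed)
  val_b <- validate(m_train, b, "training")
  m_oper <- train_change_model(dplyr::bind_rows(a, b), n_trees = n_trees,
                               seed = seed + 1L)
  if (nrow(cc) == 0) {
    warn("period C is empty: operational validation skipped.")
    val_c <- val_b[0, ]
  } else {
    val_c <- validate(m_oper, cc, "operational")
  }
  structure(
    list(models = list(training = m_train, operational = m_oper),
         validation = dplyr::bind_rows(val_b, val_c),
         sizes = c(A = nrow(a), B = nrow(b), C = nrow(cc))),
    class = "iterative_update"
  )
}

#' @export
print.iterative_update <- function(x, ...) {
  cat(sprintf("<iterative_update> |A|=%d |B|=%d |C|=%d\n",
              x$sizes["A"], x$sizes["B"], x$sizes["C"]))
  print(glance(x))
  invisible(x)
}

#' @export
glance.iterative_update <- function(x, ...) {
  x$validation |>
    dplyr::group_by(.data$phase_model, .data$ref_label) |>
    dplyr::summarise(n = dplyr::n(),
                     median_P_correct = median(.data$P_correct),
                     .groups = "drop")
}

#' Normalized-rank importance scores from a rank matrix
#'
#' Implements the averaged normalized-rank score: given ranks `x[i, j]` of
#' band j in iteration i (bottom rank 1, top rank n over the n bands),
#'
#'   S_j = (1/N) * sum_i (x[i, j] - 1) / (n - 1)
#'
#' so S = 1 means top-ranked in every iteration and S = 0 bottom-ranked in
#' every iteration.
#'
#' @param ranks An `N x n` integer matrix (iterations by bands) with values
#'   in `1..n`; column names identify bands.
#' @return A named numeric vector of scores in `[0, 1]`.
#' @export
#' @examples
#' importance_scores(matrix(c(3, 3, 1, 1, 2, 2), nrow = 2,
#'                          dimnames = list(NULL, c("a", "b", "c"))))
importance_scores <- function(ranks) {
  ranks <- as.matrix(ranks)
  n <- ncol(ranks)
  if (n < 2) abort("at least 2 bands are required.")
  if (any(ranks < 1 | ranks > n)) abort("ranks must lie in 1..n.")
  colMeans((ranks - 1) / (n - 1))
}

# Rank a vector of accuracies bottom=1 .. top=n, breaking ties by canonical
# band order (earlier band wins the higher rank) so results are
# reproducible independently of RNG state.
rank_accuracies <- function(acc, band_order) {
  n <- length(acc)
  ord <- order(acc, -band_order)  # ascending accuracy; later band loses ties
  r <- integer(n)
  r[ord] <- seq_len(n)
  r
}

#' Score per-band importance by repeated single-band forests
#'
#' For each of `n_iter` iterations, fits one forest per spectral band using
#' only that band's six temporal metrics, measures single-band accuracy as
#' 1 − OOB error (overall and per class), ranks the bands per criterion
#' (bottom = 1, top = n), and averages normalized ranks over iterations via
#' [importance_scores()]. This sidesteps the instability and
#' correlated-covariate ambiguity of within-forest importance measures.
#'
#' @param data A training tibble containing `label` and the six metric
#'   columns for every band in `bands`.
#' @param bands Bands to score (default: every band whose columns are
#'   present, in canonical order).
#' @param n_iter Number of scoring iterations (default 1000).
#' @param n_trees Trees per single-band forest (default 500; the full
#'   7000-tree setting is unnecessary for ranking stability).
#' @param seed Integer seed; iteration i uses `seed + i` for every band so
#'   bands differ only in covariates, not in bootstrap luck.
#' @return An object of class `importance_score_table`: list with `scores`
#'   (tibble: `band`, `criterion` in OVERALL/DEF/DEG/NOCH, `score`) and
#'   `ranks` (named list of `N x n` rank matrices per criterion).
#' @export
score_band_importance <- function(data, bands = NULL, n_iter = 1000,
                                  n_trees = 500, seed = 1L) {
  if (is.null(bands)) {
    bands <- LTS_BANDS[vapply(LTS_BANDS, function(b) {
      all(metric_columns(b) %in% names(data))
    }, logical(1))]
  }
  n <- length(bands)
  if (n < 2) abort("at least 2 bands are required.")
  missing_col <- setdiff(unlist(lapply(bands, metric_columns)), names(data))
  if (length(missing_col)) abort(paste0("missing column: ", missing_col[1]))
  classes <- sort(unique(as.character(data$label)))
  criteria <- c("OVERALL", classes)
  ranks <- lapply(criteria, function(cr) {
    matrix(NA_integer_, n_iter, n, dimnames = list(NULL, bands))
  })
  names(ranks) <- criteria
  band_order <- match(bands, LTS_BANDS)
  for (i in seq_len(n_iter)) {
    acc <- matrix(NA_real_, length(criteria), n,
                  dimnames = list(criteria, bands))
    for (j in seq_len(n)) {
      m <- train_change_model(
        data[c("label", metric_columns(bands[j]))],
        n_trees = n_trees, seed = seed + i
      )
      acc["OVERALL", j] <- 1 - m$oob$overall_error
      for (cl in classes) {
        acc[cl, j] <- 1 - unname(m$oob$class_errors[[cl]])
      }
    }
    for (cr in criteria) {
      ranks[[cr]][i, ] <- rank_accuracies(acc[cr, ], band_order)
    }
  }
  scores <- purrr::map_dfr(criteria, function(cr) {
    tibble(band = bands, criterion = cr,
           score = unname(importance_scores(ranks[[cr]])))
  })
  structure(list(scores = scores, ranks = ranks, n_iter = n_iter),
            class = "importance_score_table")
}

#' @export
print.importance_score_table <- function(x, ...) {
  cat(sprintf("<importance_score_table> %d iterations\n", x$n_iter))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
tidy.importance_score_table <- function(x, ...) {
  tidyr::pivot_wider(x$scores, names_from = "criterion",
                     values_from = "score")
}
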