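#' Build a baseline forest mask from NDVI
#'
#' Marks as forest every pixel whose NDVI at (or shortly after) the baseline
#' date reaches the threshold. For each pixel the earliest clear (valid)
#' acquisition from `baseline_date - tolerance` onwards is used — a
#' cloud-obscured baseline falls through to the next clear date; a pixel
#' with no clear acquisition at all is non-forest. A classified mask from an
#' external source can be substituted wherever a forest mask is accepted —
#' the mask source is pluggable.
#'
#' @param stack A `scene_stack`.
#' @param baseline_date Decimal year of the baseline (default: earliest
#'   acquisition).
#' @param ndvi_threshold NDVI at/above which a pixel counts as forest
#'   (default 0.6, appropriate for the synthetic reflectance populations).
#' @param tolerance Search half-window in years around the baseline
#'   (default 1).
#' @return A logical `n_rows x n_cols` matrix (`TRUE` = forest).
#' @export
build_forest_mask <- function(stack, baseline_date = NULL,
                              ndvi_threshold = 0.6, tolerance = 1) {
  stopifnot(inherits(stack, "scene_stack"))
  baseline_date <- baseline_date %||% min(stack$dates)
  if (!any(abs(stack$dates - baseline_date) <= tolerance)) {
    abort("no acquisition within tolerance of the baseline date.")
  }
  candidates <- which(stack$dates >= baseline_date - tolerance)
  ndvi <- index_from_bands(stack$bands, "NDVI")
  mask <- matrix(FALSE, stack$n_rows, stack$n_cols)
  for (r in seq_len(stack$n_rows)) {
    for (cc in seq_len(stack$n_cols)) {
      ok <- candidates[stack$valid[r, cc, candidates] &
                         !is.na(ndvi[r, cc, candidates])]
      if (length(ok)) {
        mask[r, cc] <- ndvi[r, cc, ok[1]] >= ndvi_threshold
      }
    }
  }
  mask
}

# Bands whose metrics a covariate schema needs, in canonical order.
schema_bands <- function(schema) {
  bands <- unique(sub("_(rlm_intercept|rlm_slope|gamma1|gamma2|beta1|beta2)$",
                      "", schema))
  unknown <- setdiff(bands, LTS_BANDS)
  if (length(unknown)) abort(paste0("schema references unknown band: ", unknown[1]))
  LTS_BANDS[LTS_BANDS %in% bands]
}

#' Compute metric rows for selected pixels of a scene
#'
#' Extracts each pixel's valid series for the requested bands (derived
#' bands computed on the fly) and runs the temporal-metric pipeline,
#' returning one row per pixel keyed by `row`/`col`. Pixels whose series
#' are too short get `NA` metrics.
#'
#' @param stack A `scene_stack`.
#' @param pixels A tibble with `row` and `col` columns (default: all
#'   pixels).
#' @param bands Bands to compute metrics for.
#' @param coeffs Tasseled-cap coefficients.
#' @param min_obs Minimum valid observations per band series.
#' @return A tibble: `row`, `col`, then `<band>_<metric>` columns.
#' @export
scene_metrics <- function(stack, pixels = NULL, bands = c("SWIR2", "TCW", "G"),
                          coeffs = tc_coefficients(), min_obs = 8) {
  stopifnot(inherits(stack, "scene_stack"))
  if (is.null(pixels)) {
    pixels <- expand.grid(row = seq_len(stack$n_rows),
                          col = seq_len(stack$n_cols))
  }
  rows <- lapply(seq_len(nrow(pixels)), function(i) {
    series <- lapply(bands, function(b) {
      extract_pixel_series(stack, pixels$row[i], pixels$col[i], b, coeffs)
    })
    names(series) <- bands
    m <- suppressMessages(extract_metrics(series, min_obs = min_obs))
    dplyr::bind_cols(tibble(row = pixels$row[i], col = pixels$col[i]), m)
  })
  dplyr::bind_rows(rows)
}

#' Map change-class probabilities across a scene
#'
#' Applies a trained (typically reduced-covariate) change model to every
#' forest pixel of a scene: the pixel's series are extracted, the model's
#' metric schema computed, and vote-fraction probabilities predicted.
#' Non-forest pixels and pixels with insufficient valid observations are
#' nodata in all classes (their count is reported in a message). Results
#' are independent of pixel processing order.
#'
#' @param stack A `scene_stack`.
#' @param model A `change_model` whose schema is computable from the
#'   stack's bands.
#' @param mask A logical forest mask from [build_forest_mask()] (or an
#'   external source); dimensions must match the scene.
#' @param coeffs Tasseled-cap coefficients.
#' @param min_obs Minimum valid observations per band series.
#' @return An object of class `probability_maps`: list with `prob` (named
#'   list of `n_rows x n_cols` matrices, one per class, `NA` = nodata),
#'   `nodata` (logical matrix), `classes`, and `modal` (character matrix of
#'   the modal class at valid pixels).
#' @export
map_change <- function(stack, model, mask, coeffs = tc_coefficients(),
                       min_obs = 8) {
  stopifnot(inherits(stack, "scene_stack"), inherits(model, "change_model"))
  if (!all(dim(mask) == c(stack$n_rows, stack$n_cols))) {
    abort("forest mask dimensions do not match the scene.")
  }
  bands <- schema_bands(model$schema)
  miss <- setdiff(intersect(bands, LTS_REFLECTANCE_BANDS), names(stack$bands))
  if (length(miss)) abort(paste0("scene lacks band required by the model: ", miss[1]))
  pixels <- which(mask, arr.ind = TRUE)
  prob <- lapply(model$classes, function(cl) {
    matrix(NA_real_, stack$n_rows, stack$n_cols)
  })
  names(prob) <- model$classes
  modal <- matrix(NA_character_, stack$n_rows, stack$n_cols)
  n_short <- 0L
  if (nrow(pixels) > 0) {
    met <- scene_metrics(stack, as.data.frame(pixels), bands, coeffs, min_obs)
    ok <- complete.cases(met[model$schema])
    n_short <- sum(!ok)
    if (any(ok)) {
      p <- predict_change_prob(model, met[ok, ])
      idx <- cbind(met$row[ok], met$col[ok])
      for (cl in model$classes) {
        prob[[cl]][idx] <- p[[paste0("P_", cl)]]
      }
      modal[idx] <- model$classes[max.col(as.matrix(p), ties.method = "first")]
    }
  }
  if (n_short > 0) {
    inform(sprintf("%d forest pixels had insufficient observations and are nodata.",
                   n_short))
  }
  structure(
    list(prob = prob, nodata = is.na(prob[[1]]), classes = model$classes,
         modal = modal),
    class = "probability_maps"
  )
}

#' @export
print.probability_maps <- function(x, ...) {
  cat(sprintf("<probability_maps> %d x %d, classes: %s, valid pixels: %d\n",
              nrow(x$nodata), ncol(x$nodata),
              paste(x$classes, collapse = ", "), sum(!x$nodata)))
  invisible(x)
}

#' Tidy probability maps into a long tibble
#'
#' @param x A `probability_maps` object.
#' @param ... Unused.
#' @return A tibble `row`, `col`, `class`, `probability` (valid pixels
#'   only).
#' @export
as_tibble.probability_maps <- function(x, ...) {
  valid <- which(!x$nodata, arr.ind = TRUE)
  purrr::map_dfr(x$classes, function(cl) {
    tibble(row = valid[, 1], col = valid[, 2], class = cl,
           probability = x$prob[[cl]][valid])
  })
}

#' Histogram summary of class probabilities
#'
#' Bins each class's valid-pixel probabilities over `[0, 1]`; nodata pixels
#' are excluded. Bin counts per class sum to the number of valid pixels.
#'
#' @param maps A `probability_maps` object.
#' @param bin_width Bin width in probability units (default 0.05).
#' @return A tibble `class`, `bin_lower`, `bin_upper`, `count`.
#' @export
summarize_probabilities <- function(maps, bin_width = 0.05) {
  stopifnot(inherits(maps, "probability_maps"))
  breaks <- seq(0, 1, by = bin_width)
  if (max(breaks) < 1) breaks <- c(breaks, 1)
  purrr::map_dfr(maps$classes, function(cl) {
    v <- maps$prob[[cl]][!maps$nodata]
    if (length(v) == 0) {
      return(tibble(class = character(), bin_lower = numeric(),
                    bin_upper = numeric(), count = integer()))
    }
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    tibble(class = cl, bin_lower = head(breaks, -1),
           bin_upper = tail(breaks, -1), count = h$counts)
  })
}

#' Plot class-probability maps
#'
#' @param maps A `probability_maps` object.
#' @return A ggplot: one facet per class, probability as fill, nodata blank.
#' @export
plot_probability_maps <- function(maps) {
  df <- as_tibble(maps)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::facet_wrap(~class) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot importance scores per band and criterion
#'
#' @param x An `importance_score_table`.
#' @return A ggplot bar chart faceted by criterion.
#' @export
plot_importance_scores <- function(x) {
  stopifnot(inherits(x, "importance_score_table"))
  df <- dplyr::mutate(x$scores,
                      band = factor(.data$band,
                                    levels = intersect(LTS_BANDS, .data$band)))
  ggplot2::ggplot(df, ggplot2::aes(.data$band, .data$score)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::facet_wrap(~criterion) +
    ggplot2::labs(y = "importance score S") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot phase-validation probability distributions
#'
#' Boxplots of predicted class probabilities for validation locations,
#' grouped by reference label, for the training and operational phases.
#'
#' @param x An `iterative_update` object.
#' @return A ggplot.
#' @export
plot_phase_probabilities <- function(x) {
  stopifnot(inherits(x, "iterative_update"))
  df <- tidyr::pivot_longer(x$validation,
                            dplyr::starts_with("P_") &
                              !dplyr::matches("^P_correct$"),
                            names_to = "class", values_to = "probability")
  df$class <- sub("^P_", "", df$class)
  df$phase_model <- factor(df$phase_model, c("training", "operational"))
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$probability)) +
    ggplot2::geom_boxplot(fill = "#a6bddb") +
    ggplot2::facet_grid(phase_model ~ ref_label,
                        labeller = ggplot2::label_both) +
    ggplot2::theme_minimal()
}
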