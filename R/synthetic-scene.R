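# Class-conditional generation of small scene stacks with known truth.
#
# Base surface reflectance (unitless, 0-1) of intact tropical moist forest
# and of stable non-forest (cropland/wetland mosaic), per band, with the
# disturbance direction each band moves in when canopy is opened: reflectance
# rises in the visible and SWIR (soil/background exposure) and falls in NIR.
FOREST_BASE <- c(B = 0.03, G = 0.05, R = 0.04,
                 NIR = 0.35, SWIR1 = 0.15, SWIR2 = 0.07)
NONFOREST_BASE <- c(B = 0.05, G = 0.08, R = 0.13,
                    NIR = 0.20, SWIR1 = 0.22, SWIR2 = 0.15)
SEASONAL_AMP <- c(B = 0.004, G = 0.006, R = 0.006,
                  NIR = 0.030, SWIR1 = 0.015, SWIR2 = 0.010)
DISTURB_DIR <- c(B = 1, G = 1, R = 1, NIR = -1, SWIR1 = 1, SWIR2 = 1)
# Full deforestation step magnitude per band (reflectance units); degradation
# uses a configurable fraction of it (partial canopy opening) or a gradual
# trend towards it.
DEF_STEP <- c(B = 0.012, G = 0.015, R = 0.030,
              NIR = 0.130, SWIR1 = 0.070, SWIR2 = 0.070)

#' Generate a synthetic scene stack with known ground truth
#'
#' Builds a small dated multi-band reflectance cube in which every pixel
#' follows a class-conditional piecewise season-trend trajectory:
#'
#' * `DEF` (deforestation): an abrupt, persistent step at a random break time
#'   in the central part of the window — NIR drops and the visible/SWIR bands
#'   brighten by the full deforestation magnitude, crossing the canopy-loss
#'   analogue of the 20% cover threshold.
#' * `DEG` (degradation): either a partial step (a configurable fraction of
#'   the deforestation magnitude, default 0.4) at a break, or a gradual trend
#'   of the same sign with no break.
#' * `NOCH` (stable forest): constant seasonal trajectory.
#' * `NONFOREST`: stable non-forest reflectance (low NDVI) throughout.
#'
#' All bands of a pixel share the break time and the cloud-outlier pattern;
#' each date has a single validity mask shared by all bands (cloud/gap
#' dropout). Per-pixel base levels are jittered log-normally so classes are
#' populations, not point masses.
#'
#' @param n_rows,n_cols Scene dimensions in pixels.
#' @param n_dates Number of acquisitions, evenly spaced over the sampling
#'   window; at least 24.
#' @param class_fractions Named numeric vector over
#'   `c("DEF","DEG","NOCH","NONFOREST")` (subsets allowed) summing to 1.
#'   Every named class must receive at least one pixel.
#' @param sampling A [sampling_model()]; its window, noise, dropout and
#'   outlier settings apply to every pixel. `outlier_shift`'s magnitude is
#'   used with a per-band sign (negative in NIR, positive elsewhere).
#' @param deg_fraction Fraction of the deforestation step magnitude used for
#'   partial-canopy degradation (default 0.4).
#' @param seed Optional integer overriding `sampling$seed`.
#'
#' @return An object of class `synthetic_scene` (also a `scene_stack`): a
#'   list with `dates` (decimal years), `bands` (named list of
#'   `n_rows x n_cols x n_dates` arrays for the six reflectance bands),
#'   `valid` (logical array of the same shape), `truth_class`
#'   (`n_rows x n_cols` character matrix) and `truth_params` (tibble with one
#'   row per pixel: `row`, `col`, `change_class`, `break_time`, `deg_mode`).
#' @export
#' @examples
#' sc <- generate_scene(8, 8, n_dates = 30,
#'                      sampling = sampling_model(seed = 7))
#' table(sc$truth_class)
generate_scene <- function(n_rows, n_cols, n_dates = 60,
                           class_fractions = c(DEF = 0.25, DEG = 0.25,
                                               NOCH = 0.40, NONFOREST = 0.10),
                           sampling = sampling_model(),
                           deg_fraction = 0.4,
                           seed = NULL) {
  stopifnot(inherits(sampling, "sampling_model"))
  if (n_dates < 24) abort("`n_dates` must be at least 24.")
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    abort("`class_fractions` must sum to 1.")
  }
  classes <- names(class_fractions)
  bad <- setdiff(classes, c("DEF", "DEG", "NOCH", "NONFOREST"))
  if (length(bad)) abort(paste0("unknown class: ", bad[1]))
  n_pix <- n_rows * n_cols
  counts <- round(class_fractions * n_pix)
  # fix rounding drift on the largest class
  counts[which.max(counts)] <- counts[which.max(counts)] + (n_pix - sum(counts))
  if (any(counts < 1)) {
    abort(paste0("class `", classes[which(counts < 1)[1]],
                 "` receives zero pixels at this scene size."))
  }

  withr_seed(seed %||% sampling$seed, {
    dates <- seq(sampling$start_time, sampling$end_time, length.out = n_dates)
    labels <- sample(rep(classes, times = counts))
    truth_class <- matrix(labels, n_rows, n_cols)

    lo <- sampling$start_time + 0.2 * (sampling$end_time - sampling$start_time)
    hi <- sampling$end_time - 0.2 * (sampling$end_time - sampling$start_time)
    break_time <- ifelse(labels %in% c("DEF", "DEG"), runif(n_pix, lo, hi),
                         NA_real_)
    deg_mode <- ifelse(labels == "DEG",
                       sample(c("step", "trend"), n_pix, replace = TRUE),
                       NA_character_)
    # trend-mode degradation has no structural break
    break_time[labels == "DEG" & deg_mode == "trend"] <- NA_real_
    phase <- runif(n_pix, -pi, pi)

    bands <- lapply(LTS_REFLECTANCE_BANDS, function(b) {
      array(NA_real_, c(n_rows, n_cols, n_dates))
    })
    names(bands) <- LTS_REFLECTANCE_BANDS

    # shared per-date validity and cloud-outlier patterns
    valid <- array(runif(n_pix * n_dates) >= sampling$dropout_prob,
                   c(n_rows, n_cols, n_dates))
    outlier <- array(runif(n_pix * n_dates) < sampling$outlier_prob,
                     c(n_rows, n_cols, n_dates))
    shift_mag <- abs(sampling$outlier_shift)

    for (p in seq_len(n_pix)) {
      r <- (p - 1) %% n_rows + 1
      cc <- (p - 1) %/% n_rows + 1
      cls <- truth_class[r, cc]
      jitter <- exp(rnorm(6, sd = 0.05))
      base <- (if (cls == "NONFOREST") NONFOREST_BASE else FOREST_BASE) * jitter
      for (b in LTS_REFLECTANCE_BANDS) {
        step <- DISTURB_DIR[[b]] * DEF_STEP[[b]]
        if (cls == "DEF") {
          pr <- trajectory_params(
            alpha1 = base[[b]] - 0, beta1 = 0,
            gamma1 = SEASONAL_AMP[[b]], delta1 = phase[p],
            alpha2 = base[[b]] + step * runif(1, 0.85, 1.15),
            beta2 = 0, gamma2 = SEASONAL_AMP[[b]] * 0.5, delta2 = phase[p],
            break_time = break_time[p], change_class = "DEF"
          )
        } else if (cls == "DEG" && deg_mode[p] == "step") {
          pr <- trajectory_params(
            alpha1 = base[[b]], beta1 = 0,
            gamma1 = SEASONAL_AMP[[b]], delta1 = phase[p],
            alpha2 = base[[b]] + deg_fraction * step * runif(1, 0.8, 1.2),
            beta2 = 0, gamma2 = SEASONAL_AMP[[b]] * 0.8, delta2 = phase[p],
            break_time = break_time[p], change_class = "DEG"
          )
        } else if (cls == "DEG") {
          # gradual degradation: trend reaching ~deg_fraction of the full
          # step over the second half of the window
          slope <- deg_fraction * step /
            (0.5 * (sampling$end_time - sampling$start_time))
          pr <- trajectory_params(
            alpha1 = base[[b]] - slope * runif(1, 0.8, 1.2) *
              (sampling$start_time - 1999),
            beta1 = slope, gamma1 = SEASONAL_AMP[[b]], delta1 = phase[p],
            change_class = "DEG"
          )
        } else {
          pr <- trajectory_params(
            alpha1 = base[[b]], beta1 = 0,
            gamma1 = SEASONAL_AMP[[b]] * (if (cls == "NONFOREST") 0.5 else 1),
            delta1 = phase[p], change_class = "NOCH"
          )
        }
        y <- eval_trajectory(pr, dates)
        y <- y + rnorm(n_dates, sd = sampling$noise_sd)
        # unmasked-cloud remnants: negative spikes in NIR, positive in the
        # visible and SWIR bands
        out <- outlier[r, cc, ]
        y[out] <- y[out] + (if (b == "NIR") -1 else 1) * shift_mag
        bands[[b]][r, cc, ] <- y
      }
    }
    truth_params <- tibble(
      row = (seq_len(n_pix) - 1) %% n_rows + 1,
      col = (seq_len(n_pix) - 1) %/% n_rows + 1,
      change_class = labels,
      break_time = break_time,
      deg_mode = deg_mode
    )
    structure(
      list(dates = dates, n_rows = n_rows, n_cols = n_cols,
           bands = bands, valid = valid,
           truth_class = truth_class, truth_params = truth_params),
      class = c("synthetic_scene", "scene_stack")
    )
  })
}

#' @export
print.scene_stack <- function(x, ...) {
  cat(sprintf("<scene_stack> %d x %d pixels, %d dates (%.2f-%.2f), bands: %s\n",
              x$n_rows, x$n_cols, length(x$dates),
              min(x$dates), max(x$dates),
              paste(names(x$bands), collapse = ", ")))
  if (!is.null(x$truth_class)) {
    tc <- table(x$truth_class)
    cat("truth:", paste(names(tc), tc, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Tidy a scene stack into a long tibble
#'
#' @param x A `scene_stack`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `time`, `band`, `value`,
#'   `valid`.
#' @export
as_tibble.scene_stack <- function(x, ...) {
  n_dates <- length(x$dates)
  grid <- expand.grid(row = seq_len(x$n_rows), col = seq_len(x$n_cols),
                      date_idx = seq_len(n_dates))
  out <- purrr::map_dfr(names(x$bands), function(b) {
    tibble(row = grid$row, col = grid$col,
           time = x$dates[grid$date_idx], band = b,
           value = as.vector(x$bands[[b]]),
           valid = as.vector(x$valid))
  })
  dplyr::arrange(out, .data$band, .data$col, .data$row, .data$time)
}

#' Simulate a labelled spectral-temporal training set
#'
#' Convenience wrapper for classifier experiments: generates a balanced
#' population of DEF / DEG / NOCH trajectories (via [generate_scene()] with
#' no non-forest pixels), extracts the temporal metrics for the requested
#' bands, and returns a training tibble with `label`, `row`, `col` and the
#' metric columns.
#'
#' @param n_per_class Pixels per class.
#' @param bands Bands to derive metrics from (default the reduced mapping
#'   set SWIR2, TCW, G).
#' @param n_dates Acquisitions per pixel.
#' @param sampling A [sampling_model()].
#' @param seed Integer seed.
#' @param deg_fraction Degradation step fraction, see [generate_scene()].
#' @return A training tibble ready for [train_change_model()].
#' @export
simulate_training_set <- function(n_per_class, bands = c("SWIR2", "TCW", "G"),
                                  n_dates = 60, sampling = sampling_model(),
                                  seed = 1L, deg_fraction = 0.4) {
  scene <- generate_scene(
    n_rows = 3, n_cols = n_per_class, n_dates = n_dates,
    class_fractions = c(DEF = 1 / 3, DEG = 1 / 3, NOCH = 1 / 3),
    sampling = sampling, seed = seed, deg_fraction = deg_fraction
  )
  met <- scene_metrics(scene, bands = bands)
  tp <- scene$truth_params[c("row", "col", "change_class")]
  names(tp)[3] <- "label"
  dplyr::inner_join(tp, met, by = c("row", "col"))
}

#' Generate a time-stamped stream of local-expert disturbance reports
#'
#' Emulates a community-based monitoring data stream over a synthetic scene:
#' reports are placed on disturbed (DEF/DEG) pixels — supplemented with
#' stable-forest (NOCH) locations — with purposive rather than probabilistic
#' spatial sampling, modelled as a logistic accessibility gradient across the
#' scene columns (field teams over-visit the accessible side). Each report
#' carries the raw form attributes (canopy cover, disturbance evidence,
#' forest status) consistent with its label, a timestamp shortly after the
#' pixel's break (or uniform over the window for stable pixels), and a phase
#' assignment A/B/C from the two phase boundaries.
#'
#' @param scene A `synthetic_scene`.
#' @param n_reports Total number of reports.
#' @param label_noise Fraction of reports whose label (and form attributes)
#'   are flipped to a different class, emulating interpretation error.
#' @param phase_boundaries Two decimal years splitting the stream into
#'   periods A (before the first), B (between) and C (after the second).
#' @param seed Integer seed.
#' @param noch_fraction Fraction of reports drawn as stable-forest
#'   supplements (default 1/3).
#' @param uniform If `TRUE`, sample locations uniformly instead of via the
#'   accessibility gradient.
#'
#' @return A tibble of class `report_stream`, sorted by timestamp, with
#'   columns `report_id`, `row`, `col`, `lon`, `lat`, `timestamp`, `phase`,
#'   `canopy_cover_pct`, `disturbance_evidence`, `forest_status`, `label`,
#'   `true_class`; phase boundaries are stored in the
#'   `"phase_boundaries"` attribute.
#' @export
generate_reports <- function(scene, n_reports, label_noise = 0,
                             phase_boundaries = NULL, seed = 1L,
                             noch_fraction = 1 / 3, uniform = FALSE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  tp <- scene$truth_params
  if (nrow(tp) == 0) abort("empty scene.")
  if (is.null(phase_boundaries)) {
    w <- range(scene$dates)
    phase_boundaries <- w[1] + c(0.45, 0.75) * diff(w)
  }
  dist_idx <- which(tp$change_class %in% c("DEF", "DEG"))
  noch_idx <- which(tp$change_class == "NOCH")
  n_noch <- min(round(noch_fraction * n_reports), length(noch_idx))
  n_dist <- n_reports - n_noch
  if (n_dist > length(dist_idx)) {
    abort("`n_reports` exceeds the number of disturbed pixels plus requested no-change supplements.")
  }
  withr_seed(seed, {
    w_access <- if (uniform) rep(1, nrow(tp)) else {
      stats::plogis((tp$col - scene$n_cols / 2) / (scene$n_cols / 6))
    }
    pick_dist <- sample(dist_idx, n_dist, prob = w_access[dist_idx])
    pick_noch <- if (n_noch > 0) {
      sample(noch_idx, n_noch, prob = w_access[noch_idx])
    } else integer()
    pick <- c(pick_dist, pick_noch)
    sel <- tp[pick, ]
    wnd <- range(scene$dates)
    ts_ <- ifelse(
      !is.na(sel$break_time),
      pmin(sel$break_time + runif(nrow(sel), 0.05, 0.8), wnd[2]),
      runif(nrow(sel), wnd[1] + 0.05 * diff(wnd), wnd[2])
    )
    label <- sel$change_class
    flip <- runif(nrow(sel)) < label_noise
    label[flip] <- vapply(label[flip], function(l) {
      sample(setdiff(LTS_CLASSES, l), 1)
    }, character(1))
    canopy <- numeric(nrow(sel))
    canopy[label == "DEF"] <- runif(sum(label == "DEF"), 0, 19)
    canopy[label == "DEG"] <- runif(sum(label == "DEG"), 25, 60)
    canopy[label == "NOCH"] <- runif(sum(label == "NOCH"), 65, 95)
    out <- tibble(
      report_id = sprintf("R%04d", seq_len(nrow(sel))),
      row = sel$row, col = sel$col,
      lon = sel$col - 0.5, lat = scene$n_rows - sel$row + 0.5,
      timestamp = ts_,
      phase = cut(ts_, c(-Inf, phase_boundaries, Inf),
                  labels = c("A", "B", "C"), right = FALSE),
      canopy_cover_pct = canopy,
      disturbance_evidence = label %in% c("DEF", "DEG"),
      forest_status = "FOREST",
      label = label,
      true_class = sel$change_class
    )
    out <- dplyr::arrange(out, .data$timestamp)
    out$phase <- as.character(out$phase)
    attr(out, "phase_boundaries") <- phase_boundaries
    class(out) <- c("report_stream", class(out))
    out
  })
}
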