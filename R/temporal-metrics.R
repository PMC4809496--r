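# Robust fitting backbone. Least squares first; when the LS residual scale
# is essentially zero (noiseless input) the LS solution is already the
# M-estimate, and the MAD scale estimate would degenerate, so it is returned
# directly. Otherwise Huber M-estimation (k = 1.345, MAD scale, IWLS to
# tolerance 1e-8 or 50 iterations) via MASS::rlm.
robust_coefs <- function(X, y) {
  ls <- stats::lm.fit(X, y)
  rss <- sum(ls$residuals^2)
  yscale <- max(abs(y), 1)
  if (sqrt(rss / length(y)) < 1e-10 * yscale) {
    return(list(coefficients = ls$coefficients, scale = 0,
                residuals = ls$residuals))
  }
  fit <- suppressWarnings(
    MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345,
              scale.est = "MAD", maxit = 50, acc = 1e-8)
  )
  list(coefficients = coef(fit), scale = fit$s, residuals = fit$residuals)
}

validate_ts <- function(ts) {
  if (!is.data.frame(ts) || !all(c("time", "value") %in% names(ts))) {
    abort("a pixel time series must be a data frame with `time` and `value`.")
  }
  if (nrow(ts) > 1 && any(diff(ts$time) <= 0)) {
    abort("`time` must be strictly increasing.")
  }
  ts
}

#' Robust linear trend over a full pixel time series
#'
#' Fits `value ~ (time - 1999)` by a Huber M-estimator, down-weighting
#' outliers such as unmasked clouds. The intercept is reported at the
#' baseline year 1999.0. No seasonal term is included; this is the
#' whole-series trend descriptor.
#'
#' @param ts A tibble with columns `time` (decimal years, strictly
#'   increasing) and `value`; at least 4 observations.
#' @return A tibble with one row: `rlm_intercept`, `rlm_slope`, `n_obs`,
#'   `scale` (robust residual scale; 0 for a noiseless fit).
#' @export
#' @examples
#' t <- seq(1999, 2014, by = 0.1)
#' fit_rlm_trend(tibble::tibble(time = t, value = 2 + 0.5 * (t - 1999)))
fit_rlm_trend <- function(ts) {
  validate_ts(ts)
  if (nrow(ts) < 4) abort("insufficient data: at least 4 observations required.")
  X <- cbind(1, ts$time - 1999)
  fit <- robust_coefs(X, ts$value)
  tibble(rlm_intercept = unname(fit$coefficients[1]),
         rlm_slope = unname(fit$coefficients[2]),
         n_obs = nrow(ts), scale = fit$scale)
}

# Internal season-trend fit on raw vectors. The seasonal pair sin(2*pi*t),
# cos(2*pi*t) is anchored to absolute decimal years (annual period); the
# trend is measured from t0 so the intercept has a defined origin.
fit_season_trend_impl <- function(time, value, t0) {
  X <- cbind(1, time - t0, sin(2 * pi * time), cos(2 * pi * time))
  fit <- robust_coefs(X, value)
  cf <- unname(fit$coefficients)
  gamma <- sqrt(cf[3]^2 + cf[4]^2)
  delta <- atan2(cf[4], cf[3])
  if (delta <= -pi) delta <- delta + 2 * pi
  list(alpha = cf[1], beta = cf[2], gamma = gamma, delta = delta,
       n_obs = length(value), scale = fit$scale,
       coefficients = cf, residuals = fit$residuals)
}

#' Robust season-trend model fit
#'
#' Fits the season-trend model
#' `y(t) = alpha + beta (t - t0) + gamma sin(2 pi t + delta)`
#' by a Huber M-estimator, using the linearised harmonic pair
#' `a sin(2 pi t) + b cos(2 pi t)` with `gamma = sqrt(a^2 + b^2)` and
#' `delta = atan2(b, a)`. The single annual harmonic matches the assumed
#' one-cycle-per-year seasonality of optical reflectance over forest.
#'
#' @param ts A tibble with `time`/`value`; at least 8 observations spanning
#'   at least one year.
#' @param t0 Trend origin in decimal years (default 1999.0).
#' @return An object of class `season_trend_fit` with elements `alpha`,
#'   `beta`, `gamma` (>= 0), `delta` (radians in (-pi, pi]), `n_obs`,
#'   `scale`, and the data for plotting. Use [tidy()] / [glance()] to get
#'   tibbles.
#' @export
#' @examples
#' t <- sort(runif(120, 1999, 2015))
#' y <- 1 + 0.2 * (t - 1999) + 0.3 * sin(2 * pi * t + 0.5)
#' fit <- fit_season_trend(tibble::tibble(time = t, value = y))
#' glance(fit)
fit_season_trend <- function(ts, t0 = 1999) {
  validate_ts(ts)
  if (nrow(ts) < 8) abort("insufficient data: at least 8 observations required.")
  if (diff(range(ts$time)) < 1) {
    abort("time span shorter than one year: seasonal amplitude unidentifiable.")
  }
  fit <- fit_season_trend_impl(ts$time, ts$value, t0)
  structure(c(fit, list(t0 = t0, data = ts)), class = "season_trend_fit")
}

#' @export
print.season_trend_fit <- function(x, ...) {
  cat(sprintf(
    "<season_trend_fit> n=%d  alpha=%.4g  beta=%.4g/yr  gamma=%.4g  delta=%.3f rad\n",
    x$n_obs, x$alpha, x$beta, x$gamma, x$delta))
  invisible(x)
}

#' @export
tidy.season_trend_fit <- function(x, ...) {
  tibble(term = c("alpha", "beta", "gamma", "delta"),
         estimate = c(x$alpha, x$beta, x$gamma, x$delta))
}

#' @export
glance.season_trend_fit <- function(x, ...) {
  tibble(alpha = x$alpha, beta = x$beta, gamma = x$gamma, delta = x$delta,
         n_obs = x$n_obs, scale = x$scale)
}

#' @export
predict.season_trend_fit <- function(object, newdata = NULL, ...) {
  time <- if (is.null(newdata)) object$data$time else newdata$time
  object$alpha + object$beta * (time - object$t0) +
    object$gamma * sin(2 * pi * time + object$delta)
}

#' @export
autoplot.season_trend_fit <- function(object, ...) {
  grid <- tibble(time = seq(min(object$data$time), max(object$data$time),
                            length.out = 400))
  grid$value <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#c0392b", linetype = "22") +
    ggplot2::labs(x = "year", y = "value") +
    ggplot2::theme_minimal()
}

#' Detect at most one structural break in a pixel time series
#'
#' Scans candidate break positions (each resulting segment must hold at
#' least `max(ceiling(min_seg_frac * n), 8)` observations), fitting the
#' season-trend model to both segments by least squares, and compares the
#' best one-break fit with the no-break fit by BIC:
#' `BIC = n log(RSS/n) + k log(n)`, with k = 4 for the single model and
#' k = 9 for two segments plus the break position. A break is accepted only
#' when the one-break BIC is strictly lower (ties resolve to no break —
#' parsimony). At most one break is ever reported, matching the assumption
#' of a single land-use conversion over the observation window.
#'
#' The BIC scan deliberately uses least squares; accepted segments are
#' refit robustly downstream (see [extract_metrics()]), mirroring the
#' chaining of least-squares break search into robust segment fits.
#'
#' @param ts A tibble with `time`/`value`.
#' @param min_seg_frac Minimum segment size as a fraction of n (default
#'   0.15); the absolute floor of 8 observations always applies.
#' @return A tibble with one row: `has_break`, `break_time` (midpoint
#'   between the neighbouring observations, `NA` if none), `break_index`
#'   (first index of segment 2), `bic0`, `bic1`, `degenerate` (series too
#'   short for the scan).
#' @export
detect_single_break <- function(ts, min_seg_frac = 0.15) {
  validate_ts(ts)
  n <- nrow(ts)
  min_seg <- max(ceiling(min_seg_frac * n), 8)
  no_break <- function(bic0, bic1, degen) {
    tibble(has_break = FALSE, break_time = NA_real_,
           break_index = NA_integer_, bic0 = bic0, bic1 = bic1,
           degenerate = degen)
  }
  if (n < 2 * min_seg) {
    return(no_break(NA_real_, NA_real_, TRUE))
  }
  t <- ts$time; y <- ts$value
  X <- cbind(1, t, sin(2 * pi * t), cos(2 * pi * t))
  rss <- function(idx) sum(stats::lm.fit(X[idx, , drop = FALSE], y[idx])$residuals^2)
  bic0 <- n * log(rss(seq_len(n)) / n) + 4 * log(n)
  cand <- seq(min_seg + 1L, n - min_seg + 1L)
  rss1 <- vapply(cand, function(i) {
    rss(seq_len(i - 1L)) + rss(seq.int(i, n))
  }, numeric(1))
  best <- which.min(rss1)
  bic1 <- n * log(rss1[best] / n) + 9 * log(n)
  if (is.finite(bic1) || is.finite(bic0)) {
    has_break <- bic1 < bic0
  } else {
    has_break <- FALSE  # both fits exact (noiseless); keep the simpler model
  }
  if (!has_break) return(no_break(bic0, bic1, FALSE))
  i <- cand[best]
  tibble(has_break = TRUE,
         break_time = (t[i - 1] + t[i]) / 2,
         break_index = as.integer(i), bic0 = bic0, bic1 = bic1,
         degenerate = FALSE)
}

#' Spectral-temporal metrics for one pixel
#'
#' Computes the six per-band spectral-temporal covariates that feed the
#' change classifier: the full-series robust linear trend (`rlm_intercept`
#' at the 1999 origin and `rlm_slope`), and per-segment season-trend
#' amplitudes and slopes (`gamma1`, `beta1`; `gamma2`, `beta2`). Segments
#' come from [detect_single_break()]; when no break is detected the
#' second-segment values duplicate the first, so the vector length is
#' constant (6 metrics x number of bands).
#'
#' @param series_by_band Either a named list of `time`/`value` tibbles (one
#'   per band) or a single long tibble with columns `band`, `time`, `value`.
#' @param min_obs Minimum observations for a band to be fit (default 8; a
#'   shorter or sub-annual series yields `NA` metrics for that band, with a
#'   message).
#' @param min_seg_frac Passed to [detect_single_break()].
#' @return A one-row tibble with columns `<band>_<metric>` for every band
#'   supplied, in canonical band order.
#' @export
#' @examples
#' ts <- generate_timeseries(trajectory_params(alpha1 = 0.3, gamma1 = 0.02),
#'                           sampling_model(seed = 3))
#' extract_metrics(list(NIR = ts))
extract_metrics <- function(series_by_band, min_obs = 8, min_seg_frac = 0.15) {
  if (is.data.frame(series_by_band)) {
    stopifnot(all(c("band", "time", "value") %in% names(series_by_band)))
    series_by_band <- split(series_by_band[c("time", "value")],
                            series_by_band$band)
  }
  bands <- names(series_by_band)
  ord <- order(match(bands, LTS_BANDS, nomatch = length(LTS_BANDS) + 1L))
  bands <- bands[ord]
  out <- lapply(bands, function(b) {
    ts <- series_by_band[[b]]
    na <- setNames(rep(NA_real_, 6), LTS_METRICS)
    if (nrow(ts) < max(min_obs, 4) || diff(range(ts$time)) < 1) {
      inform(paste0("band ", b, ": insufficient observations; metrics set to NA."))
      return(na)
    }
    trend <- fit_rlm_trend(ts)
    brk <- detect_single_break(ts, min_seg_frac)
    if (isTRUE(brk$has_break)) {
      i <- brk$break_index
      f1 <- fit_season_trend_impl(ts$time[1:(i - 1)], ts$value[1:(i - 1)], 1999)
      f2 <- fit_season_trend_impl(ts$time[i:nrow(ts)], ts$value[i:nrow(ts)], 1999)
    } else {
      f1 <- fit_season_trend_impl(ts$time, ts$value, 1999)
      f2 <- f1
    }
    c(rlm_intercept = trend$rlm_intercept, rlm_slope = trend$rlm_slope,
      gamma1 = f1$gamma, gamma2 = f2$gamma,
      beta1 = f1$beta, beta2 = f2$beta)
  })
  names(out) <- bands
  flat <- unlist(out)
  names(flat) <- as.vector(t(outer(bands, LTS_METRICS, paste, sep = "_")))
  as_tibble(as.list(flat))
}

#' Metric column names for a set of bands
#'
#' @param bands Character vector of band names.
#' @param metrics Metric names (default all six).
#' @return Character vector `<band>_<metric>` in band-major order.
#' @export
#' @examples
#' metric_columns(c("SWIR2", "TCW"))
metric_columns <- function(bands, metrics = LTS_METRICS) {
  as.vector(t(outer(bands, metrics, paste, sep = "_")))
}

#' The reduced covariate set used for wall-to-wall mapping
#'
#' All six temporal metrics of the SWIR2 and tasseled-cap wetness bands,
#' plus the robust-trend intercept and slope of the green band — the subset
#' selected by the importance-scoring analysis (14 columns).
#'
#' @return Character vector of 14 metric column names.
#' @export
reduced_covariate_set <- function() {
  c(metric_columns(c("SWIR2", "TCW")),
    metric_columns("G", c("rlm_intercept", "rlm_slope")))
}
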