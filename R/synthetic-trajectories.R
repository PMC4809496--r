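#' Trajectory parameters for one pixel time series
#'
#' Describes a piecewise season-trend trajectory with at most one structural
#' break: per segment an intercept `alpha` (value at the 1999.0 origin), a
#' linear slope `beta` (units/year), a seasonal amplitude `gamma` (>= 0) and a
#' phase `delta` (radians). The trajectory value at decimal year t within
#' segment j is
#'
#'   y(t) = alpha_j + beta_j (t - 1999) + gamma_j sin(2 pi t + delta_j)
#'
#' i.e. a single annual harmonic; the seasonal term is anchored to the
#' calendar (absolute decimal year) so that phase is comparable across pixels.
#'
#' @param alpha1,alpha2 Segment intercepts at the 1999.0 origin (reflectance
#'   or index units).
#' @param beta1,beta2 Segment slopes (units per year).
#' @param gamma1,gamma2 Seasonal amplitudes, must be non-negative.
#' @param delta1,delta2 Seasonal phases in radians.
#' @param break_time Decimal year of the structural break, or `NA` for an
#'   unbroken trajectory. When present it must lie strictly inside the
#'   sampling window at generation time.
#' @param change_class One of `"DEF"`, `"DEG"`, `"NOCH"`. A `"NOCH"`
#'   trajectory must have identical segment-1 and segment-2 parameters.
#'
#' @return An object of class `trajectory_params`.
#' @export
#' @examples
#' trajectory_params(alpha1 = 0.35, beta1 = 0, gamma1 = 0.03)
trajectory_params <- function(alpha1, beta1 = 0, gamma1 = 0, delta1 = 0,
                              alpha2 = alpha1, beta2 = beta1,
                              gamma2 = gamma1, delta2 = delta1,
                              break_time = NA_real_,
                              change_class = c("NOCH", "DEF", "DEG")) {
  change_class <- match.arg(change_class)
  if (gamma1 < 0 || gamma2 < 0) {
    abort("seasonal amplitudes `gamma1`/`gamma2` must be non-negative.")
  }
  if (change_class == "NOCH") {
    same <- isTRUE(all.equal(
      c(alpha1, beta1, gamma1, delta1),
      c(alpha2, beta2, gamma2, delta2)
    ))
    if (!same) {
      abort("a NOCH trajectory must have identical segment parameters.")
    }
  }
  structure(
    list(alpha1 = alpha1, beta1 = beta1, gamma1 = gamma1, delta1 = delta1,
         alpha2 = alpha2, beta2 = beta2, gamma2 = gamma2, delta2 = delta2,
         break_time = break_time, change_class = change_class),
    class = "trajectory_params"
  )
}

#' Sampling model for irregular acquisitions
#'
#' Controls how a noiseless trajectory is turned into an irregular observed
#' series: acquisitions are laid out every `mean_revisit` days between
#' `start_time` and `end_time`, a fraction `dropout_prob` is removed at random
#' (clouds and scan-line gaps), Gaussian noise with standard deviation
#' `noise_sd` is added, and a fraction `outlier_prob` of the surviving
#' observations is shifted by `outlier_shift` (unmasked cloud remnants; the
#' shift is signed, negative in NIR/index space and positive in the SWIR and
#' visible bands).
#'
#' @param start_time,end_time Observation window in decimal years; must span
#'   at least one year so the annual cycle is identifiable.
#' @param mean_revisit Mean revisit interval in days.
#' @param dropout_prob,outlier_prob Fractions in `[0, 1]`.
#' @param outlier_shift Signed outlier offset in value units.
#' @param noise_sd Gaussian noise standard deviation in value units.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return An object of class `sampling_model`.
#' @export
sampling_model <- function(start_time = 1999, end_time = 2015,
                           mean_revisit = 16, dropout_prob = 0.3,
                           outlier_prob = 0.05, outlier_shift = -0.15,
                           noise_sd = 0.01, seed = 1L) {
  if (end_time <= start_time) {
    abort("`end_time` must be after `start_time`.")
  }
  for (p in c(dropout_prob, outlier_prob)) {
    if (p < 0 || p > 1) abort("probabilities must lie in [0, 1].")
  }
  structure(
    list(start_time = start_time, end_time = end_time,
         mean_revisit = mean_revisit, dropout_prob = dropout_prob,
         outlier_prob = outlier_prob, outlier_shift = outlier_shift,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "sampling_model"
  )
}

#' Evaluate a noiseless trajectory
#'
#' @param params A [trajectory_params()] object.
#' @param times Decimal years.
#' @return Numeric vector of trajectory values.
#' @export
eval_trajectory <- function(params, times) {
  seg2 <- !is.na(params$break_time) & times >= params$break_time
  y <- params$alpha1 + params$beta1 * (times - 1999) +
    params$gamma1 * sin(2 * pi * times + params$delta1)
  if (any(seg2)) {
    t2 <- times[seg2]
    y[seg2] <- params$alpha2 + params$beta2 * (t2 - 1999) +
      params$gamma2 * sin(2 * pi * t2 + params$delta2)
  }
  y
}

#' Generate one irregular pixel time series
#'
#' Samples a piecewise season-trend trajectory at irregular acquisition times
#' and contaminates it with Gaussian noise and one-sided cloud-like outliers,
#' per the sampling model.
#'
#' @param params A [trajectory_params()] object.
#' @param sampling A [sampling_model()] object.
#' @return A tibble with columns `time` (decimal year, strictly increasing),
#'   `value`, and `is_outlier` (logical; which observations received the
#'   outlier shift — ground truth for robustness experiments).
#' @export
#' @examples
#' ts <- generate_timeseries(
#'   trajectory_params(alpha1 = 0.35, gamma1 = 0.03),
#'   sampling_model(noise_sd = 0.005, seed = 42)
#' )
#' head(ts)
generate_timeseries <- function(params, sampling) {
  stopifnot(inherits(params, "trajectory_params"),
            inherits(sampling, "sampling_model"))
  span <- sampling$end_time - sampling$start_time
  if (span < 1) {
    abort("observation window shorter than one year: the annual cycle is not identifiable.")
  }
  if (!is.na(params$break_time) &&
      (params$break_time <= sampling$start_time ||
       params$break_time >= sampling$end_time)) {
    abort("`break_time` must lie strictly inside the observation window.")
  }
  withr_seed(sampling$seed, {
    step <- sampling$mean_revisit / 365.25
    times <- seq(sampling$start_time, sampling$end_time, by = step)
    keep <- runif(length(times)) >= sampling$dropout_prob
    times <- times[keep]
    y <- eval_trajectory(params, times)
    if (sampling$noise_sd > 0) {
      y <- y + rnorm(length(y), sd = sampling$noise_sd)
    }
    out <- runif(length(y)) < sampling$outlier_prob
    y[out] <- y[out] + sampling$outlier_shift
    tibble(time = times, value = y, is_outlier = out)
  })
}

# Run `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators compose without side effects.
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
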