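#' Tasseled-cap coefficients for surface reflectance
#'
#' Loads the packaged coefficient table (published reflectance-factor
#' coefficients for the Landsat sensors; a single set is applied across
#' sensors since all inputs are surface reflectance). Columns are named by
#' band, so coefficient-to-band assignment is explicit.
#'
#' @param path Optional path to an alternative coefficient CSV with columns
#'   `index,B,G,R,NIR,SWIR1,SWIR2` and rows `TCB`, `TCG`, `TCW`.
#' @return A tibble with one row per tasseled-cap index.
#' @export
#' @examples
#' tc_coefficients()
tc_coefficients <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tasseled_cap_coefficients.csv",
                                package = "ltschange", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("index", LTS_REFLECTANCE_BANDS)
  if (!all(need %in% names(out))) {
    abort("coefficient file must have columns index,B,G,R,NIR,SWIR1,SWIR2.")
  }
  out
}

#' Sieve small isolated valid clusters out of a mask
#'
#' Removes connected clusters of valid (TRUE) pixels of at most
#' `min_cluster` pixels that are entirely surrounded by invalid pixels or
#' the image edge — the residue of unmasked clouds sitting inside scan-line
#' gaps. Connectivity is 4-neighbour. The operation is idempotent.
#'
#' @param mask A 2-D logical matrix (`TRUE` = valid).
#' @param min_cluster Maximum cluster size to remove (default 5).
#' @return A logical matrix of the same shape.
#' @export
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 2:4] <- TRUE
#' apply_sieve(m)  # 3-pixel cluster removed
apply_sieve <- function(mask, min_cluster = 5) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort("`mask` must be a 2-D logical matrix.")
  }
  if (min_cluster < 1) abort("`min_cluster` must be >= 1.")
  lab <- label_components(mask)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- which(sizes <= min_cluster)
  if (length(drop)) mask[lab %in% drop] <- FALSE
  mask
}

# 4-connected component labelling by iterative flood fill; returns an
# integer matrix (0 = background).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          q <- (c2 - 1L) * nr + r2
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  lab
}

# Evaluate a derived index from a named list/data frame of reflectance
# vectors (or arrays of identical shape). Zero denominators yield NA.
index_from_bands <- function(vals, index, coeffs = tc_coefficients(),
                             tca_convention = c("paper", "literature")) {
  tca_convention <- match.arg(tca_convention)
  need <- switch(index,
    NDVI = c("NIR", "R"), NDMI = c("NIR", "SWIR1"),
    NBR = c("NIR", "SWIR2"), NBR2 = c("SWIR1", "SWIR2"),
    TCB = , TCG = , TCW = , TCA = LTS_REFLECTANCE_BANDS,
    abort(paste0("`", index, "` is not a derived band."))
  )
  missing_band <- setdiff(need, names(vals))
  if (length(missing_band)) {
    abort(paste0("missing source band: ", missing_band[1]))
  }
  nd <- function(a, b) {
    den <- a + b
    out <- (a - b) / den
    out[den == 0] <- NA_real_
    out
  }
  tc <- function(idx) {
    cf <- coeffs[coeffs$index == idx, LTS_REFLECTANCE_BANDS]
    out <- 0
    for (b in LTS_REFLECTANCE_BANDS) out <- out + cf[[b]] * vals[[b]]
    out
  }
  switch(index,
    NDVI = nd(vals$NIR, vals$R),
    NDMI = nd(vals$NIR, vals$SWIR1),
    NBR  = nd(vals$NIR, vals$SWIR2),
    NBR2 = nd(vals$SWIR1, vals$SWIR2),
    TCB  = tc("TCB"),
    TCG  = tc("TCG"),
    TCW  = tc("TCW"),
    TCA  = if (tca_convention == "paper") atan(tc("TCB") / tc("TCG"))
           else atan(tc("TCG") / tc("TCB"))
  )
}

#' Compute a derived spectral index over a scene stack
#'
#' Computes one of the eight derived bands for every date of the stack:
#' normalized differences NDVI = (NIR−R)/(NIR+R), NDMI = (NIR−SWIR1)/
#' (NIR+SWIR1), NBR = (NIR−SWIR2)/(NIR+SWIR2), NBR2 = (SWIR1−SWIR2)/
#' (SWIR1+SWIR2); tasseled-cap brightness/greenness/wetness as fixed linear
#' combinations of the six reflectance bands; and the tasseled-cap angle.
#' Invalid pixels propagate; zero denominators become invalid (`NA`).
#'
#' The tasseled-cap angle is computed as `atan(TCB/TCG)` by default
#' (`tca_convention = "paper"`); set `tca_convention = "literature"` for the
#' conventional `atan(TCG/TCB)` form.
#'
#' @param stack A `scene_stack`.
#' @param index One of the derived band names (see [lts_bands()]).
#' @param coeffs Tasseled-cap coefficients, see [tc_coefficients()].
#' @param tca_convention `"paper"` or `"literature"`.
#' @return An `n_rows x n_cols x n_dates` numeric array.
#' @export
compute_index <- function(stack, index, coeffs = tc_coefficients(),
                          tca_convention = c("paper", "literature")) {
  stopifnot(inherits(stack, "scene_stack"))
  if (!index %in% LTS_DERIVED_BANDS) {
    abort(paste0("`", index, "` is not a derived band."))
  }
  out <- index_from_bands(stack$bands, index, coeffs,
                          match.arg(tca_convention))
  out[!stack$valid] <- NA_real_
  out
}

#' Extract one pixel's valid observations as an irregular time series
#'
#' Returns the dated observations of one band at one pixel, restricted to
#' dates where the validity mask is true. Derived bands are computed on the
#' fly. A pixel with no valid observations yields an empty series (not an
#' error; downstream fitters decide how to handle it).
#'
#' @param stack A `scene_stack`.
#' @param row,col Pixel indices (1-based).
#' @param band A band name, reflectance or derived.
#' @param coeffs Tasseled-cap coefficients (used for TC* bands).
#' @return A tibble with columns `time` and `value`, `time` strictly
#'   increasing, and attribute `band`.
#' @export
extract_pixel_series <- function(stack, row, col, band,
                                 coeffs = tc_coefficients()) {
  stopifnot(inherits(stack, "scene_stack"))
  if (row < 1 || row > stack$n_rows || col < 1 || col > stack$n_cols) {
    abort("pixel indices out of range.")
  }
  if (band %in% names(stack$bands)) {
    v <- stack$bands[[band]][row, col, ]
  } else if (band %in% LTS_DERIVED_BANDS) {
    vals <- lapply(stack$bands, function(a) a[row, col, ])
    v <- index_from_bands(vals, band, coeffs)
  } else {
    abort(paste0("unknown band: ", band))
  }
  ok <- stack$valid[row, col, ] & !is.na(v)
  out <- tibble(time = stack$dates[ok], value = v[ok])
  attr(out, "band") <- band
  out
}

#' Write or read a scene stack as per-band TIFF files with a CSV manifest
#'
#' Each acquisition/band pair is written as one grayscale floating-point
#' TIFF alongside a manifest CSV (`date,sensor,band,path,offset,scale`).
#' TIFF samples are restricted to `[0, 1]`, so each grid is affinely encoded
#' into `[0, 0.9]` with the offset/scale recorded in the manifest, and
#' invalid pixels are stored as the sentinel value 1. These are plain TIFFs:
#' geo-referencing, if any, travels in manifest columns rather than embedded
#' tags. Requires the `tiff` package.
#'
#' @param stack A `scene_stack`.
#' @param dir Output directory (created if absent).
#' @param sensor Sensor tag recorded in the manifest.
#' @return `write_scene()` returns the manifest tibble invisibly;
#'   `read_scene()` returns a `scene_stack`.
#' @export
write_scene <- function(stack, dir, sensor = "SYN") {
  rlang::check_installed("tiff")
  stopifnot(inherits(stack, "scene_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_dates <- length(stack$dates)
  rows <- list()
  for (d in seq_len(n_dates)) {
    for (b in names(stack$bands)) {
      v <- stack$bands[[b]][, , d]
      ok <- stack$valid[, , d]
      lo <- if (any(ok)) min(v[ok]) else 0
      hi <- if (any(ok)) max(v[ok]) else 1
      scale <- if (hi > lo) (hi - lo) / 0.9 else 1
      enc <- (v - lo) / scale
      enc[!ok | is.na(enc)] <- 1
      path <- sprintf("scene_%03d_%s.tif", d, b)
      tiff::writeTIFF(enc, file.path(dir, path), bits.per.sample = 32L)
      rows[[length(rows) + 1]] <- tibble(
        date = stack$dates[d], sensor = sensor, band = b, path = path,
        offset = lo, scale = scale
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  rlang::check_installed("tiff")
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  dates <- sort(unique(manifest$date))
  bands_present <- unique(manifest$band)
  probe <- tiff::readTIFF(file.path(dir, manifest$path[1]))
  nr <- nrow(probe); nc <- ncol(probe)
  n_dates <- length(dates)
  bands <- lapply(bands_present, function(b) array(NA_real_, c(nr, nc, n_dates)))
  names(bands) <- bands_present
  valid <- array(TRUE, c(nr, nc, n_dates))
  for (k in seq_len(nrow(manifest))) {
    d <- match(manifest$date[k], dates)
    enc <- tiff::readTIFF(file.path(dir, manifest$path[k]))
    bad <- enc > 0.95
    v <- enc * manifest$scale[k] + manifest$offset[k]
    v[bad] <- NA_real_
    bands[[manifest$band[k]]][, , d] <- v
    valid[, , d] <- valid[, , d] & !bad
  }
  structure(
    list(dates = dates, n_rows = nr, n_cols = nc,
         bands = bands, valid = valid),
    class = "scene_stack"
  )
}
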