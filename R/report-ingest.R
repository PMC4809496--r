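#' Classification rules for disturbance reports
#'
#' Deforestation and degradation are defined on the canopy-cover dimension
#' only: a disturbance that reduces canopy cover below the forest-definition
#' threshold (default 20%) is deforestation regardless of the contiguous
#' area cleared; a disturbance leaving cover at or above the threshold is
#' degradation. The area-based criterion (sub-0.5-ha clearings counting as
#' degradation) is available behind a flag but disabled by default, since
#' affected area is rarely determinable from field forms.
#'
#' @param canopy_threshold_pct Canopy-cover threshold in percent, in (0, 100).
#' @param area_rule_enabled Enable the area-based degradation criterion.
#' @param min_area_ha Area threshold in hectares when the area rule is on.
#' @return An object of class `classification_rules`.
#' @export
classification_rules <- function(canopy_threshold_pct = 20,
                                 area_rule_enabled = FALSE,
                                 min_area_ha = 0.5) {
  if (canopy_threshold_pct <= 0 || canopy_threshold_pct >= 100) {
    abort("`canopy_threshold_pct` must lie in (0, 100).")
  }
  structure(list(canopy_threshold_pct = canopy_threshold_pct,
                 area_rule_enabled = area_rule_enabled,
                 min_area_ha = min_area_ha),
            class = "classification_rules")
}

#' Assign provisional change-class labels to disturbance reports
#'
#' Automatic interpretation of the form attributes: non-forest status maps
#' to `NONFOREST`; a forest report with disturbance evidence maps to `DEF`
#' when canopy cover is below the threshold and `DEG` otherwise; a forest
#' report without evidence maps to `NOCH`. With the area rule enabled, a
#' below-threshold clearing smaller than `min_area_ha` (column `area_ha`)
#' is downgraded to `DEG`.
#'
#' @param reports A tibble with columns `forest_status`
#'   (`"FOREST"`/`"NONFOREST"`), `disturbance_evidence` (logical) and
#'   `canopy_cover_pct` (0-100; required on forest reports).
#' @param rules A [classification_rules()] object.
#' @return `reports` with a `provisional_label` column added (every valid
#'   report receives exactly one label).
#' @export
#' @examples
#' r <- tibble::tibble(forest_status = "FOREST",
#'                     disturbance_evidence = TRUE, canopy_cover_pct = 15)
#' assign_provisional_label(r)$provisional_label
assign_provisional_label <- function(reports, rules = classification_rules()) {
  stopifnot(inherits(rules, "classification_rules"))
  need <- c("forest_status", "disturbance_evidence", "canopy_cover_pct")
  miss <- setdiff(need, names(reports))
  if (length(miss)) abort(paste0("missing report column: ", miss[1]))
  forest <- reports$forest_status == "FOREST"
  if (any(forest & is.na(reports$canopy_cover_pct))) {
    abort("missing canopy cover on a forest report.")
  }
  if (any(!is.na(reports$canopy_cover_pct) &
          (reports$canopy_cover_pct < 0 | reports$canopy_cover_pct > 100))) {
    abort("`canopy_cover_pct` must lie in [0, 100].")
  }
  lab <- dplyr::case_when(
    !forest ~ "NONFOREST",
    !reports$disturbance_evidence ~ "NOCH",
    reports$canopy_cover_pct < rules$canopy_threshold_pct ~ "DEF",
    TRUE ~ "DEG"
  )
  if (rules$area_rule_enabled && "area_ha" %in% names(reports)) {
    small <- lab == "DEF" & !is.na(reports$area_ha) &
      reports$area_ha < rules$min_area_ha
    lab[small] <- "DEG"
  }
  reports$provisional_label <- lab
  reports
}

#' Finalize labels after manual verification
#'
#' Verification against plot photos and narratives is a human step; it is
#' modelled as an explicit overrides map. Every override is recorded in an
#' audit log attached to the result (attribute `"audit_log"`), one record
#' per changed report.
#'
#' @param reports A tibble with `report_id` and `provisional_label`.
#' @param overrides Named character vector (or 2-column tibble
#'   `report_id`,`label`) mapping report ids to verified labels.
#' @return `reports` with a `final_label` column; unset overrides default to
#'   the provisional label.
#' @export
finalize_labels <- function(reports, overrides = character()) {
  if (is.data.frame(overrides)) {
    overrides <- setNames(overrides$label, overrides$report_id)
  }
  valid <- c(LTS_CLASSES, "NONFOREST")
  if (length(overrides)) {
    bad_lab <- setdiff(unname(overrides), valid)
    if (length(bad_lab)) abort(paste0("invalid label token: ", bad_lab[1]))
    bad_id <- setdiff(names(overrides), reports$report_id)
    if (length(bad_id)) abort(paste0("override for unknown report id: ", bad_id[1]))
  }
  reports$final_label <- reports$provisional_label
  hit <- match(names(overrides), reports$report_id)
  audit <- tibble(report_id = names(overrides) %||% character(),
                  from = reports$provisional_label[hit],
                  to = unname(overrides))
  reports$final_label[hit] <- unname(overrides)
  attr(reports, "audit_log") <- audit
  reports
}

#' Build a training-set skeleton from finalized reports
#'
#' Keeps deforestation and degradation reports, drops no-change and
#' non-forest reports (field-reported "no change" is unreliable as a stable
#' class sample), and appends independently sampled and validated
#' stable-forest supplement points labelled `NOCH`. The result carries
#' locations, timestamps and labels, ready for metric extraction and
#' joining.
#'
#' @param reports A finalized report tibble (with `final_label`).
#' @param supplements A tibble of no-change points with at least location
#'   columns (`row`/`col` or `lon`/`lat`); a `label` column is added/forced
#'   to `"NOCH"`.
#' @return A labelled-locations tibble with a `label` column; errors if the
#'   result holds fewer than two classes.
#' @export
filter_for_training <- function(reports, supplements = NULL) {
  if (!"final_label" %in% names(reports)) {
    abort("reports must be finalized (call `finalize_labels()` first).")
  }
  keep <- dplyr::filter(reports, .data$final_label %in% c("DEF", "DEG"))
  keep$label <- keep$final_label
  if (!is.null(supplements) && nrow(supplements) > 0) {
    supplements$label <- "NOCH"
    if (!"report_id" %in% names(supplements)) {
      supplements$report_id <- sprintf("S%04d", seq_len(nrow(supplements)))
    }
    keep <- dplyr::bind_rows(keep, supplements)
  }
  if (length(unique(keep$label)) < 2) {
    abort("training skeleton has fewer than 2 classes.")
  }
  keep
}

#' Read and write disturbance reports
#'
#' Reports travel as CSV or GeoJSON point features. The GeoJSON writer emits
#' one `Point` feature per report with all non-coordinate columns as
#' properties; the reader inverts it.
#'
#' @param path File path; format chosen by extension (`.csv` vs
#'   `.geojson`/`.json`).
#' @param reports A report tibble with `lon`/`lat` columns.
#' @return `read_reports()` returns a tibble; `write_reports()` the path,
#'   invisibly.
#' @export
read_reports <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    return(readr::read_csv(path, show_col_types = FALSE))
  }
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) abort("not a GeoJSON FeatureCollection.")
  purrr::map_dfr(gj$features, function(f) {
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    c(tibble(lon = f$geometry$coordinates[[1]],
             lat = f$geometry$coordinates[[2]]), props)
  })
}

#' @rdname read_reports
#' @export
write_reports <- function(reports, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(reports, path)
    return(invisible(path))
  }
  if (!all(c("lon", "lat") %in% names(reports))) {
    abort("GeoJSON output requires `lon` and `lat` columns.")
  }
  props <- setdiff(names(reports), c("lon", "lat"))
  features <- lapply(seq_len(nrow(reports)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(reports$lon[i], reports$lat[i])),
         properties = as.list(reports[i, props, drop = FALSE]))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
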