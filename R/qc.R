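#' Quality-control configuration
#'
#' Thresholds of the sample-exclusion rules applied to the modern
#' calibration set (and, for the count rule, to the fossil set):
#' geolocation error above 100 m, recorded-vs-DEM elevation mismatch above
#' 200 m, riverine/estuarine contexts, terrestrial count not greater than
#' 100 grains, land-class inconsistencies, and the AP/cover rule (arboreal
#' pollen > 80 percent paired with forest cover < 25 percent), from which
#' samples collected in extensive treeless contexts are exempt.
#'
#' @param max_loc_error maximum geolocation error (m).
#' @param max_elev_diff maximum |sample elevation - DEM elevation| (m).
#' @param min_count minimum terrestrial pollen count (grains).
#' @param strict_count if `TRUE` (default) the rule is strictly greater
#'   than `min_count`; if `FALSE`, at least `min_count`.
#' @param ap_thresh,cover_thresh AP/cover rule thresholds (percent).
#' @param class_cover land-class consistency cover threshold (percent).
#' @param excluded_contexts contexts excluded outright.
#' @param exempt_contexts extensive treeless contexts exempt from the
#'   AP/cover rule.
#' @param open_contexts,forest_contexts context groups for the land-class
#'   consistency checks.
#' @export
qc_config <- function(max_loc_error = 100, max_elev_diff = 200,
                      min_count = 100, strict_count = TRUE,
                      ap_thresh = 80, cover_thresh = 25, class_cover = 15,
                      excluded_contexts = c("riverine", "estuarine"),
                      exempt_contexts = c("treeless", "tundra",
                                          "alpine_grassland", "desert"),
                      open_contexts = c("treeless", "pasture"),
                      forest_contexts = c("dense_forest", "forest_undefined")) {
  list(max_loc_error = max_loc_error, max_elev_diff = max_elev_diff,
       min_count = min_count, strict_count = strict_count,
       ap_thresh = ap_thresh, cover_thresh = cover_thresh,
       class_cover = class_cover,
       excluded_contexts = excluded_contexts, exempt_contexts = exempt_contexts,
       open_contexts = open_contexts, forest_contexts = forest_contexts)
}

# land-class raster codes used throughout the package
LANDCLASS_OPEN <- 1
LANDCLASS_FOREST <- 2

#' Quality-filter the modern calibration set
#'
#' Applies the exclusion rules conjunctively, in order: duplicate removal
#' (identical coordinates and identical assemblage; first kept), location
#' error, DEM elevation mismatch, riverine/estuarine context, minimum
#' terrestrial count, land-class consistency (open-context samples in a
#' forested class with cover above 15 percent and median tree height above
#' zero; forest-context samples in an open class with cover below 15
#' percent and median height zero), and the AP/cover rule with its
#' treeless-context exemption. Samples with a missing location-error
#' estimate are retained so as not to depopulate the analog pool. Entries
#' failing the tree-height screen of [calibrate_samples()] are also
#' removed here (rule `"height_screen"`).
#'
#' @param samples modern `pollen_samples`.
#' @param entries calibration table from [calibrate_samples()] (same order).
#' @param dict a [pft_dictionary()] (for AP percentages).
#' @param dem elevation [fc_raster()] or `NULL` (rule skipped with warning).
#' @param class_raster land-class [fc_raster()] or `NULL` (rules skipped).
#' @param height_raster tree-height [fc_raster()] or `NULL`.
#' @param config a [qc_config()].
#' @return list with `report` (one row per sample: `id`, `dropped`, `rules`
#'   -- semicolon-separated machine-readable rule codes), `samples` and
#'   `entries` restricted to the survivors, and `counts` (drops per rule).
#' @export
qc_modern <- function(samples, entries, dict, dem = NULL, class_raster = NULL,
                      height_raster = NULL, config = qc_config()) {
  stopifnot(nrow(samples) == nrow(entries))
  n <- nrow(samples)
  rules <- vector("list", n)
  add <- function(idx, code) for (i in idx) rules[[i]] <<- c(rules[[i]], code)

  pm <- taxon_matrix(samples)
  dup_key <- paste(samples$lon, samples$lat, apply(round(pm, 6), 1, paste, collapse = "|"))
  add(which(duplicated(dup_key)), "duplicate")

  add(which(!is.na(samples$loc_error) & samples$loc_error > config$max_loc_error),
      "location_error")

  if (is.null(dem)) {
    warning("DEM missing: elevation-mismatch rule skipped")
  } else {
    dem_elev <- vapply(seq_len(n), function(i)
      raster_value(dem, samples$lon[i], samples$lat[i]), 0)
    add(which(!is.na(dem_elev) & abs(samples$elev - dem_elev) > config$max_elev_diff),
        "elevation_mismatch")
  }

  add(which(samples$context %in% config$excluded_contexts), "context_excluded")

  cnt <- samples$count_total
  low <- if (config$strict_count) cnt <= config$min_count else cnt < config$min_count
  add(which(!is.na(cnt) & low), "low_count")

  if (!is.null(class_raster)) {
    cls <- vapply(seq_len(n), function(i) {
      ij <- cell_index(class_raster, samples$lon[i], samples$lat[i])
      if (anyNA(ij)) NA_real_ else class_raster$values[ij[1], ij[2]]
    }, 0)
    medh <- if (is.null(height_raster)) rep(NA_real_, n) else
      vapply(seq_len(n), function(i)
        median_height(height_raster, samples$lon[i], samples$lat[i],
                      entries$sigma[i]), 0)
    open_ctx <- samples$context %in% config$open_contexts
    forest_ctx <- samples$context %in% config$forest_contexts
    add(which(open_ctx & !is.na(cls) & cls == LANDCLASS_FOREST &
                !is.na(entries$cover) & entries$cover > config$class_cover &
                !is.na(medh) & medh > 0),
        "class_open_mismatch")
    add(which(forest_ctx & !is.na(cls) & cls == LANDCLASS_OPEN &
                !is.na(entries$cover) & entries$cover < config$class_cover &
                !is.na(medh) & medh == 0),
        "class_forest_mismatch")
  }

  ap <- ap_percentage(pm, dict)
  exempt <- samples$context %in% config$exempt_contexts
  add(which(!exempt & ap > config$ap_thresh &
              !is.na(entries$cover) & entries$cover < config$cover_thresh),
      "ap_cover")

  add(which(!entries$screen_pass), "height_screen")
  add(which(is.na(entries$cover)), "no_cover_value")

  rule_str <- vapply(rules, function(r) paste(unique(r), collapse = ";"), "")
  dropped <- nzchar(rule_str)
  report <- data.frame(id = samples$id, dropped = dropped, rules = rule_str,
                       stringsAsFactors = FALSE)
  counts <- sort(table(unlist(lapply(rules, unique))), decreasing = TRUE)
  keep <- !dropped
  list(report = report,
       samples = samples[keep, , drop = FALSE],
       entries = entries[keep, , drop = FALSE],
       counts = counts)
}

#' Quality-filter a fossil series
#'
#' Only the terrestrial-count rule applies to fossil samples; all
#' modern-only rules are skipped.
#'
#' @param series fossil `pollen_samples` (ages required).
#' @param config a [qc_config()].
#' @export
qc_fossil <- function(series, config = qc_config()) {
  if (nrow(series) == 0) return(series)
  cnt <- series$count_total
  low <- if (config$strict_count) cnt <= config$min_count else cnt < config$min_count
  series[is.na(cnt) | !low, , drop = FALSE]
}
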