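#' Great-circle distance (meters)
#'
#' Haversine formula on a sphere with the authalic Earth radius
#' (6,371,007.2 m); window sizes used here (<= 50 km) are far below the
#' scale at which ellipsoidal corrections matter.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorized).
#' @export
gc_distance <- function(lon1, lat1, lon2, lat2) {
  r <- 6371007.2
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Extraction configuration
#'
#' Parameters of the distance-weighted raster extraction used to pair
#' modern pollen samples with forest cover: circular search radius `R`
#' (default 50 km, matching the source area assumed for regional
#' reconstructions), the three admissible Gaussian half-widths sigma, the
#' dense-forest trigger (cover above which the 100-m sigma is tried for
#' forest-context samples), the small-lake surface limit, and the cover
#' trigger that defines a small lake as "surrounded by forest".
#'
#' @param R search radius (m).
#' @param sigmas admissible sigma values (m), ascending.
#' @param dense_trigger dense-forest trigger cover (percent).
#' @param small_lake_ha small-lake surface limit (ha).
#' @param lake_forest_trigger cover (percent) around a small lake above
#'   which the 500-m sigma is used instead of 10 km.
#' @export
extraction_config <- function(R = 50000, sigmas = c(100, 500, 10000),
                              dense_trigger = 40, small_lake_ha = 20,
                              lake_forest_trigger = 40) {
  stopifnot(R > 0, all(sigmas > 0), !is.unsorted(sigmas))
  list(R = R, sigmas = sigmas, dense_trigger = dense_trigger,
       small_lake_ha = small_lake_ha, lake_forest_trigger = lake_forest_trigger)
}

# distances (m) from a point to every cell center of a raster
.cell_distances <- function(raster, lon, lat) {
  lons <- raster_lons(raster)
  lats <- raster_lats(raster)
  outer(lats, lons, function(la, lo) gc_distance(lon, lat, lo, la))
}

#' Gaussian distance-weighted raster extraction
#'
#' Weighted mean of land-pixel values within `R` of a point, with weights
#' `exp(-r^2 / (2 sigma^2))` evaluated at pixel centers. Water and no-data
#' pixels are excluded from both numerator and denominator, so their weight
#' share is transferred to the remaining pixels ("weight is automatically
#' added to the outer regions" around lakes).
#'
#' @param raster an [fc_raster()].
#' @param lon,lat sample location (decimal degrees).
#' @param sigma Gaussian half-width (m).
#' @param R search radius (m).
#' @return weighted mean (percent); `NA` with attribute `flag = "no_valid_pixels"`
#'   when no land pixel lies within the window.
#' @export
extract_cover <- function(raster, lon, lat, sigma, R = 50000) {
  stopifnot(sigma > 0, R > 0)
  d <- .cell_distances(raster, lon, lat)
  v <- raster$values
  ok <- d <= R & v != raster$nodata & v != raster$water
  if (!any(ok)) {
    out <- NA_real_
    attr(out, "flag") <- "no_valid_pixels"
    return(out)
  }
  w <- exp(-d[ok]^2 / (2 * sigma^2))
  sum(w * v[ok]) / sum(w)
}

#' Context-dependent sigma selection
#'
#' Implements the decision rules pairing each modern sample with one of the
#' three admissible Gaussian half-widths:
#' \itemize{
#'   \item moss/soil (and any other terrestrial context): sigma = 500 m;
#'   \item dense-forest or undefined-forest context with cover(500 m) above
#'     the dense trigger: sigma = 100 m is computed and kept only when it
#'     yields a higher cover (denser forest right at the sampling spot);
#'   \item lakes: sigma = 10 km, except lakes smaller than the surface limit
#'     surrounded by forested landscapes (water-excluded cover at 500 m
#'     above the trigger), which fall back to sigma = 500 m;
#'   \item unknown context: sigma = 500 m with a warning.
#' }
#'
#' @param sample one-row data frame (or list) with `lon`, `lat`, `context`
#'   and, for lakes, `lake_area_ha`.
#' @param raster forest-cover [fc_raster()].
#' @param config an [extraction_config()].
#' @return list with elements `sigma` (m) and `cover` (percent).
#' @export
select_sigma <- function(sample, raster, config = extraction_config()) {
  sg <- config$sigmas          # c(100, 500, 10000)
  ctx <- as.character(sample$context)
  cov500 <- extract_cover(raster, sample$lon, sample$lat, sg[2], config$R)
  if (!(ctx %in% .contexts)) {
    warning("unknown sampling context '", ctx, "': defaulting to sigma = ", sg[2], " m")
    return(list(sigma = sg[2], cover = cov500))
  }
  if (ctx %in% c("dense_forest", "forest_undefined")) {
    if (!is.na(cov500) && cov500 > config$dense_trigger) {
      cov100 <- extract_cover(raster, sample$lon, sample$lat, sg[1], config$R)
      if (!is.na(cov100) && cov100 > cov500)
        return(list(sigma = sg[1], cover = cov100))
    }
    return(list(sigma = sg[2], cover = cov500))
  }
  if (ctx == "lake") {
    area <- if (!is.null(sample$lake_area_ha)) sample$lake_area_ha else NA_real_
    if (!is.na(area) && area < config$small_lake_ha &&
        !is.na(cov500) && cov500 > config$lake_forest_trigger)
      return(list(sigma = sg[2], cover = cov500))
    return(list(sigma = sg[3],
                cover = extract_cover(raster, sample$lon, sample$lat, sg[3], config$R)))
  }
  list(sigma = sg[2], cover = cov500)
}

#' Median tree height within a radius
#'
#' Median of height-raster land pixels whose centers lie within `radius` of
#' the point. Water and no-data pixels are excluded.
#'
#' @param raster tree-height [fc_raster()] (m).
#' @param lon,lat point coordinates.
#' @param radius search radius (m).
#' @export
median_height <- function(raster, lon, lat, radius) {
  d <- .cell_distances(raster, lon, lat)
  v <- raster$values
  ok <- d <= radius & v != raster$nodata & v != raster$water
  # the 1-sigma area always contains the sample's own pixel, even when no
  # pixel center falls inside the radius on a coarse grid
  if (!any(ok)) return(raster_value(raster, lon, lat))
  stats::median(v[ok])
}

#' Tree-height screen for lacustrine samples
#'
#' Satellite cover maps can score tall shrubland as forest. To drop such
#' cells from the analog pool, lake samples (sigma = 10 km) located inside
#' the land-class coverage whose median tree height within 1 sigma is zero
#' are excluded. All other samples pass unscreened; if the height raster is
#' absent the screen is skipped.
#'
#' @param sample one-row data frame with `lon`, `lat`.
#' @param sigma the sigma (m) assigned by [select_sigma()].
#' @param height_raster tree-height [fc_raster()] or `NULL`.
#' @param class_raster land-class [fc_raster()]; the screen applies only to
#'   samples falling inside its coverage.
#' @return `TRUE` to keep the sample, `FALSE` to drop it.
#' @export
tree_height_screen <- function(sample, sigma, height_raster, class_raster,
                               config = extraction_config()) {
  if (is.null(height_raster)) {
    message("height raster absent: tree-height screen skipped")
    return(TRUE)
  }
  if (sigma != config$sigmas[3]) return(TRUE)
  if (!is.null(class_raster)) {
    ij <- cell_index(class_raster, sample$lon, sample$lat)
    outside <- anyNA(ij) || class_raster$values[ij[1], ij[2]] == class_raster$nodata
    if (outside) return(TRUE)  # screen applies only inside the class coverage
  }
  med <- median_height(height_raster, sample$lon, sample$lat, sigma)
  is.na(med) || med > 0
}

#' Build the calibration table for a modern sample set
#'
#' Runs [select_sigma()] and [tree_height_screen()] for every sample and
#' returns one calibration entry per sample: the extracted distance-weighted
#' forest cover, the sigma used, and the screen verdict. Entries failing the
#' screen or without valid pixels are flagged, not silently dropped.
#'
#' @param samples a `pollen_samples` table.
#' @param cover_raster,height_raster,class_raster input rasters.
#' @param config an [extraction_config()].
#' @return data frame with columns `id`, `cover`, `sigma`, `screen_pass`,
#'   `context`.
#' @export
calibrate_samples <- function(samples, cover_raster, height_raster = NULL,
                              class_raster = NULL, config = extraction_config()) {
  n <- nrow(samples)
  cover <- sigma <- numeric(n)
  pass <- logical(n)
  for (i in seq_len(n)) {
    s <- samples[i, ]
    sel <- select_sigma(s, cover_raster, config)
    cover[i] <- sel$cover
    sigma[i] <- sel$sigma
    pass[i] <- if (is.null(height_raster)) TRUE else
      tree_height_screen(s, sel$sigma, height_raster, class_raster, config)
  }
  data.frame(id = samples$id, cover = cover, sigma = sigma,
             screen_pass = pass, context = samples$context,
             stringsAsFactors = FALSE)
}
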