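#' Timeslice scheme
#'
#' The fossil record is divided into 49 timeslices with centers every 250
#' years from 12,000 to 0 BP. Each slice covers a 250-year window; a
#' boundary age belongs to the younger slice. The most recent window
#' cannot project into the future and is truncated at the youngest
#' admissible age (default -60 BP, i.e. AD 2010), so it spans 185 years
#' centered on 0 BP.
#'
#' @param oldest,step,halfwidth scheme geometry (years).
#' @param youngest youngest admissible age (BP; negative = post-1950).
#' @return data frame of class `"timeslice_scheme"` with `center`, `lower`
#'   (inclusive), `upper` (inclusive; the lower bound of the next older
#'   slice is `upper + `one year equivalent via the half-open rule).
#' @export
timeslice_scheme <- function(oldest = 12000, step = 250, halfwidth = 125,
                             youngest = -60) {
  centers <- seq(oldest, 0, by = -step)
  df <- data.frame(center = centers,
                   lower = centers - halfwidth,
                   upper = centers + halfwidth)
  df$lower[df$center == 0] <- youngest
  attr(df, "step") <- step
  attr(df, "halfwidth") <- halfwidth
  attr(df, "youngest") <- youngest
  class(df) <- c("timeslice_scheme", class(df))
  df
}

#' Assign fossil samples to timeslices
#'
#' An age `a` belongs to the slice with center `c` when
#' `a` is in `(c - 125, c + 125]`: the shared boundary age goes to the
#' younger slice. Ages older than the oldest window or younger than the
#' configured youngest age are unassigned (`NA`).
#'
#' @param ages calibrated ages (years BP).
#' @param scheme a [timeslice_scheme()].
#' @return vector of slice centers (same length as `ages`).
#' @export
assign_timeslices <- function(ages, scheme = timeslice_scheme()) {
  step <- attr(scheme, "step")
  hw <- attr(scheme, "halfwidth")
  centers <- step * ceiling((ages - hw) / step)
  out_of_range <- ages > max(scheme$center) + hw | ages < attr(scheme, "youngest") |
    centers > max(scheme$center) | centers < 0
  centers[out_of_range] <- NA_real_
  centers
}

#' Space-time interpolation configuration
#'
#' Controls the thin-plate-spline gridding of per-site reconstructions.
#' The coordinate scaling sets the anisotropy of the 4-D
#' (lon, lat, elevation, age) metric: by default one vertical kilometer
#' and one 250-year timeslice step weigh like one degree, making
#' neighboring slices and realistic elevation ranges commensurate with
#' horizontal distances.
#'
#' @param scale positive scale factors for (lon deg, lat deg, elev m,
#'   age yr).
#' @param lambda TPS smoothing (`NULL` = per-fit GCV).
#' @param mask_radius_km low-density mask: cells farther than this from
#'   every contributing site are masked.
#' @param min_sites minimum sites for a slice to be mapped.
#' @param neighborhood slices on each side contributing to a 4-D fit.
#' @param error_factor coarsening factor of the error grid relative to the
#'   value grid (the error field is produced at coarser resolution).
#' @export
interpolation_config <- function(scale = c(1, 1, 1 / 1000, 1 / 250),
                                 lambda = NULL, mask_radius_km = 250,
                                 min_sites = 6, neighborhood = 2,
                                 error_factor = 4) {
  stopifnot(all(scale > 0), mask_radius_km > 0)
  list(scale = scale, lambda = lambda, mask_radius_km = mask_radius_km,
       min_sites = min_sites, neighborhood = neighborhood,
       error_factor = error_factor)
}

# per-site slice means of a value column
.site_slice_values <- function(results, value_col) {
  agg <- stats::aggregate(results[[value_col]],
                          by = list(site = results$site, slice = results$slice,
                                    lon = results$lon, lat = results$lat,
                                    elev = results$elev),
                          FUN = mean, na.rm = TRUE)
  names(agg)[names(agg) == "x"] <- "value"
  agg[is.finite(agg$value), , drop = FALSE]
}

#' Interpolate one timeslice onto a grid
#'
#' Per-site slice means are interpolated over the DEM grid with a
#' thin-plate spline: a 4-D (lon, lat, elev, age) fit using all sites
#' within `neighborhood` slices of the target slice, or a 3-D
#' (lon, lat, elev) fit for the 0 BP slice (whose sampling is unbalanced
#' around the 0 BP mark). Cover and AP fields are clamped to `[0, 100]`;
#' cells farther than the mask radius from every contributing site are
#' masked as low-density; water cells of the land mask are masked.
#'
#' @param results data frame of per-sample reconstructions with columns
#'   `site`, `lon`, `lat`, `elev`, `slice` and the value column.
#' @param slice target slice center (years BP).
#' @param dem elevation [fc_raster()] defining the output grid (its water
#'   and no-data cells become the water/ice mask).
#' @param value_col column of `results` to interpolate (`"fit"`,
#'   `"fit_cal"`, `"ap"`, `"se"`, ...).
#' @param variable declared variable of the output field (`"cover"`,
#'   `"AP"`, `"SE"`).
#' @param config an [interpolation_config()].
#' @param mode `"4d"` (default; falls back to 3-D for slice 0) or `"3d"`.
#' @return a [gridded_field()], or `NULL` (with a message) when the slice
#'   has fewer than `min_sites` contributing sites.
#' @export
map_timeslice <- function(results, slice, dem, value_col = "fit",
                          variable = "cover", config = interpolation_config(),
                          mode = c("4d", "3d")) {
  mode <- match.arg(mode)
  if (slice == 0) mode <- "3d"
  step <- 250
  if (mode == "4d") {
    keep <- !is.na(results$slice) &
      abs(results$slice - slice) <= config$neighborhood * step
  } else {
    keep <- !is.na(results$slice) & results$slice == slice
  }
  pts <- .site_slice_values(results[keep, , drop = FALSE], value_col)
  n_sites_here <- length(unique(pts$site[pts$slice == slice]))
  if (n_sites_here < config$min_sites) {
    message(sprintf("slice %s skipped: %d sites < min_sites = %d",
                    format(slice), n_sites_here, config$min_sites))
    return(NULL)
  }
  lons <- raster_lons(dem)
  lats <- raster_lats(dem)
  elev <- dem$values
  elev_v <- as.vector(elev)          # column-major: index = (col-1)*nrow + row
  coords_grid <- cbind(lon = rep(lons, each = nrow(elev)),
                       lat = rep(lats, times = ncol(elev)),
                       elev = ifelse(elev_v == dem$nodata | elev_v == dem$water,
                                     0, elev_v))
  if (mode == "4d") {
    fit <- tps(as.matrix(pts[, c("lon", "lat", "elev", "slice")]), pts$value,
               lambda = config$lambda, scale = config$scale)
    vals <- predict(fit, cbind(coords_grid, slice))
  } else {
    fit <- tps(as.matrix(pts[, c("lon", "lat", "elev")]), pts$value,
               lambda = config$lambda, scale = config$scale[1:3])
    vals <- predict(fit, coords_grid)
  }
  vmat <- matrix(vals, nrow = nrow(dem$values))   # column-major back to matrix
  if (variable %in% c("cover", "AP")) vmat <- pmin(pmax(vmat, 0), 100)
  if (variable == "SE") vmat <- pmax(vmat, 0)
  # low-density mask: distance from each cell to the nearest contributing site
  sites <- unique(pts[pts$slice == slice | mode == "3d", c("lon", "lat")])
  if (nrow(sites) == 0) sites <- unique(pts[, c("lon", "lat")])
  dmin <- matrix(Inf, nrow(dem$values), ncol(dem$values))
  for (s in seq_len(nrow(sites))) {
    ds <- outer(lats, lons, function(la, lo)
      gc_distance(sites$lon[s], sites$lat[s], lo, la))
    dmin <- pmin(dmin, ds)
  }
  mask_ld <- dmin > config$mask_radius_km * 1000
  mask_w <- elev == dem$water | elev == dem$nodata
  gridded_field(vmat, dem$xll, dem$yll, dem$cellsize, label = slice,
                variable = variable, mask_lowdensity = mask_ld, mask_water = mask_w,
                range = if (variable == "SE") c(0, Inf) else c(0, 100))
}

#' Coarse error grid for one timeslice
#'
#' Total reconstruction error = the interpolated per-sample analog
#' standard error plus the standard error contributed by the interpolation
#' itself, estimated by a delete-one-site jackknife of the TPS prediction
#' at each coarse cell. Produced at a coarser resolution than the value
#' grid (`error_factor` cells aggregated per side).
#'
#' @param results per-sample reconstructions with columns `site`, `lon`,
#'   `lat`, `elev`, `slice`, `fit` and `se`.
#' @param slice target slice center.
#' @param dem elevation [fc_raster()] (geometry source).
#' @param config an [interpolation_config()].
#' @return a [gridded_field()] with `variable = "SE"`, or `NULL` when fewer
#'   than 3 sites contribute.
#' @export
error_grid <- function(results, slice, dem, config = interpolation_config()) {
  keep <- !is.na(results$slice) & results$slice == slice
  pts <- .site_slice_values(results[keep, , drop = FALSE], "fit")
  ses <- .site_slice_values(results[keep, , drop = FALSE], "se")
  if (nrow(pts) < 3 || nrow(ses) < 3) {
    message("error grid not produced: fewer than 3 sites in slice ", format(slice))
    return(NULL)
  }
  f <- config$error_factor
  nr <- max(1L, floor(nrow(dem$values) / f))
  nc <- max(1L, floor(ncol(dem$values) / f))
  cs <- dem$cellsize * f
  lons <- dem$xll + (seq_len(nc) - 0.5) * cs
  lats <- dem$yll + (nr - seq_len(nr) + 0.5) * cs
  coords <- cbind(lon = rep(lons, each = nr), lat = rep(lats, times = nc), elev = 0)
  # elevation of coarse cells from the DEM cell containing the center
  coords[, "elev"] <- vapply(seq_len(nrow(coords)), function(i) {
    v <- raster_value(dem, coords[i, "lon"], coords[i, "lat"])
    if (is.na(v)) 0 else v
  }, 0)
  xyz <- as.matrix(ses[, c("lon", "lat", "elev")])
  se_fit <- tps(xyz, ses$value, lambda = config$lambda, scale = config$scale[1:3])
  analog_se <- pmax(0, predict(se_fit, coords))
  jk <- tps_jackknife_se(as.matrix(pts[, c("lon", "lat", "elev")]), pts$value,
                         coords, lambda = config$lambda, scale = config$scale[1:3])
  total <- matrix(analog_se + ifelse(is.na(jk), 0, jk), nrow = nr)
  gridded_field(pmax(total, 0), dem$xll, dem$yll, cs, label = slice,
                variable = "SE", range = c(0, Inf))
}
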