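#' Region polygons
#'
#' Regions are closed polygons in lon/lat used for area-average summaries.
#' A region set is a named list of two-column matrices (lon, lat). Polygons
#' may not overlap; cells outside all regions are ignored.
#'
#' @param ... named polygons, each a two-column matrix or data frame.
#' @export
region_set <- function(...) {
  regs <- list(...)
  if (length(regs) == 1 && is.list(regs[[1]]) && !is.data.frame(regs[[1]]) &&
      !is.matrix(regs[[1]])) regs <- regs[[1]]
  regs <- lapply(regs, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2)
    p
  })
  if (is.null(names(regs)) || any(!nzchar(names(regs))))
    names(regs) <- paste0("region_", seq_along(regs))
  regs
}

# which grid cells (given lon/lat vectors per cell) fall inside a polygon
.cells_in_polygon <- function(lon, lat, poly) {
  mgcv::in.out(rbind(poly, poly[1, ]), cbind(lon, lat))
}

#' Regional area-average time series
#'
#' Per region and timeslice: the cosine-latitude area-weighted mean of the
#' unmasked land cells inside the region polygon, and the (weighted)
#' standard deviation. The deviation measures inter-cell variability of the
#' field, not the error of the reconstruction. Water/ice and low-density
#' cells are excluded; a region with no unmasked cell in a slice yields
#' `NA`.
#'
#' @param fields list of [gridded_field()]s (one per timeslice, shared
#'   geometry).
#' @param regions a [region_set()].
#' @return data frame with `region`, `slice`, `mean`, `sd`, `n_cells`.
#' @export
regional_series <- function(fields, regions) {
  fields <- fields[!vapply(fields, is.null, TRUE)]
  stopifnot(length(fields) > 0)
  f1 <- fields[[1]]
  lons <- f1$xll + (seq_len(ncol(f1$values)) - 0.5) * f1$cellsize
  lats <- f1$yll + (nrow(f1$values) - seq_len(nrow(f1$values)) + 0.5) * f1$cellsize
  cell_lon <- rep(lons, each = nrow(f1$values))
  cell_lat <- rep(lats, times = ncol(f1$values))
  w_area <- cos(cell_lat * pi / 180)
  inside <- lapply(regions, function(p) .cells_in_polygon(cell_lon, cell_lat, p))
  out <- list()
  for (f in fields) {
    v <- as.vector(f$values)
    for (rn in names(regions)) {
      sel <- inside[[rn]] & !is.na(v)
      if (any(sel)) {
        w <- w_area[sel] / sum(w_area[sel])
        m <- sum(w * v[sel])
        s <- sqrt(sum(w * (v[sel] - m)^2))
      } else {
        m <- s <- NA_real_
      }
      out[[length(out) + 1]] <- data.frame(region = rn, slice = f$label,
                                           mean = m, sd = s, n_cells = sum(sel),
                                           stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Elevation caps per period
#'
#' Site coverage thins at high altitude early in the record, so band
#' summaries are capped: below 2,800 m throughout, lowered to 2,400 m
#' before 11,000 BP and to 2,600 m from 10,000 to 11,000 BP.
#'
#' @param age slice center (years BP).
#' @export
default_elevation_cap <- function(age) {
  ifelse(age > 11000, 2400, ifelse(age > 10000, 2600, 2800))
}

#' Elevation-band summary of gridded reconstructions
#'
#' Groups the cells of a region into 200-m elevation bands (cells below
#' 400 m form a single band) and reports the mean cover per band and
#' timeslice, plus the forest-threshold track: the upper edge of the
#' highest band whose mean cover exceeds the threshold (50 percent, a
#' simplistic timberline indicator). Bands above the period's elevation
#' cap are flagged `capped` and carry `NA` means rather than being dropped.
#'
#' @param fields list of [gridded_field()]s.
#' @param dem elevation [fc_raster()] co-registered with the fields.
#' @param region polygon (two-column matrix) or `NULL` for the whole grid.
#' @param cap_fun function age -> maximum elevation (m); default
#'   [default_elevation_cap()].
#' @param threshold forest threshold (percent).
#' @param band_width band width (m); lowest band is `(-Inf, 400)`.
#' @return list with `bands` (data frame `slice`, `band_lower`,
#'   `band_upper`, `mean`, `n_cells`, `capped`) and `track` (data frame
#'   `slice`, `threshold_elev` -- `NA` when no band exceeds the threshold).
#' @export
elevation_bands <- function(fields, dem, region = NULL,
                            cap_fun = default_elevation_cap,
                            threshold = 50, band_width = 200) {
  fields <- fields[!vapply(fields, is.null, TRUE)]
  stopifnot(length(fields) > 0)
  elev_v <- as.vector(dem$values)
  land <- elev_v != dem$nodata & elev_v != dem$water
  lons <- raster_lons(dem)
  lats <- raster_lats(dem)
  cell_lon <- rep(lons, each = nrow(dem$values))
  cell_lat <- rep(lats, times = ncol(dem$values))
  inside <- if (is.null(region)) rep(TRUE, length(elev_v)) else
    .cells_in_polygon(cell_lon, cell_lat, as.matrix(region))
  top <- max(2800, max(elev_v[land], 0))
  edges <- c(-Inf, seq(400, top + band_width, by = band_width))
  bands_rows <- list()
  track_rows <- list()
  for (f in fields) {
    v <- as.vector(f$values)
    cap <- cap_fun(f$label)
    best <- NA_real_
    for (b in seq_len(length(edges) - 1)) {
      lo <- edges[b]; up <- edges[b + 1]
      capped <- up > cap
      sel <- inside & land & !is.na(v) & elev_v >= lo & elev_v < up
      m <- if (!capped && any(sel)) mean(v[sel]) else NA_real_
      bands_rows[[length(bands_rows) + 1]] <-
        data.frame(slice = f$label, band_lower = lo, band_upper = up,
                   mean = m, n_cells = sum(sel), capped = capped)
      if (!capped && !is.na(m) && m > threshold) best <- max(best, up, na.rm = TRUE)
    }
    track_rows[[length(track_rows) + 1]] <-
      data.frame(slice = f$label, threshold_elev = best)
  }
  list(bands = do.call(rbind, bands_rows), track = do.call(rbind, track_rows))
}

#' Locate the maximum of a noisy time series
#'
#' The timing of a forest-cover maximum is read from a local quadratic
#' smooth (loess) of the series rather than the raw argmax: near a broad
#' mid-Holocene plateau the curvature over two or three slices is smaller
#' than the reconstruction noise, so the raw argmax is noise-dominated
#' while the smoothed argmax is stable.
#'
#' @param slice slice centers (years BP).
#' @param value series values.
#' @param span loess span.
#' @return the slice center at which the smoothed series is maximal.
#' @export
series_peak <- function(slice, value, span = 0.35) {
  ok <- !is.na(value)
  f <- stats::loess(value[ok] ~ slice[ok], span = span, degree = 2)
  slice[ok][which.max(stats::fitted(f))]
}

.series_stats <- function(a, b) {
  n <- length(a)
  if (n < 3) return(data.frame(n = n, r = NA_real_, mad = NA_real_,
                               slope = NA_real_, intercept = NA_real_))
  co <- stats::coef(stats::lm(b ~ a))
  data.frame(n = n,
             r = if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b) else NA_real_,
             mad = mean(abs(a - b)),
             slope = unname(co[2]), intercept = unname(co[1]))
}

#' Align and compare a reconstruction against a reference series
#'
#' Re-bins both series onto common time windows of the reference's width
#' (default 200 years, the resolution at which mechanistic
#' pollen-productivity reconstructions are typically run) and returns
#' paired Pearson correlation, mean absolute difference, and the
#' least-squares slope/intercept of reference on reconstruction -- overall
#' and for the Early (11,700-8,100 BP), Mid (8,100-4,100 BP) and Late
#' (4,100-0 BP) Holocene sub-periods.
#'
#' @param x reconstruction series: data frame with `age`, `value`.
#' @param reference reference series: data frame with `age`, `value`.
#' @param window bin width (years).
#' @return list with `overall` (one-row data frame) and `periods`
#'   (per-sub-period rows); fewer than 3 paired windows gives `NA`
#'   statistics.
#' @export
compare_series <- function(x, reference, window = 200) {
  bin <- function(df) {
    b <- window * floor(df$age / window) + window / 2
    stats::aggregate(list(value = df$value), list(bin = b), mean, na.rm = TRUE)
  }
  bx <- bin(x); br <- bin(reference)
  m <- merge(bx, br, by = "bin", suffixes = c("_x", "_ref"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  periods <- data.frame(name = c("early", "mid", "late"),
                        from = c(11700, 8100, 4100), to = c(8100, 4100, 0))
  per <- do.call(rbind, lapply(seq_len(nrow(periods)), function(i) {
    sel <- m$bin <= periods$from[i] & m$bin > periods$to[i]
    cbind(period = periods$name[i], .series_stats(m$value_x[sel], m$value_ref[sel]))
  }))
  list(overall = .series_stats(m$value_x, m$value_ref), periods = per,
       paired = m)
}
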