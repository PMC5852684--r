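#' Lon/lat raster grid
#'
#' A minimal single-band raster on a regular longitude/latitude grid.
#' Values are stored as a matrix whose first row is the northernmost row
#' (the ESRI ASCII grid convention). Two reserved codes mark cells without
#' data: `nodata` for missing land values and `water` for water bodies --
#' the distinction matters because water cells are excluded from kernel
#' averaging while remaining part of the grid geometry.
#'
#' @param values numeric matrix, row 1 = north.
#' @param xll,yll longitude/latitude of the lower-left corner of the grid
#'   (cell edge, decimal degrees).
#' @param cellsize cell size in decimal degrees.
#' @param nodata reserved no-data code.
#' @param water reserved water code (must differ from `nodata`).
#' @return an object of class `fc_raster`.
#' @export
fc_raster <- function(values, xll, yll, cellsize, nodata = -9999, water = -3333) {
  stopifnot(is.matrix(values), cellsize > 0)
  if (identical(nodata, water)) stop("water code must differ from no-data code")
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize,
                 nodata = nodata, water = water),
            class = "fc_raster")
}

#' @export
print.fc_raster <- function(x, ...) {
  v <- land_values(x)
  cat(sprintf("fc_raster: %d x %d cells, %.4f deg, origin (%.4f, %.4f)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  cat(sprintf("  land cells: %d, water: %d, nodata: %d\n",
              length(v), sum(x$values == x$water), sum(x$values == x$nodata)))
  if (length(v)) cat(sprintf("  value range: [%.2f, %.2f]\n", min(v), max(v)))
  invisible(x)
}

#' @rdname fc_raster
#' @param r an `fc_raster`.
#' @export
land_values <- function(r) {
  v <- r$values
  v[v != r$nodata & v != r$water]
}

# Cell-center coordinates. Column j has lon xll + (j - 1/2) * cs; row i
# (counted from the north) has lat yll + (nrow - i + 1/2) * cs.
raster_lons <- function(r) r$xll + (seq_len(ncol(r$values)) - 0.5) * r$cellsize
raster_lats <- function(r) r$yll + (nrow(r$values) - seq_len(nrow(r$values)) + 0.5) * r$cellsize

#' Locate the cell containing a point
#'
#' Cells are half-open intervals `[edge, edge + cellsize)` in both axes so
#' that every point maps to exactly one cell.
#'
#' @param r an `fc_raster`.
#' @param lon,lat point coordinates (decimal degrees).
#' @return integer vector `c(row, col)`, or `NA` if outside the grid.
#' @export
cell_index <- function(r, lon, lat) {
  j <- floor((lon - r$xll) / r$cellsize) + 1L
  i_from_south <- floor((lat - r$yll) / r$cellsize) + 1L
  i <- nrow(r$values) - i_from_south + 1L
  if (j < 1L || j > ncol(r$values) || i < 1L || i > nrow(r$values)) return(c(NA_integer_, NA_integer_))
  c(i, j)
}

#' @rdname cell_index
#' @export
raster_value <- function(r, lon, lat) {
  ij <- cell_index(r, lon, lat)
  if (anyNA(ij)) return(NA_real_)
  v <- r$values[ij[1], ij[2]]
  if (v == r$nodata || v == r$water) NA_real_ else v
}

#' Read/write rasters as ESRI ASCII grids
#'
#' Plain-text interchange format readable by standard GIS tools. The water
#' code is not part of the ASCII grid header, so it is passed explicitly on
#' read and recorded as a trailing comment line (ignored by other readers).
#'
#' @param r an `fc_raster`.
#' @param path file path.
#' @export
write_asc <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", r$nodata)), con)
  writeLines(apply(r$values, 1, function(row)
    paste(sprintf("%.17g", row), collapse = " ")), con)
  writeLines(sprintf("# water_value %.10g", r$water), con)
  invisible(path)
}

#' @rdname write_asc
#' @param water water code to assume when the trailing comment is absent.
#' @export
read_asc <- function(path, water = -3333) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  wline <- grep("^# water_value", lines, value = TRUE)
  if (length(wline)) water <- as.numeric(sub("^# water_value\\s+", "", wline[1]))
  body <- lines[-(1:6)]
  body <- body[!startsWith(body, "#") & nzchar(trimws(body))]
  vals <- matrix(scan(text = body, quiet = TRUE), nrow = h[["nrows"]], byrow = TRUE)
  fc_raster(vals, h[["xllcorner"]], h[["yllcorner"]], h[["cellsize"]],
            nodata = h[["nodata_value"]], water = water)
}

#' Gridded output field with masks
#'
#' One interpolated timeslice field (forest cover, AP, or a standard-error
#' surface) together with its low-density and water/ice masks and grid
#' geometry. Masked cells carry `NA` in `values`; the two masks record why.
#'
#' @param values numeric matrix (row 1 = north), `NA` where masked.
#' @param xll,yll,cellsize grid geometry as in [fc_raster()].
#' @param label timeslice label (age BP of the slice center).
#' @param variable one of `"cover"`, `"AP"`, `"SE"`.
#' @param mask_lowdensity,mask_water logical matrices, `TRUE` = masked.
#' @param range declared valid range for unmasked values.
#' @export
gridded_field <- function(values, xll, yll, cellsize, label = NA_real_,
                          variable = "cover",
                          mask_lowdensity = NULL, mask_water = NULL,
                          range = if (variable == "SE") c(0, Inf) else c(0, 100)) {
  stopifnot(is.matrix(values))
  if (is.null(mask_lowdensity)) mask_lowdensity <- matrix(FALSE, nrow(values), ncol(values))
  if (is.null(mask_water)) mask_water <- matrix(FALSE, nrow(values), ncol(values))
  values[mask_lowdensity | mask_water] <- NA_real_
  ok <- !is.na(values)
  if (any(ok) && (min(values[ok]) < range[1] - 1e-9 || max(values[ok]) > range[2] + 1e-9))
    stop("unmasked values outside declared range")
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize,
                 label = label, variable = variable,
                 mask_lowdensity = mask_lowdensity, mask_water = mask_water,
                 range = range),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("gridded_field [%s] slice %s: %d x %d cells, %d masked\n",
              x$variable, format(x$label), nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

fmt_block <- function(m) {
  apply(m, 1, function(row)
    paste(ifelse(is.na(row), "NA", sprintf("%.17g", row)), collapse = " "))
}

write_field_block <- function(f, con) {
  writeLines(c("FIELD",
               sprintf("ncols %d", ncol(f$values)),
               sprintf("nrows %d", nrow(f$values)),
               sprintf("xll %.10g", f$xll),
               sprintf("yll %.10g", f$yll),
               sprintf("cellsize %.10g", f$cellsize),
               sprintf("label %.10g", f$label),
               sprintf("variable %s", f$variable),
               sprintf("range %.10g %.10g", f$range[1], f$range[2]),
               "VALUES"), con)
  writeLines(fmt_block(f$values), con)
  writeLines("MASK_LOWDENSITY", con)
  writeLines(apply(f$mask_lowdensity, 1, function(r) paste(as.integer(r), collapse = " ")), con)
  writeLines("MASK_WATER", con)
  writeLines(apply(f$mask_water, 1, function(r) paste(as.integer(r), collapse = " ")), con)
}

#' Read/write gridded fields and timeslice stacks as plain text
#'
#' A self-describing delimited-text container holding one or more
#' [gridded_field()]s (a stack of timeslices shares one grid geometry).
#' Round trips preserve values, masks, labels and geometry exactly.
#'
#' @param x a `gridded_field` or a list of them.
#' @param path file path.
#' @export
write_grid <- function(x, path) {
  if (inherits(x, "gridded_field")) x <- list(x)
  geo <- vapply(x, function(f) c(f$xll, f$yll, f$cellsize, nrow(f$values), ncol(f$values)),
                numeric(5))
  if (length(x) > 1 && any(apply(geo, 1, function(g) diff(range(g)) > 0)))
    stop("all fields in a stack must share one grid geometry")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# matcover grid stack v1", sprintf("NFIELDS %d", length(x))), con)
  for (f in x) write_field_block(f, con)
  invisible(path)
}

#' @rdname write_grid
#' @return `read_grid` returns a list of `gridded_field`s (length-1 list for a
#'   single field).
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  nf <- as.integer(sub("NFIELDS ", "", grep("^NFIELDS", lines, value = TRUE)[1]))
  starts <- which(lines == "FIELD")
  stopifnot(length(starts) == nf)
  out <- vector("list", nf)
  for (s in seq_len(nf)) {
    i <- starts[s]
    hdr <- lines[(i + 1):(i + 8)]
    get <- function(key) sub(paste0(key, " "), "", grep(paste0("^", key, " "), hdr, value = TRUE)[1])
    nc <- as.integer(get("ncols")); nr <- as.integer(get("nrows"))
    rng <- as.numeric(strsplit(get("range"), " ")[[1]])
    j <- i + 9  # "VALUES" marker
    stopifnot(lines[j] == "VALUES")
    vals <- matrix(suppressWarnings(as.numeric(scan(text = lines[(j + 1):(j + nr)],
                                                    what = "", quiet = TRUE))),
                   nrow = nr, byrow = TRUE)
    j <- j + nr + 1
    stopifnot(lines[j] == "MASK_LOWDENSITY")
    mld <- matrix(scan(text = lines[(j + 1):(j + nr)], quiet = TRUE) == 1, nrow = nr, byrow = TRUE)
    j <- j + nr + 1
    stopifnot(lines[j] == "MASK_WATER")
    mw <- matrix(scan(text = lines[(j + 1):(j + nr)], quiet = TRUE) == 1, nrow = nr, byrow = TRUE)
    out[[s]] <- gridded_field(vals, as.numeric(get("xll")), as.numeric(get("yll")),
                              as.numeric(get("cellsize")), label = as.numeric(get("label")),
                              variable = get("variable"),
                              mask_lowdensity = mld, mask_water = mw, range = rng)
  }
  out
}
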