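#' Pollen sample tables
#'
#' Modern and fossil pollen samples are plain data frames carrying metadata
#' columns plus one column per terrestrial pollen taxon. The taxon columns
#' are recorded in the `"taxa"` attribute; taxon values are percentages of
#' the terrestrial sum (0-100) and the raw terrestrial count is kept in
#' `count_total`. Ages follow the BP convention (calibrated years before
#' AD 1950; a sample collected in AD 2010 has age -60).
#'
#' Mandatory metadata columns: `id`, `lon`, `lat`, `elev`, `age`, `context`.
#' Optional: `loc_error` (geolocation error estimate, m; may be `NA`),
#' `lake_area_ha` (lake surface for lacustrine samples), `count_total`.
#'
#' @name pollen_samples
NULL

.contexts <- c("moss", "soil", "lake", "dense_forest", "forest_undefined",
               "treeless", "pasture", "riverine", "estuarine", "unknown")

#' @rdname pollen_samples
#' @param df a data frame.
#' @param taxa character vector naming the taxon columns of `df`.
#' @export
as_pollen_samples <- function(df, taxa) {
  stopifnot(all(c("id", "lon", "lat", "elev", "age", "context") %in% names(df)),
            all(taxa %in% names(df)))
  if (any(df$lon < -180 | df$lon > 180) || any(df$lat < -90 | df$lat > 90))
    stop("coordinates outside valid lon/lat ranges")
  pm <- as.matrix(df[, taxa, drop = FALSE])
  if (any(pm < 0)) stop("negative taxon values")
  s <- rowSums(pm)
  if (any(abs(s - 100) > 0.5 & s > 0))
    stop("taxon percentages must sum to 100 (+/- 0.5)")
  if (!"loc_error" %in% names(df)) df$loc_error <- NA_real_
  if (!"count_total" %in% names(df)) df$count_total <- NA_real_
  attr(df, "taxa") <- taxa
  class(df) <- c("pollen_samples", class(df))
  df
}

#' @rdname pollen_samples
#' @param x a `pollen_samples` table.
#' @export
sample_taxa <- function(x) attr(x, "taxa")

#' @export
`[.pollen_samples` <- function(x, ...) {
  taxa <- attr(x, "taxa")
  out <- NextMethod()
  if (is.data.frame(out) && all(taxa %in% names(out))) {
    attr(out, "taxa") <- taxa
    if (!inherits(out, "pollen_samples")) class(out) <- c("pollen_samples", class(out))
  }
  out
}

#' @rdname pollen_samples
#' @export
taxon_matrix <- function(x) as.matrix(x[, attr(x, "taxa"), drop = FALSE])

#' Read a pollen sample table from delimited text
#'
#' The field separator (comma or tab) is autodetected from the header line.
#' Non-metadata numeric columns are taken as per-taxon counts and converted
#' to percentages of their row sum; the raw terrestrial total is retained in
#' `count_total`. Taxon names are matched against the dictionary
#' case-insensitively after whitespace normalization; columns absent from the
#' dictionary are carried through unmapped with a warning.
#'
#' @param path file path.
#' @param dictionary optional [pft_dictionary()] used to check taxon names.
#' @return a `pollen_samples` data frame (see [pollen_samples]).
#' @export
read_samples <- function(path, dictionary = NULL) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  meta <- c("id", "lon", "lat", "elev", "age", "context", "loc_error",
            "lake_area_ha", "count_total")
  missing <- setdiff(c("id", "lon", "lat", "elev", "age", "context"), names(df))
  if (length(missing)) stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  taxa <- setdiff(names(df), meta)
  cnt <- as.matrix(df[, taxa, drop = FALSE])
  if (any(cnt < 0)) stop("negative count in taxon column(s)")
  if (!is.null(dictionary)) {
    known <- normalize_taxon(dictionary$taxon)
    unmapped <- taxa[!(normalize_taxon(taxa) %in% known)]
    if (length(unmapped))
      warning("taxon column(s) not in dictionary, carried through unmapped: ",
              paste(unmapped, collapse = ", "))
  }
  tot <- rowSums(cnt)
  df$count_total <- tot
  pct <- cnt
  nz <- tot > 0
  pct[nz, ] <- 100 * cnt[nz, , drop = FALSE] / tot[nz]
  df[, taxa] <- pct
  as_pollen_samples(df, taxa)
}

#' @rdname read_samples
#' @param x a `pollen_samples` table.
#' @export
write_samples <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# canonical form used for taxon-name matching
normalize_taxon <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Renormalize taxon percentages to sum to 100
#'
#' Idempotent; rows with an all-zero assemblage are left untouched.
#' @param x a `pollen_samples` table.
#' @export
normalize_percentages <- function(x) {
  taxa <- attr(x, "taxa")
  pm <- as.matrix(x[, taxa, drop = FALSE])
  s <- rowSums(pm)
  nz <- s > 0
  pm[nz, ] <- 100 * pm[nz, , drop = FALSE] / s[nz]
  x[, taxa] <- pm
  x
}
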