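#' Synthetic world configuration
#'
#' Parameters of the synthetic landscape generator: a domain in lon/lat, a
#' smooth latent forest-cover field with a configurable spatial correlation
#' length, companion tree-height / land-class / elevation rasters, modern
#' pollen samples drawn from a forward model with long-distance-transport
#' mixing, and fossil cores driven by a prescribed forest-cover history.
#' Every generated quantity keeps its ground truth, so downstream recovery
#' is checkable.
#'
#' The forward model: the expected arboreal share of an assemblage equals
#' the local true cover fraction, blended with a fixed long-distance
#' background composition as `(1 - lambda) * local + lambda * background`;
#' within the arboreal and open groups taxa split by fixed
#' pollen-productivity multipliers; counts are multinomial.
#'
#' @param lon_range,lat_range domain bounds (decimal degrees).
#' @param res_m raster resolution (m).
#' @param corr_len_m spatial correlation length of the cover field (m):
#'   the distance at which the field's autocorrelation falls to 1/e.
#' @param dict taxon dictionary with productivity column (default
#'   [synthetic_pft_dictionary()]).
#' @param transport_frac long-distance-transport fraction lambda in [0, 1].
#' @param background_ap arboreal share of the long-distance background.
#' @param count_total pollen grains counted per sample.
#' @param n_modern,n_fossil_sites,n_per_site sample sizes.
#' @param defect_frac fraction of modern samples receiving an injected
#'   metadata defect (location error, elevation mismatch, low count, or a
#'   riverine context), labelled in the ground truth.
#' @param history function age -> cover multiplier relative to present
#'   (default: deglacial rise to a mid-Holocene maximum near 7,250 BP
#'   followed by decline, the trend-level shape of the European record).
#' @param age_range ages (BP) over which fossil cores are generated.
#' @param constant_cover if non-`NULL`, a degenerate constant cover field.
#' @param noiseless if `TRUE`, assemblages are the exact expected
#'   percentages (no multinomial noise).
#' @param shrub_patch include a tall-shrubland patch (cover > 0, height 0)
#'   to exercise the tree-height screen.
#' @param seed random seed.
#' @export
world_config <- function(lon_range = c(6, 12), lat_range = c(45, 49),
                         res_m = 8000, corr_len_m = 60000,
                         dict = synthetic_pft_dictionary(),
                         transport_frac = 0.15, background_ap = 0.35,
                         count_total = 400,
                         n_modern = 150, n_fossil_sites = 8, n_per_site = 80,
                         defect_frac = 0, history = default_history,
                         age_range = c(0, 12000),
                         constant_cover = NULL, noiseless = FALSE,
                         shrub_patch = TRUE, seed = 1) {
  if (res_m <= 0) stop("raster resolution must be positive")
  if (transport_frac < 0 || transport_frac > 1)
    stop("transport fraction must lie in [0, 1]")
  if (nrow(dict) == 0) stop("empty taxon list")
  h <- history(seq(age_range[1], age_range[2], length.out = 49))
  if (any(!is.finite(h)) || any(h < 0))
    stop("history multiplier must be finite and non-negative over the age range")
  list(lon_range = lon_range, lat_range = lat_range, res_m = res_m,
       corr_len_m = corr_len_m, dict = dict,
       transport_frac = transport_frac, background_ap = background_ap,
       count_total = count_total, n_modern = n_modern,
       n_fossil_sites = n_fossil_sites, n_per_site = n_per_site,
       defect_frac = defect_frac, history = history, age_range = age_range,
       constant_cover = constant_cover, noiseless = noiseless,
       shrub_patch = shrub_patch, seed = seed)
}

#' Default forest-cover history multiplier
#'
#' Cover relative to present: sparse late-glacial landscapes (about 55
#' percent of present), a rise to a maximum of 1.8 times present centered
#' near 7,250 BP (inside the 8,500-6,000 BP window of maximum Holocene
#' forest), then decline to the present level.
#'
#' @param age calibrated years BP (vectorized).
#' @export
default_history <- function(age) {
  base <- 1 - 0.45 * age / 12000
  bump <- 1.072 * exp(-((age - 7250) / 2200)^2)
  pmax(0, base + bump)
}

# Gaussian smoothing of a matrix with edge renormalization, via row/column
# smoothing operators (exact separable filter for these grid sizes).
.gaussian_smooth <- function(m, sigma_cells) {
  smoother <- function(n) {
    s <- outer(seq_len(n), seq_len(n), function(i, j) stats::dnorm(i - j, sd = sigma_cells))
    s / rowSums(s)
  }
  smoother(nrow(m)) %*% m %*% t(smoother(ncol(m)))
}

#' Generate the synthetic cover, height, land-class and elevation rasters
#'
#' The latent cover field is filtered Gaussian noise (kernel width tied to
#' the configured correlation length) rescaled to `[0, 100]`; a lake blob
#' provides water cells; tree height is a monotone function of cover plus
#' noise, with an optional tall-shrubland patch (cover > 0, height 0); the
#' land-class raster marks open/forest/water; elevation is an independent
#' smooth field in `[0, 2000]` m.
#'
#' @param config a [world_config()].
#' @return list of [fc_raster()]s: `cover`, `height`, `landclass`, `dem`.
#' @export
generate_cover_raster <- function(config) {
  set.seed(config$seed)
  res_deg <- config$res_m / 111320
  nx <- max(8L, ceiling(diff(config$lon_range) / res_deg))
  ny <- max(8L, ceiling(diff(config$lat_range) / res_deg))
  sigma_cells <- config$corr_len_m / (2 * config$res_m)  # 1/e distance = corr_len
  field <- .gaussian_smooth(matrix(stats::rnorm(ny * nx), ny, nx), sigma_cells)
  field <- 100 * (field - min(field)) / (max(field) - min(field))
  if (!is.null(config$constant_cover)) field[] <- config$constant_cover
  # lake blob in the west-central part of the domain
  ci <- round(ny * 0.4); cj <- round(nx * 0.3)
  lake <- outer(seq_len(ny), seq_len(nx),
                function(i, j) sqrt((i - ci)^2 + (j - cj)^2)) <= max(2, round(nx / 28))
  height <- pmax(0.3 * field + stats::rnorm(ny * nx, sd = 0.5), 0)  # pmax keeps dims of arg 1
  height[field < 5] <- 0
  if (config$shrub_patch) {
    pi_ <- seq(max(1, ny - 4), ny)
    pj <- seq(max(1, nx - 4), nx)
    field[pi_, pj] <- pmax(field[pi_, pj], 30)  # shrubby cover, zero height
    height[pi_, pj] <- 0
  }
  landclass <- matrix(LANDCLASS_OPEN, ny, nx)
  landclass[field > 40 & height > 0] <- LANDCLASS_FOREST
  dem <- .gaussian_smooth(matrix(stats::rnorm(ny * nx), ny, nx), sigma_cells / 2)
  dem <- 2000 * (dem - min(dem)) / (max(dem) - min(dem))
  water <- -3333
  field[lake] <- water
  height[lake] <- water
  landclass[lake] <- water
  dem[lake] <- water
  xll <- config$lon_range[1]; yll <- config$lat_range[1]
  list(cover = fc_raster(field, xll, yll, res_deg, water = water),
       height = fc_raster(height, xll, yll, res_deg, water = water),
       landclass = fc_raster(landclass, xll, yll, res_deg, water = water),
       dem = fc_raster(dem, xll, yll, res_deg, water = water))
}

#' Expected assemblage of the forward model
#'
#' @param fc true forest cover (percent).
#' @param config a [world_config()].
#' @return named vector of expected taxon proportions (sum 1).
#' @export
expected_assemblage <- function(fc, config) {
  dict <- config$dict
  forest <- dict$arboreal & !dict$dwarf_shrub & !dict$vine
  wf <- ifelse(forest, dict$productivity, 0); wf <- wf / sum(wf)
  wo <- ifelse(!forest, dict$productivity, 0); wo <- wo / sum(wo)
  mix <- function(ap) ap * wf + (1 - ap) * wo
  lam <- config$transport_frac
  p <- (1 - lam) * mix(fc / 100) + lam * mix(config$background_ap)
  stats::setNames(p, dict$taxon)
}

.draw_assemblage <- function(fc, config, total) {
  p <- expected_assemblage(fc, config)
  if (config$noiseless) return(100 * p)
  cnt <- stats::rmultinom(1, total, p)[, 1]
  if (sum(cnt) == 0) return(100 * p)
  100 * cnt / sum(cnt)
}

# random land cell centers (with sub-cell jitter unless jitter = 0)
.sample_land_cells <- function(rasters, n, jitter = 0.3, replace = TRUE) {
  r <- rasters$cover
  land <- which(r$values != r$nodata & r$values != r$water)
  cells <- sample(land, n, replace = replace)
  ny <- nrow(r$values)
  i <- (cells - 1) %% ny + 1
  j <- (cells - 1) %/% ny + 1
  lon <- r$xll + (j - 0.5 + stats::runif(n, -jitter, jitter)) * r$cellsize
  lat <- r$yll + (ny - i + 0.5 + stats::runif(n, -jitter, jitter)) * r$cellsize
  data.frame(cell = cells, lon = lon, lat = lat,
             cover = r$values[cells],
             elev = rasters$dem$values[cells])
}

#' Generate modern pollen samples over a synthetic landscape
#'
#' Samples are placed at random land cells with context labels, collection
#' ages around the present, and assemblages drawn from the forward model at
#' the local true cover. A configurable fraction receives one injected
#' metadata defect (location jitter > 100 m, elevation mismatch > 200 m,
#' low count, or a riverine context), recorded in the returned truth table.
#'
#' @param rasters output of [generate_cover_raster()].
#' @param config a [world_config()].
#' @return list with `samples` (a `pollen_samples` table) and `truth`
#'   (data frame `id`, `true_cover`, `defect`).
#' @export
generate_modern_samples <- function(rasters, config) {
  if (nrow(config$dict) == 0) stop("empty taxon list")
  n <- config$n_modern
  loc <- .sample_land_cells(rasters, n)
  ctx <- sample(c("moss", "soil", "lake", "dense_forest", "treeless"), n,
                replace = TRUE, prob = c(0.35, 0.25, 0.15, 0.15, 0.10))
  ctx[ctx == "dense_forest" & loc$cover < 45] <- "soil"
  lake_area <- ifelse(ctx == "lake", round(stats::runif(n, 5, 200), 1), NA_real_)
  age <- round(stats::runif(n, -60, 60))
  loc_error <- ifelse(stats::runif(n) < 0.2, NA_real_, round(stats::runif(n, 0, 80)))
  totals <- rep(config$count_total, n)
  defect <- rep("none", n)
  elev <- loc$elev
  ndef <- round(config$defect_frac * n)
  if (ndef > 0) {
    di <- sample.int(n, ndef)
    types <- sample(c("loc_error", "elev_mismatch", "low_count", "riverine"),
                    ndef, replace = TRUE)
    defect[di] <- types
    loc_error[di[types == "loc_error"]] <- round(stats::runif(sum(types == "loc_error"), 120, 500))
    em <- di[types == "elev_mismatch"]
    elev[em] <- elev[em] + sample(c(-1, 1), length(em), replace = TRUE) *
      stats::runif(length(em), 250, 600)
    totals[di[types == "low_count"]] <- 60
    ctx[di[types == "riverine"]] <- "riverine"
  }
  pm <- t(vapply(seq_len(n), function(i)
    .draw_assemblage(loc$cover[i], config, totals[i]),
    numeric(nrow(config$dict))))
  colnames(pm) <- config$dict$taxon
  df <- data.frame(id = sprintf("M%04d", seq_len(n)), lon = loc$lon, lat = loc$lat,
                   elev = elev, age = age, context = ctx,
                   loc_error = loc_error, lake_area_ha = lake_area,
                   count_total = totals, stringsAsFactors = FALSE)
  df <- cbind(df, pm)
  list(samples = as_pollen_samples(df, config$dict$taxon),
       truth = data.frame(id = df$id, true_cover = loc$cover, defect = defect,
                          stringsAsFactors = FALSE))
}

#' Generate fossil pollen cores driven by the prescribed history
#'
#' Per site, samples at irregular ages spanning the configured age range;
#' each assemblage is drawn from the same forward model evaluated at the
#' site's true cover history `clamp(present_cover * history(age), 0, 100)`.
#'
#' @inheritParams generate_modern_samples
#' @return list with `samples` (a `pollen_samples` table with a `site`
#'   column) and `truth` (`site`, `age`, `true_cover`).
#' @export
generate_fossil_cores <- function(rasters, config) {
  sites <- .sample_land_cells(rasters, config$n_fossil_sites, jitter = 0,
                              replace = FALSE)
  rows <- list(); truths <- list()
  for (s in seq_len(nrow(sites))) {
    ages <- sort(stats::runif(config$n_per_site,
                              config$age_range[1], config$age_range[2]))
    fc <- pmin(100, pmax(0, sites$cover[s] * config$history(ages)))
    pm <- t(vapply(seq_along(ages), function(i)
      .draw_assemblage(fc[i], config, config$count_total),
      numeric(nrow(config$dict))))
    colnames(pm) <- config$dict$taxon
    site_id <- sprintf("S%02d", s)
    df <- data.frame(id = sprintf("%s_%03d", site_id, seq_along(ages)),
                     site = site_id, lon = sites$lon[s], lat = sites$lat[s],
                     elev = sites$elev[s], age = round(ages),
                     context = "lake", loc_error = NA_real_,
                     count_total = config$count_total, stringsAsFactors = FALSE)
    rows[[s]] <- cbind(df, pm)
    truths[[s]] <- data.frame(site = site_id, age = round(ages), true_cover = fc)
  }
  all <- do.call(rbind, rows)
  list(samples = as_pollen_samples(all, config$dict$taxon),
       truth = do.call(rbind, truths))
}

#' Generate a complete synthetic world
#'
#' Rasters, modern samples and fossil cores under one seed, with all ground
#' truths persisted. The returned `fc_true` function gives the true cover
#' at any location and age; `truth_series(slices)` gives the area-weighted
#' regional mean of the true field at each slice center.
#'
#' @param config a [world_config()].
#' @return an object of class `synthetic_world`.
#' @export
generate_world <- function(config = world_config()) {
  rasters <- generate_cover_raster(config)
  set.seed(config$seed + 1)
  modern <- generate_modern_samples(rasters, config)
  set.seed(config$seed + 2)
  cores <- generate_fossil_cores(rasters, config)
  r <- rasters$cover
  fc_true <- function(lon, lat, elev, age) {
    base <- raster_value(r, lon, lat)
    pmin(100, pmax(0, base * config$history(age)))
  }
  land <- r$values != r$nodata & r$values != r$water
  lat_cells <- matrix(rep(raster_lats(r), times = ncol(r$values)), nrow(r$values))
  w <- cos(lat_cells[land] * pi / 180)
  base_land <- r$values[land]
  truth_series <- function(ages) {
    vapply(ages, function(a) {
      v <- pmin(100, pmax(0, base_land * config$history(a)))
      sum(w * v) / sum(w)
    }, 0)
  }
  structure(list(config = config, cover = rasters$cover, height = rasters$height,
                 landclass = rasters$landclass, dem = rasters$dem,
                 modern = modern$samples, modern_truth = modern$truth,
                 cores = cores$samples, core_truth = cores$truth,
                 fc_true = fc_true, truth_series = truth_series),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world: %d x %d cells, %d modern samples, %d fossil sites\n",
              nrow(x$cover$values), ncol(x$cover$values),
              nrow(x$modern), length(unique(x$cores$site))))
  invisible(x)
}

#' Write a synthetic world to plain-text files
#'
#' Rasters as ESRI ASCII grids, sample/core tables as tab-delimited text,
#' and ground truths as sidecar tables.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("cover", "height", "landclass", "dem"))
    write_asc(world[[nm]], file.path(dir, paste0(nm, ".asc")))
  write_samples(world$modern, file.path(dir, "modern_samples.tsv"))
  write_samples(world$cores, file.path(dir, "fossil_cores.tsv"))
  utils::write.table(world$modern_truth, file.path(dir, "modern_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(world$core_truth, file.path(dir, "core_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
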