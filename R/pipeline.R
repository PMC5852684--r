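#' Run the full reconstruction pipeline on a synthetic world
#'
#' Convenience driver chaining every stage: Gaussian-kernel calibration of
#' the modern samples against the cover raster, quality control, PFT
#' scoring, MAT fit, leave-one-out and repeated two-fold cross-validation,
#' quantile-mapping bias correction, fossil reconstruction with timeslice
#' assignment, thin-plate-spline gridding, and regional area-average
#' series. Returns every intermediate product.
#'
#' @param world a [generate_world()] result.
#' @param k,T MAT parameters (see [mat()]).
#' @param theta PFT scoring threshold (percent).
#' @param twofold_iterations two-fold cross-validation iterations.
#' @param bias_iterations resampling iterations of the bias-correction fit.
#' @param map_slices slice centers to grid (default: all 49); `NULL` skips
#'   mapping.
#' @param interp an [interpolation_config()].
#' @param seed seed for the stochastic stages (splits, resampling).
#' @param verbose print progress.
#' @return list with components `entries`, `qc`, `model`, `loo`, `twofold`,
#'   `curve`, `fossil` (per-sample reconstruction table), `fields` (gridded
#'   cover per mapped slice), `series` (regional means of the gridded
#'   reconstruction), `truth_series` (same slices, ground truth).
#' @export
reconstruct_world <- function(world, k = 8, T = 0.3, theta = 0.5,
                              twofold_iterations = 99, bias_iterations = 99,
                              map_slices = timeslice_scheme()$center,
                              interp = interpolation_config(),
                              seed = 1, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  cfg <- world$config
  dict <- cfg$dict

  say("calibrating modern samples against the cover raster")
  entries <- calibrate_samples(world$modern, world$cover, world$height,
                               world$landclass)

  say("quality filtering")
  qc <- qc_modern(world$modern, entries, dict, dem = world$dem,
                  class_raster = world$landclass, height_raster = world$height)
  fossil_qc <- qc_fossil(world$cores)

  say("PFT scoring and MAT fit")
  pft_cal <- taxa_to_pft(taxon_matrix(qc$samples), dict, theta)
  model <- mat(pft_cal, qc$entries$cover, k = k, T = T, ids = qc$samples$id)

  loo <- loo_cv(model)
  tf <- twofold_cv(model, iterations = twofold_iterations, seed = seed)

  say("bias-correction curve")
  curve <- fit_curve(tf$pred, tf$obs,
                     resample_config(iterations = bias_iterations, seed = seed + 1))

  say("fossil reconstruction")
  pft_fos <- taxa_to_pft(taxon_matrix(fossil_qc), dict, theta)
  pred <- predict(model, pft_fos, ids = fossil_qc$id)
  pred <- apply_curve(curve, pred)
  fossil <- data.frame(id = fossil_qc$id, site = fossil_qc$site,
                       lon = fossil_qc$lon, lat = fossil_qc$lat,
                       elev = fossil_qc$elev, age = fossil_qc$age,
                       slice = assign_timeslices(fossil_qc$age),
                       fit = pred$fit, fit_cal = pred$fit_cal, se = pred$se,
                       n_used = pred$n_used, no_analog = pred$no_analog,
                       ap = ap_percentage(taxon_matrix(fossil_qc), dict),
                       stringsAsFactors = FALSE)

  fields <- series <- truth_series <- NULL
  if (!is.null(map_slices)) {
    say("gridding ", length(map_slices), " timeslices")
    fields <- lapply(map_slices, function(s)
      map_timeslice(fossil, s, world$dem, value_col = "fit_cal",
                    variable = "cover", config = interp))
    names(fields) <- as.character(map_slices)
    region <- domain_polygon(world)
    series <- regional_series(fields, region_set(domain = region))
    mapped <- !vapply(fields, is.null, TRUE)
    truth_series <- data.frame(slice = map_slices[mapped],
                               truth = world$truth_series(map_slices[mapped]))
  }
  list(entries = entries, qc = qc, model = model, loo = loo, twofold = tf,
       curve = curve, fossil = fossil, fields = fields, series = series,
       truth_series = truth_series)
}

#' Rectangle polygon covering a world's domain
#' @param world a [generate_world()] result.
#' @export
domain_polygon <- function(world) {
  lr <- world$config$lon_range
  la <- world$config$lat_range
  cbind(lon = c(lr[1], lr[2], lr[2], lr[1]) + c(-1, 1, 1, -1) * 0.01,
        lat = c(la[1], la[1], la[2], la[2]) + c(-1, -1, 1, 1) * 0.01)
}
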