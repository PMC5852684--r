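test_that("the default scheme has 49 tiling slices with a 185-yr terminal window", {
  sch <- timeslice_scheme()
  expect_equal(nrow(sch), 49)
  expect_equal(sch$center[1], 12000)
  expect_equal(sch$center[49], 0)
  # windows tile without overlap: each upper bound is the next lower bound
  expect_equal(sch$upper[-1], sch$lower[-49])
  expect_equal(sch$upper[49] - sch$lower[49], 185)
})

test_that("ages map to slices with boundaries going to the younger slice", {
  expect_equal(assign_timeslices(12000), 12000)
  expect_equal(assign_timeslices(11875), 11750)   # boundary -> younger
  expect_equal(assign_timeslices(11876), 12000)
  expect_equal(assign_timeslices(c(125, 126)), c(0, 250))
  expect_equal(assign_timeslices(-60), 0)         # AD 2010 admissible
  expect_true(is.na(assign_timeslices(-61)))
  expect_equal(assign_timeslices(12125), 12000)
  expect_true(is.na(assign_timeslices(12126)))
})

test_that("every in-range age gets exactly one slice (partition property)", {
  set.seed(71)
  ages <- runif(500, -60, 12125)
  sl <- assign_timeslices(ages)
  expect_false(anyNA(sl))
  sch <- timeslice_scheme()
  for (i in sample(500, 50)) {
    row <- sch[sch$center == sl[i], ]
    in_window <- if (row$center == 0) ages[i] >= row$lower & ages[i] <= row$upper
                 else ages[i] > row$lower & ages[i] <= row$upper
    expect_true(in_window)
  }
})

flat_results <- function(value = 55, n_sites = 8, slices = c(750, 1000, 1250),
                         seed = 72) {
  set.seed(seed)
  sites <- data.frame(site = sprintf("S%d", 1:n_sites),
                      lon = runif(n_sites, 6.5, 11.5),
                      lat = runif(n_sites, 45.5, 48.5),
                      elev = runif(n_sites, 100, 1500))
  do.call(rbind, lapply(slices, function(s) {
    out <- sites
    out$slice <- s
    out$age <- s
    out$fit <- value
    out$se <- 2
    out
  }))
}

small_dem <- function() {
  set.seed(73)
  v <- matrix(runif(20 * 30, 0, 1500), 20, 30)
  v[3:5, 4:6] <- -3333                      # a water patch
  fc_raster(v, 6, 45, 0.2)
}

test_that("constant site values interpolate to a constant unmasked field", {
  dem <- small_dem()
  f <- map_timeslice(flat_results(55), 1000, dem,
                     config = interpolation_config(mask_radius_km = 1000))
  expect_s3_class(f, "gridded_field")
  vals <- f$values[!is.na(f$values)]
  expect_equal(vals, rep(55, length(vals)), tolerance = 1e-6)
  # water cells masked
  expect_true(all(is.na(f$values[3:5, 4:6])))
})

test_that("removing a site masks its formerly covered neighborhood", {
  res <- flat_results(55)
  dem <- small_dem()
  cfg <- interpolation_config(mask_radius_km = 150, min_sites = 5)
  f_all <- map_timeslice(res, 1000, dem, config = cfg)
  # drop the westernmost site entirely
  drop_site <- res$site[which.min(res$lon)]
  f_less <- map_timeslice(res[res$site != drop_site, ], 1000, dem, config = cfg)
  newly_masked <- is.na(f_less$values) & !is.na(f_all$values)
  expect_gt(sum(newly_masked), 0)
  # masks are monotone in the radius
  f_wide <- map_timeslice(res, 1000, dem,
                          config = interpolation_config(mask_radius_km = 400,
                                                        min_sites = 5))
  expect_true(all(which(is.na(f_wide$values)) %in% which(is.na(f_all$values))))
})

test_that("a linear east-west gradient is recovered within 10%", {
  res <- flat_results(0, n_sites = 12)
  truth <- function(lon) 20 + 8 * (lon - 6)       # 20% at 6E rising eastward
  res$fit <- truth(res$lon)
  dem <- small_dem()
  f <- map_timeslice(res, 1000, dem,
                     config = interpolation_config(mask_radius_km = 1000))
  lons <- 6 + (seq_len(ncol(f$values)) - 0.5) * 0.2
  interior <- 5:25
  for (j in interior) {
    col_vals <- f$values[, j]
    got <- mean(col_vals, na.rm = TRUE)
    expect_lt(abs(got - truth(lons[j])) / truth(lons[j]), 0.10)
  }
  # gradient sign preserved
  prof <- colMeans(f$values[, interior], na.rm = TRUE)
  expect_true(all(diff(prof) > 0))
})

test_that("slices with too few sites are skipped with a report", {
  res <- flat_results(55, n_sites = 3)
  expect_message(f <- map_timeslice(res, 1000, small_dem()), "skipped")
  expect_null(f)
})

test_that("the error grid combines analog SE with a jackknife term", {
  dem <- small_dem()
  res <- flat_results(50, n_sites = 10)
  res$fit <- 30 + res$lon * 2 + rnorm(nrow(res), 0, 0.1)
  res$se <- 0                              # no analog-error contribution
  eg <- error_grid(res, 1000, dem,
                   config = interpolation_config(lambda = 1e-4))
  expect_s3_class(eg, "gridded_field")
  expect_true(all(eg$values >= 0, na.rm = TRUE))
  # with zero analog SEs the total is the jackknife term alone: small for a
  # near-planar field sampled by many sites
  expect_lt(median(eg$values, na.rm = TRUE), 5)
  # and the jackknife term matches a brute-force refit at one query cell
  pts <- unique(res[res$slice == 1000, c("site", "lon", "lat", "elev", "fit")])
  q <- matrix(c(9, 47, 500), 1)
  got <- tps_jackknife_se(as.matrix(pts[, c("lon", "lat", "elev")]), pts$fit,
                          q, lambda = 1e-4, scale = c(1, 1, 1 / 1000))
  n <- nrow(pts)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    o <- oracle_tps_fit(as.matrix(pts[-i, c("lon", "lat", "elev")]), pts$fit[-i],
                        lambda = 1e-4, scale = c(1, 1, 1 / 1000))
    preds[i] <- oracle_tps_predict(o, q)
  }
  expect_equal(got, sqrt((n - 1) / n * sum((preds - mean(preds))^2)),
               tolerance = 1e-6)
})

test_that("fewer than three sites yields no error grid", {
  res <- flat_results(50, n_sites = 2)
  expect_message(eg <- error_grid(res, 1000, small_dem()), "fewer than 3")
  expect_null(eg)
})
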