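test_that("extraction over a uniform raster returns the constant for all sigma", {
  r <- uniform_raster(37)
  for (s in c(100, 500, 10000))
    expect_equal(extract_cover(r, 10.045, 50.045, s), 37)
})

test_that("two equidistant pixels with values 0 and 100 average to 50", {
  v <- matrix(-9999, 1, 3)
  v[1, 1] <- 0; v[1, 3] <- 100
  r <- fc_raster(v, 10, 50, 0.01)
  # sample at the (nodata) center pixel: the two valid pixels are symmetric
  expect_equal(extract_cover(r, 10.015, 50.005, 500), 50)
})

test_that("extraction matches the brute-force double-loop oracle", {
  r <- toy_raster_3x3()
  lon <- 10.015; lat <- 50.015             # center-pixel center
  pitch <- gc_distance(10.015, 50.015, 10.025, 50.015)  # one pixel pitch
  got <- extract_cover(r, lon, lat, pitch)
  expect_equal(got, oracle_extract(r, lon, lat, pitch), tolerance = 1e-12)
  # and with water/no-data pixels excluded
  r$values[1, 1] <- r$water
  r$values[3, 3] <- r$nodata
  expect_equal(extract_cover(r, lon, lat, pitch),
               oracle_extract(r, lon, lat, pitch), tolerance = 1e-12)
})

test_that("weights over included pixels renormalize to one under water exclusion", {
  r <- toy_raster_3x3()
  r$values[2, 2] <- r$water
  lon <- 10.015; lat <- 50.015
  d <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3)
    d[i, j] <- gc_distance(lon, lat, 10 + (j - 0.5) * 0.01, 50 + (3 - i + 0.5) * 0.01)
  w <- exp(-d^2 / (2 * 500^2))
  keep <- r$values != r$water
  expect_equal(sum((w[keep] / sum(w[keep]))), 1)
  # the weighted mean equals the renormalized-weight combination
  expect_equal(extract_cover(r, lon, lat, 500),
               sum(w[keep] / sum(w[keep]) * r$values[keep]))
})

test_that("excluding water shifts weight share beyond the shoreline", {
  # lake at the center: weight share of the outer ring strictly increases
  r <- toy_raster_3x3(matrix(50, 3, 3))
  lon <- 10.015; lat <- 50.015
  share_outer <- function(rr) {
    d <- matrix(NA_real_, 3, 3)
    for (i in 1:3) for (j in 1:3)
      d[i, j] <- gc_distance(lon, lat, 10 + (j - 0.5) * 0.01, 50 + (3 - i + 0.5) * 0.01)
    w <- exp(-d^2 / (2 * 800^2))
    keep <- rr$values != rr$water
    outer_ring <- d > min(d)
    sum(w[keep & outer_ring]) / sum(w[keep])
  }
  before <- share_outer(r)
  r$values[2, 2] <- r$water
  expect_gt(share_outer(r), before)
})

test_that("extraction is invariant to a common translation of raster and sample", {
  r1 <- toy_raster_3x3()
  r2 <- r1; r2$xll <- r1$xll + 5
  expect_equal(extract_cover(r1, 10.012, 50.018, 700),
               extract_cover(r2, 15.012, 50.018, 700), tolerance = 1e-9)
})

test_that("shrinking sigma converges to the sample's own pixel value", {
  r <- toy_raster_3x3()
  expect_equal(extract_cover(r, 10.015, 50.015, 5), 50, tolerance = 1e-6)
  expect_equal(extract_cover(r, 10.005, 50.025, 5), 10, tolerance = 1e-6)
})

test_that("no valid pixels yields a flagged missing value", {
  r <- fc_raster(matrix(-9999, 3, 3), 10, 50, 0.01)
  got <- extract_cover(r, 10.015, 50.015, 500)
  expect_true(is.na(got))
  expect_equal(attr(got, "flag"), "no_valid_pixels")
})

test_that("sigma selection reproduces the context decision table", {
  # six cases on constructed rasters
  uniform55 <- uniform_raster(55)
  # moss -> sigma 500
  sel <- select_sigma(make_sample_row(context = "moss"), uniform55)
  expect_equal(sel$sigma, 500)
  expect_equal(sel$cover, 55)
  # dense forest, cover(500) = 55 > 40 and cover(100) higher -> sigma 100
  center_high <- uniform_raster(55, n = 21, cellsize = 0.002)
  center_high$values[11, 11] <- 100   # sample sits on a denser pixel
  sel <- select_sigma(make_sample_row(lon = 10.021, lat = 50.021,
                                      context = "dense_forest"), center_high)
  expect_equal(sel$sigma, 100)
  expect_gt(sel$cover, extract_cover(center_high, 10.021, 50.021, 500))
  # dense forest but cover(100) lower -> stay at 500
  center_low <- uniform_raster(55, n = 21, cellsize = 0.002)
  center_low$values[11, 11] <- 0
  sel <- select_sigma(make_sample_row(lon = 10.021, lat = 50.021,
                                      context = "dense_forest"), center_low)
  expect_equal(sel$sigma, 500)
  # dense forest below the 40% trigger -> 100 m never tried
  uniform30 <- uniform_raster(30)
  sel <- select_sigma(make_sample_row(context = "dense_forest"), uniform30)
  expect_equal(sel$sigma, 500)
  # large lake -> sigma 10 km
  sel <- select_sigma(make_sample_row(context = "lake", lake_area_ha = 150), uniform55)
  expect_equal(sel$sigma, 10000)
  # small lake surrounded by forest -> sigma 500
  sel <- select_sigma(make_sample_row(context = "lake", lake_area_ha = 8), uniform55)
  expect_equal(sel$sigma, 500)
  # small lake in open landscape -> sigma 10 km
  sel <- select_sigma(make_sample_row(context = "lake", lake_area_ha = 8), uniform30)
  expect_equal(sel$sigma, 10000)
})

test_that("unknown context defaults to 500 m with a warning", {
  expect_warning(sel <- select_sigma(make_sample_row(context = "weird"),
                                     uniform_raster(42)), "unknown")
  expect_equal(sel$sigma, 500)
})

test_that("tree-height screen drops only treeless-surround lake samples", {
  zero_h <- uniform_raster(0, n = 15, cellsize = 0.01)
  cls <- uniform_raster(1, n = 15, cellsize = 0.01)
  s <- make_sample_row(lon = 10.075, lat = 50.075)
  # lake sample (sigma 10 km) over zero heights -> drop
  expect_false(tree_height_screen(s, 10000, zero_h, cls))
  # nonzero median height -> keep
  some_h <- uniform_raster(4, n = 15, cellsize = 0.01)
  expect_true(tree_height_screen(s, 10000, some_h, cls))
  # moss sample (sigma 500) over zero heights -> keep, screen not applicable
  expect_true(tree_height_screen(s, 500, zero_h, cls))
  # outside land-class coverage -> keep
  far <- make_sample_row(lon = 40, lat = 70)
  expect_true(tree_height_screen(far, 10000, zero_h, cls))
  # absent height raster -> screen skipped
  expect_message(keep <- tree_height_screen(s, 10000, NULL, cls), "skipped")
  expect_true(keep)
})
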