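test_that("all generators are deterministic under a fixed seed", {
  cfg <- world_config(seed = 5, n_modern = 20, n_per_site = 10,
                      n_fossil_sites = 3)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$cover$values, w2$cover$values)
  expect_identical(w1$height$values, w2$height$values)
  expect_equal(as.data.frame(w1$modern), as.data.frame(w2$modern))
  expect_equal(as.data.frame(w1$cores), as.data.frame(w2$cores))
})

test_that("the cover field's correlation length matches the configuration", {
  cfg <- world_config(seed = 12, corr_len_m = 60000, shrub_patch = FALSE)
  r <- generate_cover_raster(cfg)$cover
  # empirical correlogram along rows: distance at which correlation drops
  # below 1/e, compared with the configured correlation length
  v <- r$values
  v[v == r$water] <- NA
  cell_m <- cfg$res_m
  maxlag <- floor(ncol(v) / 2)
  corr <- vapply(1:maxlag, function(l) {
    a <- as.vector(v[, 1:(ncol(v) - l)])
    b <- as.vector(v[, (1 + l):ncol(v)])
    ok <- !is.na(a) & !is.na(b)
    cor(a[ok], b[ok])
  }, 0)
  est_range <- cell_m * which(corr < exp(-1))[1]
  expect_lt(abs(est_range - cfg$corr_len_m) / cfg$corr_len_m, 0.25)
})

test_that("the constant-field option sets every land pixel to the value", {
  cfg <- world_config(seed = 2, constant_cover = 40, shrub_patch = FALSE)
  r <- generate_cover_raster(cfg)$cover
  expect_equal(unique(land_values(r)), 40)
})

test_that("non-positive resolution is a configuration error", {
  expect_error(world_config(res_m = 0), "resolution")
  expect_error(world_config(transport_frac = 1.2), "transport")
  d0 <- suppressWarnings(synthetic_pft_dictionary()[0, ])
  expect_error(world_config(dict = d0), "empty")
})

test_that("the noiseless forward model is deterministic in true cover", {
  cfg <- world_config(transport_frac = 0, noiseless = TRUE)
  a <- expected_assemblage(60, cfg)
  b <- expected_assemblage(60, cfg)
  expect_identical(a, b)
  expect_equal(sum(a), 1)
  # zero cover with zero transport -> no arboreal pollen at all
  p0 <- 100 * expected_assemblage(0, cfg)
  expect_equal(ap_percentage(p0, cfg$dict), 0)
})

test_that("expected arboreal share rises strictly with true cover", {
  for (lam in c(0, 0.3, 0.8)) {
    cfg <- world_config(transport_frac = lam)
    ap <- vapply(seq(0, 100, 10), function(fc)
      ap_percentage(100 * expected_assemblage(fc, cfg), cfg$dict), 0)
    expect_true(all(diff(ap) > 0), label = sprintf("lambda = %g", lam))
  }
  # at full transport the local signal vanishes
  cfg1 <- world_config(transport_frac = 1)
  expect_equal(expected_assemblage(0, cfg1), expected_assemblage(100, cfg1))
})

test_that("defect injection labels the requested fraction of samples", {
  cfg <- world_config(seed = 8, n_modern = 100, defect_frac = 0.3)
  rasters <- generate_cover_raster(cfg)
  set.seed(cfg$seed + 1)
  gen <- generate_modern_samples(rasters, cfg)
  expect_equal(sum(gen$truth$defect != "none"), 30)
  # injected location errors exceed 100 m; elevation mismatches exceed 200 m
  le <- gen$truth$defect == "loc_error"
  expect_true(all(gen$samples$loc_error[le] > 100))
  em <- gen$truth$defect == "elev_mismatch"
  if (any(em)) {
    dem_at <- vapply(which(em), function(i)
      raster_value(rasters$dem, gen$samples$lon[i], gen$samples$lat[i]), 0)
    expect_true(all(abs(gen$samples$elev[em] - dem_at) > 200))
  }
})

test_that("fossil cores from a constant history share one expected assemblage", {
  cfg <- world_config(seed = 9, n_fossil_sites = 2, n_per_site = 30,
                      constant_cover = 70, history = function(age) rep(1, length(age)),
                      noiseless = TRUE, shrub_patch = FALSE)
  rasters <- generate_cover_raster(cfg)
  set.seed(cfg$seed + 2)
  gen <- generate_fossil_cores(rasters, cfg)
  pm <- taxon_matrix(gen$samples)
  expect_equal(max(apply(pm, 2, function(col) diff(range(col)))), 0)
  expect_equal(unique(gen$truth$true_cover), 70)
})

test_that("a step history raises arboreal pollen across the step", {
  step_hist <- function(age) ifelse(age >= 8000, 0.25, 1)   # 20% -> 80% cover
  cfg <- world_config(seed = 10, n_fossil_sites = 4, n_per_site = 60,
                      constant_cover = 80, history = step_hist,
                      shrub_patch = FALSE)
  rasters <- generate_cover_raster(cfg)
  set.seed(cfg$seed + 2)
  gen <- generate_fossil_cores(rasters, cfg)
  ap <- ap_percentage(taxon_matrix(gen$samples), cfg$dict)
  old <- gen$samples$age >= 8000
  expect_gt(mean(ap[!old]), mean(ap[old]))
  expect_equal(sort(unique(gen$truth$true_cover)), c(20, 80))
})

test_that("an age span outside the history domain is a configuration error", {
  bad_hist <- function(age) ifelse(age > 10000, NA_real_, 1)
  expect_error(world_config(history = bad_hist, age_range = c(0, 12000)),
               "history")
})

test_that("ground truth is persisted for every generated sample", {
  w <- shared_world()
  expect_equal(nrow(w$modern_truth), nrow(w$modern))
  expect_setequal(w$modern_truth$id, w$modern$id)
  expect_equal(nrow(w$core_truth), nrow(w$cores))
  # and written worlds round trip through plain text
  dir <- withr::local_tempdir()
  write_world(w, dir)
  r2 <- read_asc(file.path(dir, "cover.asc"))
  expect_equal(r2$values, w$cover$values)
  s2 <- read_samples(file.path(dir, "modern_samples.tsv"))
  expect_equal(nrow(s2), nrow(w$modern))
  truth2 <- read.delim(file.path(dir, "modern_truth.tsv"))
  expect_equal(truth2$true_cover, w$modern_truth$true_cover)
})

test_that("the default history peaks inside the mid-Holocene forest maximum", {
  ages <- seq(0, 12000, 25)
  h <- default_history(ages)
  peak <- ages[which.max(h)]
  expect_gte(peak, 6000)
  expect_lte(peak, 8500)
  expect_lt(h[ages == 12000], h[ages == 0])   # late-glacial below present
})
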