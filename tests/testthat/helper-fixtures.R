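# Shared fixtures, built in code. The small world is generated once per
# test run and reused (read-only) across files.

uniform_raster <- function(value = 37, n = 9, cellsize = 0.01,
                           xll = 10, yll = 50) {
  fc_raster(matrix(value, n, n), xll, yll, cellsize)
}

# 3x3 toy raster with distinct values, sample at the center pixel
toy_raster_3x3 <- function(values = matrix(c(10, 20, 30,
                                             40, 50, 60,
                                             70, 80, 90), 3, byrow = TRUE),
                           cellsize = 0.01) {
  fc_raster(values, 10, 50, cellsize)
}

# tiny calibration set: m assemblages over 3 PFTs with known covers
tiny_calibration <- function(m = 10, seed = 42) {
  set.seed(seed)
  x <- matrix(rgamma(m * 3, 2), m, 3)
  x <- x / rowSums(x)
  colnames(x) <- c("pft_a", "pft_b", "pft_c")
  rownames(x) <- sprintf("cal%02d", seq_len(m))
  list(x = x, y = round(runif(m, 0, 100), 1))
}

shared_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_world(world_config(seed = 7, defect_frac = 0.1))
    cache
  }
})

make_sample_row <- function(id = "s1", lon = 10.045, lat = 50.045, elev = 500,
                            age = 0, context = "moss", loc_error = 10,
                            lake_area_ha = NA_real_) {
  data.frame(id = id, lon = lon, lat = lat, elev = elev, age = age,
             context = context, loc_error = loc_error,
             lake_area_ha = lake_area_ha, stringsAsFactors = FALSE)
}
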