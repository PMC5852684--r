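# QC fixture landscape and 12-sample rule-violation set, shared between
# the module tests and the acceptance suite.

# Constructed QC landscape: a forested west block (cover 55, height 10,
# forest class) and an open east block (cover 5, height 0, open class),
# uniform DEM at 500 m.
qc_landscape <- function() {
  n <- 21
  cover <- matrix(55, n, n); cover[, 13:21] <- 5
  height <- matrix(10, n, n); height[, 13:21] <- 0
  cls <- matrix(2, n, n); cls[, 13:21] <- 1
  dem <- matrix(500, n, n)
  list(cover = fc_raster(cover, 10, 50, 0.01),
       height = fc_raster(height, 10, 50, 0.01),
       cls = fc_raster(cls, 10, 50, 0.01),
       dem = fc_raster(dem, 10, 50, 0.01))
}

# 12 samples: one violation per rule plus passing samples; the designed
# survivor set is s01, s10, s11, s12.
qc_fixture <- function() {
  forest <- c(10.05, 50.10)   # deep inside the forested block
  open <- c(10.18, 50.10)     # deep inside the open block
  row <- function(id, lon, lat, context = "moss", elev = 500, loc_error = 10,
                  count = 300, pinus = 60) {
    data.frame(id = id, lon = lon, lat = lat, elev = elev, age = 0,
               context = context, loc_error = loc_error,
               lake_area_ha = if (context == "lake") 150 else NA_real_,
               count_total = count, Pinus = pinus, Poaceae = 100 - pinus,
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    row("s01", forest[1], forest[2]),                                  # pass
    row("s02", forest[1], forest[2]),                                  # duplicate of s01
    row("s03", forest[1] + 0.01, forest[2], loc_error = 150),          # location error
    row("s04", forest[1] + 0.02, forest[2], elev = 800),               # DEM says 500
    row("s05", forest[1] + 0.03, forest[2], context = "riverine"),
    row("s06", forest[1] + 0.04, forest[2], count = 80),               # low count
    row("s07", forest[1] + 0.05, forest[2], context = "treeless"),     # open ctx in forest
    row("s08", open[1], open[2], context = "dense_forest"),            # forest ctx in open
    row("s09", open[1], open[2] + 0.01, pinus = 85),                   # AP 85, cover ~5
    row("s10", open[1], open[2] + 0.02, context = "treeless", pinus = 85),  # exempt
    row("s11", forest[1], forest[2] + 0.02, context = "lake"),         # pass (large lake)
    row("s12", forest[1], forest[2] + 0.03))                           # pass
  as_pollen_samples(df, c("Pinus", "Poaceae"))
}

run_qc <- function(samples, land = qc_landscape()) {
  entries <- calibrate_samples(samples, land$cover, land$height, land$cls)
  qc_modern(samples, entries, synthetic_pft_dictionary(), dem = land$dem,
            class_raster = land$cls, height_raster = land$height)
}
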