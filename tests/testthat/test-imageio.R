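test_that("multichannel images validate their channels", {
  ch <- matrix(1, 8, 8)
  img <- multichannel_image(list(poi = ch, post_marker = ch * 2))
  expect_s3_class(img, "multichannel_image")
  expect_error(multichannel_image(list(foo = ch)), "unknown channel role")
  expect_error(multichannel_image(list(poi = ch, actin = matrix(1, 4, 4))),
               "identical dimensions")
  expect_error(multichannel_image(list(poi = -ch)), "negative")
  expect_error(multichannel_image(list(poi = ch), pixel_size_nm = 0),
               "positive scalar")
})

test_that("TIFF + sidecar round-trips all four roles at stored precision", {
  set.seed(81)
  ch <- function(scale) matrix(sample(0:4095, 64, replace = TRUE) * scale,
                               8, 8)
  img <- multichannel_image(list(poi = ch(1), post_marker = ch(10),
                                 pre_marker = ch(0.5), actin = ch(2)),
                            pixel_size_nm = 30, experiment_id = "expA",
                            field_id = "fld7")
  f <- tempfile(fileext = ".tif")
  write_multichannel_tiff(img, f)
  back <- read_multichannel_tiff(f)
  expect_equal(names(back$channels), names(img$channels))
  for (r in names(img$channels))
    expect_equal(back$channels[[r]], img$channels[[r]], tolerance = 1e-6)
  expect_equal(back$pixel_size_nm, 30)
  expect_equal(back$experiment_id, "expA")
  expect_equal(back$field_id, "fld7")
})

test_that("plane-count mismatches and missing metadata are handled", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.2, 8, 8),
                       matrix(0.3, 8, 8)), f, bits.per.sample = 32L)
  expect_error(read_multichannel_tiff(f, channel_map = c(poi = 1,
                                                         post_marker = 2,
                                                         pre_marker = 3,
                                                         actin = 4)),
               "format error")
  expect_warning(img <- read_multichannel_tiff(f, channel_map = c(poi = 1,
                                                                  post_marker = 2,
                                                                  pre_marker = 3)),
                 "pixel size")
  expect_equal(length(img$channels), 3L)
  expect_error(read_multichannel_tiff("/nonexistent.tif"), "not found")
})

test_that("config defaults match the published analysis settings", {
  f <- tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg <- load_config(f)
  expect_equal(cfg$crop_side_um, 3.0)
  expect_equal(cfg$n_bins, 5L)
  expect_equal(cfg$centre_radius_px, 10L)
  expect_equal(cfg$ring_range_px, c(35L, 45L))
  expect_equal(cfg$outlier_k, 3)
  expect_equal(cfg$wavelet_scale, 2L)
  expect_equal(cfg$wavelet_threshold_pct, 80)
})

test_that("invalid configurations fail on load with named fields", {
  expect_error(pipeline_config(ring_range_px = c(45, 35)), "increasing")
  expect_error(pipeline_config(centre_radius_px = 40), "centre window")
  # 45 px ring at 30 nm/px needs a crop radius of at least 1.35 um
  expect_error(pipeline_config(crop_side_um = 2.0), "smaller than the outer ring")
  f <- tempfile(fileext = ".yaml")
  writeLines("ring_range_px: [45, 35]", f)
  expect_error(load_config(f), "increasing")
})

test_that("result files echo the full configuration deterministically", {
  cfg <- pipeline_config(seed = 9L)
  res <- list(per_synapse = data.frame(crop_id = sprintf("c%02d", 1:10),
                                       marker_mean = 1:10),
              config = cfg)
  p1 <- file.path(tempdir(), "wrA"); p2 <- file.path(tempdir(), "wrB")
  f1 <- write_results(res, p1)
  f2 <- write_results(res, p2)
  tab <- read.csv(paste0(p1, "_synapses.csv"))
  expect_equal(nrow(tab), 10)
  # identical inputs give byte-identical CSV bodies
  expect_identical(readLines(paste0(p1, "_synapses.csv")),
                   readLines(paste0(p2, "_synapses.csv")))
  man <- jsonlite::read_json(paste0(p1, "_manifest.json"),
                             simplifyVector = TRUE)
  expect_true(all(setdiff(names(unclass(cfg)), "synapse_threshold") %in%
                    names(man$config)))
  expect_equal(man$seed, 9L)
  # empty tables still produce header-only files plus a manifest
  fe <- write_results(list(config = cfg), file.path(tempdir(), "wrE"))
  expect_true(all(file.exists(fe)))
  expect_equal(nrow(read.csv(grep("synapses", fe, value = TRUE))), 0)
})
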