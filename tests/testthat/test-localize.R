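test_that("crop side converts micrometres to an odd pixel count", {
  expect_equal(crop_side_px(3.0, 30), 101L)     # 100 px rounded up to odd
  expect_equal(crop_side_px(3.03, 30), 101L)
  expect_equal(crop_side_px(1.5, 30), 51L)
  expect_equal(crop_side_px(3.0, 40), 75L)
})

test_that("thresholding records the applied value and matches a sort oracle", {
  img <- matrix(c(5, 5, 5, 5), 2, 2)
  m <- threshold_marker(img, list(type = "absolute", value = 10))
  expect_false(any(m))
  m <- threshold_marker(img, list(type = "absolute", value = 0))
  expect_true(all(m))
  set.seed(31)
  img <- matrix(sample(1:100), 10, 10)          # distinct values
  m <- threshold_marker(img, list(type = "quantile", value = 0.5))
  expect_equal(sort(img[m]), sort(img)[51:100]) # exactly the upper half
  expect_equal(attr(m, "threshold"), median(img))
  expect_error(threshold_marker(img, list(type = "quantile", value = 1.5)),
               "quantile")
})

test_that("punctum centres are intensity-weighted centroids of 8-connected blobs", {
  ch <- matrix(0, 30, 30)
  ch[10:12, 10:12] <- 4                         # uniform 3x3 square
  centres <- find_synapse_centres(ch > 0, ch, min_area_px = 4)
  expect_equal(nrow(centres), 1L)
  expect_equal(c(centres$row, centres$col), c(11L, 11L))
  expect_equal(centres$area_px, 9L)
  # two-lobe component joined by a bridge: single centre at the symmetry point
  ch2 <- matrix(0, 30, 30)
  ch2[10, 5:9] <- 3; ch2[10, 13:17] <- 3; ch2[10, 10:12] <- 1
  centres2 <- find_synapse_centres(ch2 > 0, ch2, min_area_px = 4)
  expect_equal(nrow(centres2), 1L)
  expect_equal(centres2$col, 11L)
  # diagonal touching counts as one component (8-connectivity)
  ch3 <- matrix(0, 10, 10)
  ch3[2, 2] <- 1; ch3[3, 3] <- 1; ch3[4, 4] <- 1; ch3[5, 5] <- 1
  expect_equal(nrow(find_synapse_centres(ch3 > 0, ch3, min_area_px = 4)), 1L)
  # components below min_area vanish; empty mask gives empty table
  ch4 <- matrix(0, 10, 10); ch4[2, 2] <- 1; ch4[8, 8] <- 1
  expect_equal(nrow(find_synapse_centres(ch4 > 0, ch4, min_area_px = 4)), 0L)
  expect_equal(nrow(find_synapse_centres(matrix(FALSE, 5, 5),
                                         matrix(0, 5, 5))), 0L)
})

test_that("puncta are returned brightest-first", {
  ch <- matrix(0, 40, 40)
  ch[5:7, 5:7] <- 1; ch[20:22, 20:22] <- 10
  centres <- find_synapse_centres(ch > 0, ch, min_area_px = 4)
  expect_equal(centres$row, c(21L, 6L))
})

test_that("crops are centred, flagged at borders, and carry recomputable means", {
  cfg <- pipeline_config(crop_side_um = 0.9, pixel_size_nm = 30,
                         centre_radius_px = 4, ring_range_px = c(10, 14))  # 31 px
  ch <- matrix(2, 80, 80); ch[40, 40] <- 9
  img <- multichannel_image(list(post_marker = ch, poi = ch * 0.5),
                            pixel_size_nm = 30)
  cr <- extract_crop(img, c(40, 40), cfg)
  expect_true(cr$valid)
  expect_equal(cr$side_px, 31L)
  expect_equal(cr$arrays$post_marker[16, 16], 9)   # punctum at central pixel
  expect_equal(cr$mean_intensity[["poi"]], mean(cr$arrays$poi))
  border <- extract_crop(img, c(1, 1), cfg)
  expect_false(border$valid)
  expect_null(border$arrays)
  expect_error(extract_crop(img, c(200, 5), cfg), "outside")
  # constant image: mean equals the constant in every role
  flat <- multichannel_image(list(poi = matrix(3, 80, 80)), pixel_size_nm = 30)
  expect_equal(extract_crop(flat, c(40, 40), cfg)$mean_intensity[["poi"]], 3)
})

test_that("localization is translation-equivariant away from borders", {
  set.seed(32)
  base <- matrix(0, 90, 90)
  base[30:32, 40:42] <- matrix(runif(9, 5, 9), 3, 3)
  shifted <- matrix(0, 90, 90)
  shifted[35:37, 47:49] <- base[30:32, 40:42]
  c1 <- find_synapse_centres(base > 1, base, 4)
  c2 <- find_synapse_centres(shifted > 1, shifted, 4)
  expect_equal(c2$row - c1$row, 5L)
  expect_equal(c2$col - c1$col, 7L)
  cfg <- pipeline_config(crop_side_um = 0.9, pixel_size_nm = 30,
                         centre_radius_px = 4, ring_range_px = c(10, 14))
  i1 <- multichannel_image(list(poi = base), pixel_size_nm = 30)
  i2 <- multichannel_image(list(poi = shifted), pixel_size_nm = 30)
  cr1 <- extract_crop(i1, c(c1$row, c1$col), cfg)
  cr2 <- extract_crop(i2, c(c2$row, c2$col), cfg)
  expect_equal(cr1$arrays$poi, cr2$arrays$poi)
})
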