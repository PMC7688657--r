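canonical_landmarks <- function(id = "s", class = "mushroom",
                                centre = c(51, 51), rh = 10, neck = 9) {
  args <- list(crop_id = id, spine_class = class,
               head_top = centre + c(-rh, 0), head_bottom = centre + c(rh, 0),
               head_left = centre + c(0, -rh), head_right = centre + c(0, rh),
               shaft_junction = centre + c(rh + neck + 2, 0))
  if (class == "mushroom") {
    args$neck_top <- centre + c(rh, 0)
    args$neck_bottom <- centre + c(rh + neck, 0)
  }
  do.call(spine_landmarks, args)
}

test_that("head centre is the centroid of the four border points", {
  lm <- canonical_landmarks(centre = c(40, 60))
  expect_equal(head_centre(lm), c(40, 60))
  pt <- spine_landmarks("p", "stubby", head_top = c(7, 9), head_bottom = c(7, 9),
                        head_left = c(7, 9), head_right = c(7, 9),
                        shaft_junction = c(20, 9))
  expect_equal(head_centre(pt), c(7, 9))
  expect_error(spine_landmarks("m", "mushroom", head_top = c(1, 1),
                               head_bottom = c(2, 2), head_left = c(1, 2),
                               head_right = c(2, 1), shaft_junction = c(5, 5)),
               "neck_top")
})

test_that("aligning an already-aligned spine is the identity", {
  set.seed(61)
  img <- matrix(runif(101 * 101), 101, 101)
  out <- align_spine_crop(img, canonical_landmarks())
  expect_lt(max(abs(out - img), na.rm = TRUE), 1e-6)
})

test_that("rotated spines align back to their reference", {
  base <- matrix(0, 101, 101)
  base[42:60, 47:55] <- 5; base[61:85, 49:53] <- 2   # head blob + shaft
  lmA <- canonical_landmarks(class = "stubby")
  ref <- align_spine_crop(base, lmA)
  # same content rotated by 90 degrees, landmarks rotated with it
  rot90 <- matrix(0, 101, 101)
  for (r in 1:101) rot90[, 102 - r] <- base[r, ]
  lmB <- spine_landmarks("b", "stubby",
                         head_top = c(51, 61), head_bottom = c(51, 41),
                         head_left = c(41, 51), head_right = c(61, 51),
                         shaft_junction = c(51, 102 - 72))
  out <- align_spine_crop(rot90, lmB)
  ok <- !is.na(ref) & !is.na(out)
  expect_lt(max(abs(out[ok] - ref[ok])), 0.02 * max(base))
  # shaft directly above the head: a 180-degree flip is applied
  flip <- base[101:1, ]
  lmC <- spine_landmarks("c", "stubby",
                         head_top = c(61, 51), head_bottom = c(41, 51),
                         head_left = c(51, 41), head_right = c(51, 61),
                         shaft_junction = c(30, 51))
  out2 <- align_spine_crop(flip, lmC)
  ok2 <- !is.na(out2) & !is.na(ref)
  expect_lt(max(abs(out2[ok2] - ref[ok2])), 0.02 * max(base))
  # degenerate orientation errors
  bad <- canonical_landmarks()
  bad$shaft_junction <- head_centre(bad)
  expect_error(align_spine_crop(base, bad), "undefined orientation")
})

test_that("rigid alignment approximately preserves interior intensity", {
  set.seed(62)
  img <- matrix(0, 101, 101)
  img[35:65, 35:65] <- runif(31 * 31, 1, 3)
  lm45 <- spine_landmarks("d", "stubby",
                          head_top = c(51, 51) - c(7, 7), head_bottom = c(58, 58),
                          head_left = c(58, 44), head_right = c(44, 58),
                          shaft_junction = c(65, 65))
  out <- align_spine_crop(img, lm45)
  expect_lt(abs(sum(out, na.rm = TRUE) / sum(img) - 1), 0.01)
})

test_that("missing-aware averaging uses per-pixel counts, never zero-fill", {
  a <- matrix(1, 5, 5); a[1, 1] <- NA
  b <- matrix(3, 5, 5); b[5, 5] <- NA
  avg <- average_aligned(list(a, b))
  expect_equal(avg$data[3, 3], 2)
  expect_equal(avg$data[1, 1], 3)               # only b contributes
  expect_equal(avg$data[5, 5], 1)               # only a contributes
  expect_equal(avg$counts[1, 1], 1L)
  expect_equal(avg$counts[3, 3], 2L)
  one <- average_aligned(list(a))
  expect_equal(one$data, a)
  expect_error(average_aligned(list()), "empty")
})

test_that("synthetic mushroom spines place POI mass on the dendritic side", {
  synth <- synth_config(n_synapses = 150, seed = 63,
                        spine_fracs = c(mushroom = 0.6, stubby = 0.2,
                                        none = 0.2))
  truth <- sample_synapse_population(synth)
  idx <- which(truth$spine_class == "mushroom")
  expect_gt(length(idx), 20)
  crops <- stedsynapse:::render_truth_crops(truth, synth)
  aligned <- lapply(idx, function(i)
    align_spine_crop(crops[[i]]$arrays$poi, crop_spine_landmarks(truth, i)))
  avg <- average_aligned(aligned, spine_class = "mushroom")
  cr <- (nrow(avg$data) + 1) / 2
  below <- sum(avg$data[(cr + 1):nrow(avg$data), ], na.rm = TRUE)
  above <- sum(avg$data[1:(cr - 1), ], na.rm = TRUE)
  expect_gt(below, above)
})

test_that("landmark CSV round-trips through read_landmarks", {
  df <- data.frame(crop_id = c("a", "b"), spine_class = c("mushroom", "stubby"),
                   head_top_x = c(51, 50), head_top_y = c(41, 40),
                   head_bottom_x = c(51, 50), head_bottom_y = c(61, 60),
                   head_left_x = c(41, 40), head_left_y = c(51, 50),
                   head_right_x = c(61, 60), head_right_y = c(51, 50),
                   neck_top_x = c(51, NA), neck_top_y = c(61, NA),
                   neck_bottom_x = c(51, NA), neck_bottom_y = c(70, NA),
                   shaft_junction_x = c(51, 50), shaft_junction_y = c(72, 71))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  lms <- read_landmarks(f)
  expect_length(lms, 2)
  expect_equal(lms[[1]]$spine_class, "mushroom")
  expect_equal(lms[[1]]$head_top, c(41, 51))     # (row, col) from (y, x)
  expect_null(lms[[2]]$neck_top)
  expect_equal(head_centre(lms[[2]]), c(50, 50))
})
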