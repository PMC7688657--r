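# B3-spline scaling kernel of the a-trous scheme
B3_KERNEL <- c(1, 4, 6, 4, 1) / 16

# reflect an index vector into 1..n (whole-sample mirror, edge not repeated)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  i <- ((i - 1L) %% p + p) %% p
  ifelse(i >= n, p - i, i) + 1L
}

# separable B3 smoothing with holes of spacing h, mirror boundary
b3_smooth <- function(image, h) {
  nr <- nrow(image); nc <- ncol(image)
  offs <- c(-2L, -1L, 0L, 1L, 2L) * h
  out <- matrix(0, nr, nc)
  for (t in 1:5)  # rows
    out <- out + B3_KERNEL[t] * image[reflect_index(seq_len(nr) + offs[t], nr), , drop = FALSE]
  res <- matrix(0, nr, nc)
  for (t in 1:5)  # columns
    res <- res + B3_KERNEL[t] * out[, reflect_index(seq_len(nc) + offs[t], nc), drop = FALSE]
  res
}

#' A-trous (undecimated) B3-spline wavelet decomposition
#'
#' Decomposes an image into `n_scales` detail planes `W1..Wn` and a smooth
#' residual by iterated separable smoothing with the B3-spline kernel
#' (1,4,6,4,1)/16, inserting `2^(j-1) - 1` holes between taps at scale `j`
#' (mirror boundary). The scheme is exactly additive:
#' `image = W1 + ... + Wn + residual`. Detail plane `Wj` isolates
#' structures of characteristic size around `2^j` px, which is what makes
#' the scale-2 plane a matched filter for diffraction-sized fluorescent
#' spots.
#'
#' @param image numeric matrix.
#' @param n_scales number of detail scales (>= 1).
#' @return list with `details` (list of matrices `W1..Wn`) and `residual`.
#' @export
atrous_decompose <- function(image, n_scales = 2L) {
  stopifnot(is.matrix(image), is.numeric(image), n_scales >= 1L)
  support <- 4L * 2L^(n_scales - 1L) + 1L
  if (min(dim(image)) < support)
    stop("image of size ", nrow(image), "x", ncol(image),
         " is too small for ", n_scales, " scales (kernel support ",
         support, " px)")
  details <- vector("list", n_scales)
  current <- image
  for (j in seq_len(n_scales)) {
    smoothed <- b3_smooth(current, 2L^(j - 1L))
    details[[j]] <- current - smoothed
    current <- smoothed
  }
  names(details) <- paste0("W", seq_len(n_scales))
  list(details = details, residual = current)
}

#' Detect fluorescent spots in a crop by wavelet thresholding
#'
#' The scale-`wavelet_scale` detail plane (default 2) is hard-thresholded at
#' `t = k * MAD(W) / 0.6745`, where the sensitivity `s =
#' wavelet_threshold_pct` maps to `k = (100 - s)/10 + 1` (so the default
#' s = 80 gives k = 3; s = 100 is most permissive, s near 0 strictest).
#' Connected components (8-connectivity) of supra-threshold pixels with
#' area >= `min_spot_area_px` become spots; centroids are intensity-weighted
#' on the original crop. The sensitivity mapping is an explicit, monotone
#' convention of this package.
#'
#' @param crop a [extract_crop()] object or a plain numeric matrix.
#' @param config a [pipeline_config()].
#' @param role channel role when `crop` is a `synapse_crop` (default "poi").
#' @return object of class `spot_set`: data frame `spots` (`row`, `col`
#'   sub-pixel centroid, `area_px`, `total_intensity`, `diameter_nm`),
#'   `threshold`, `scale`, `n_spots`.
#' @export
detect_spots <- function(crop, config = pipeline_config(), role = "poi") {
  if (inherits(crop, "synapse_crop")) {
    if (!isTRUE(crop$valid)) stop("cannot detect spots in an invalid crop")
    img <- crop$arrays[[role]]
  } else img <- crop
  stopifnot(is.matrix(img))
  dec <- atrous_decompose(img, config$wavelet_scale)
  W <- dec$details[[config$wavelet_scale]]
  k <- (100 - config$wavelet_threshold_pct) / 10 + 1
  thr <- k * mad(W)               # stats::mad already scales MAD by 1/0.6745
  mask <- W > thr
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      area_px = integer(0), total_intensity = numeric(0),
                      diameter_nm = numeric(0))
  if (!any(mask)) {
    return(structure(list(spots = empty, threshold = thr,
                          scale = config$wavelet_scale, n_spots = 0L),
                     class = "spot_set"))
  }
  lab <- label_components8(mask)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  area <- tabulate(comp)
  w <- pmax(img[idx], 0)
  tot <- rowsum(w, comp)[, 1]
  totz <- ifelse(tot > 0, tot, tabulate(comp))
  wz <- ifelse(tot[comp] > 0, w, 1)
  crow <- rowsum(wz * row(lab)[idx], comp)[, 1] / totz
  ccol <- rowsum(wz * col(lab)[idx], comp)[, 1] / totz
  keep <- which(area >= config$min_spot_area_px)
  spots <- if (length(keep)) {
    ddnm <- 2 * sqrt(area[keep] * config$pixel_size_nm^2 / pi)
    df <- data.frame(row = crow[keep], col = ccol[keep],
                     area_px = as.integer(area[keep]),
                     total_intensity = as.numeric(rowsum(img[idx], comp)[, 1][keep]),
                     diameter_nm = ddnm)
    df[order(-df$total_intensity), , drop = FALSE]
  } else empty
  structure(list(spots = spots, threshold = thr,
                 scale = config$wavelet_scale, n_spots = nrow(spots)),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot_set: %d spot(s), scale %d, threshold %.4g\n",
              x$n_spots, x$scale, x$threshold))
  invisible(x)
}

#' Summarize spot counts and sizes per group
#'
#' Groups spot sets (e.g. by intensity bin or spine class) and reports the
#' mean and SEM of the per-crop spot count and of the individual spot area.
#' SEM is reported as `NA` for groups with a single observation.
#'
#' @param spot_sets list of [detect_spots()] results.
#' @param groups vector parallel to `spot_sets` assigning each set to a
#'   group.
#' @return data frame: `group`, `n_crops`, `count_mean`, `count_sem`,
#'   `n_spots`, `area_mean`, `area_sem`.
#' @export
spot_stats <- function(spot_sets, groups = rep(1L, length(spot_sets))) {
  if (length(spot_sets) == 0L) stop("empty spot set list")
  stopifnot(length(groups) == length(spot_sets))
  groups <- as.character(groups)
  counts <- vapply(spot_sets, function(s) s$n_spots, integer(1))
  sem <- function(v) if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v))
  out <- lapply(unique(groups), function(g) {
    sel <- groups == g
    areas <- unlist(lapply(spot_sets[sel], function(s) s$spots$area_px))
    data.frame(group = g,
               n_crops = sum(sel),
               count_mean = mean(counts[sel]),
               count_sem = sem(counts[sel]),
               n_spots = length(areas),
               area_mean = if (length(areas)) mean(areas) else NA_real_,
               area_sem = sem(areas))
  })
  do.call(rbind, out)
}
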