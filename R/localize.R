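#' Crop side length in pixels
#'
#' Converts the requested physical crop side to pixels and adjusts the
#' result upward to the next odd integer, so that the punctum sits on an
#' exact central pixel (required for the radial analysis). At the default
#' 30 nm pixel size, a 3.0 um request gives 101 px.
#'
#' @param crop_side_um crop side in micrometres.
#' @param pixel_size_nm pixel pitch in nm.
#' @return odd integer side length in pixels.
#' @export
crop_side_px <- function(crop_side_um, pixel_size_nm) {
  n <- round(crop_side_um * 1000 / pixel_size_nm)
  n <- as.integer(n)
  if (n < 1L) stop("crop side rounds to less than one pixel")
  if (n %% 2L == 0L) n <- n + 1L
  n
}

#' Threshold a marker channel
#'
#' Replaces the manual thresholding of the synapse-marker channel by an
#' explicit rule: either an absolute intensity or an intensity quantile of
#' the channel. The threshold actually applied is recorded on the returned
#' mask so it can be logged in the run manifest.
#'
#' @param channel numeric matrix.
#' @param threshold_spec list with `type` ("absolute" or "quantile") and
#'   `value` (absolute intensity, or quantile in (0,1)).
#' @return logical matrix, `TRUE` where intensity strictly exceeds the
#'   threshold, with attribute `threshold` (the value applied).
#' @export
threshold_marker <- function(channel, threshold_spec) {
  stopifnot(is.matrix(channel))
  type <- threshold_spec$type %||% "absolute"
  val <- threshold_spec$value
  thr <- switch(type,
    absolute = val,
    quantile = {
      if (!(val > 0 && val < 1))
        stop("invalid config: quantile threshold must lie in (0, 1)")
      as.numeric(quantile(channel, probs = val, names = FALSE))
    },
    stop("invalid config: unknown threshold type '", type, "'"))
  mask <- channel > thr
  attr(mask, "threshold") <- thr
  mask
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs (down-right and down-left)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) unite(pairs[k, 1], pairs[k, 2])
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Locate synaptic puncta in a thresholded marker channel
#'
#' Connected components (8-connectivity) of the mask with area at least
#' `min_area_px` are treated as candidate synaptic puncta. Each punctum
#' centre is the intensity-weighted centroid of its component, rounded to
#' the nearest pixel. Puncta are returned sorted by descending component
#' total intensity.
#'
#' @param mask logical matrix from [threshold_marker()].
#' @param channel the underlying intensity matrix (same dimensions).
#' @param min_area_px minimum component area in pixels.
#' @return data frame with columns `row`, `col` (integer centre),
#'   `area_px`, `total_intensity`; zero rows when nothing is found.
#' @export
find_synapse_centres <- function(mask, channel, min_area_px = 4L) {
  stopifnot(identical(dim(mask), dim(channel)))
  empty <- data.frame(row = integer(0), col = integer(0),
                      area_px = integer(0), total_intensity = numeric(0))
  if (!any(mask)) return(empty)
  lab <- label_components8(mask)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  w <- channel[idx]
  rows <- row(lab)[idx]; cols <- col(lab)[idx]
  area <- tabulate(comp)
  tot <- rowsum(w, comp)[, 1]
  # guard: all-zero-intensity components fall back to unweighted centroid
  wz <- ifelse(rep(tot[comp] > 0, 1), w, 1)
  totz <- rowsum(wz, comp)[, 1]
  crow <- rowsum(wz * rows, comp)[, 1] / totz
  ccol <- rowsum(wz * cols, comp)[, 1] / totz
  keep <- which(area >= min_area_px)
  if (!length(keep)) return(empty)
  out <- data.frame(row = as.integer(round(crow[keep])),
                    col = as.integer(round(ccol[keep])),
                    area_px = as.integer(area[keep]),
                    total_intensity = as.numeric(tot[keep]))
  out[order(-out$total_intensity), , drop = FALSE]
}

#' Excise a fixed-size square crop centred on a punctum
#'
#' The crop side is the odd pixel count from [crop_side_px()], so the
#' punctum occupies the exact central pixel. Crops that would overlap the
#' image border are flagged `valid = FALSE` (no padding is applied, since
#' padded pixels would bias the peripheral ring) and carry no pixel data.
#'
#' @param image a [multichannel_image()].
#' @param centre integer pair `c(row, col)` inside the image.
#' @param config a [pipeline_config()]; supplies `crop_side_um`.
#' @return object of class `synapse_crop`: per-role arrays, `centre`,
#'   `side_px`, per-role `mean_intensity`, `valid`, plus source ids.
#' @export
extract_crop <- function(image, centre, config = pipeline_config()) {
  stopifnot(inherits(image, "multichannel_image"), length(centre) == 2L)
  d <- dim(image$channels[[1]])
  centre <- as.integer(round(centre))
  if (centre[1] < 1L || centre[1] > d[1] || centre[2] < 1L || centre[2] > d[2])
    stop("crop centre (", centre[1], ",", centre[2], ") lies outside the image")
  side <- crop_side_px(config$crop_side_um, image$pixel_size_nm)
  half <- (side - 1L) %/% 2L
  r0 <- centre[1] - half; r1 <- centre[1] + half
  c0 <- centre[2] - half; c1 <- centre[2] + half
  valid <- r0 >= 1L && c0 >= 1L && r1 <= d[1] && c1 <= d[2]
  arrays <- NULL
  means <- setNames(rep(NA_real_, length(image$channels)),
                    names(image$channels))
  if (valid) {
    arrays <- lapply(image$channels, function(ch) ch[r0:r1, c0:c1])
    means <- vapply(arrays, mean, numeric(1))
  }
  structure(list(arrays = arrays,
                 centre = centre,
                 side_px = side,
                 mean_intensity = means,
                 valid = valid,
                 field_id = image$field_id,
                 experiment_id = image$experiment_id),
            class = "synapse_crop")
}

#' @export
print.synapse_crop <- function(x, ...) {
  cat(sprintf("synapse_crop %s/%s @ (%d,%d), %d px, valid=%s\n",
              x$experiment_id, x$field_id, x$centre[1], x$centre[2],
              x$side_px, x$valid))
  invisible(x)
}
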