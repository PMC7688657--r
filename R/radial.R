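#' Radial intensity profile about a centre pixel
#'
#' Every pixel is assigned to the integer radius bin
#' `round(Euclidean distance to the centre in px)`; the profile reports the
#' mean intensity and pixel count of each radius bin up to the largest
#' complete ring that fits inside the image, so that
#' `sum(n_pixels * mean_intensity)` equals the total intensity within that
#' radius (conservation).
#'
#' @param image numeric matrix (typically an [average_image()]'s `data`).
#' @param centre integer pair `c(row, col)`; defaults to the central pixel
#'   of an odd-sized image.
#' @return object of class `radial_profile`: data frame `profile` with
#'   columns `radius`, `mean_intensity`, `n_pixels`, plus `centre`, `r_max`.
#' @export
radial_profile <- function(image, centre = NULL) {
  if (inherits(image, "average_image")) image <- image$data
  stopifnot(is.matrix(image), is.numeric(image))
  d <- dim(image)
  if (is.null(centre)) centre <- (d + 1L) %/% 2L
  centre <- as.numeric(centre)
  if (centre[1] < 1 || centre[1] > d[1] || centre[2] < 1 || centre[2] > d[2])
    stop("centre (", centre[1], ",", centre[2], ") lies outside the image")
  r_max <- floor(min(centre[1] - 1, d[1] - centre[1],
                     centre[2] - 1, d[2] - centre[2]))
  dr <- row(image) - centre[1]
  dc <- col(image) - centre[2]
  r <- as.integer(round(sqrt(dr * dr + dc * dc)))
  keep <- r <= r_max
  rk <- r[keep] + 1L                     # 1-based bin index for tabulate
  n_pix <- tabulate(rk, nbins = r_max + 1L)
  rs <- rowsum(image[keep], rk)
  means <- numeric(r_max + 1L)
  means[as.integer(rownames(rs))] <- rs[, 1]
  means <- means / pmax(n_pix, 1L)
  structure(list(profile = data.frame(radius = 0:r_max,
                                      mean_intensity = means,
                                      n_pixels = n_pix),
                 centre = centre, r_max = r_max),
            class = "radial_profile")
}

#' Periphery-to-centre intensity ratio of a radial profile
#'
#' The statistic that quantifies how dispersed a protein is around the
#' synaptic punctum: the mean of the ring-mean intensities over the
#' peripheral radius window (default radii 35--45 px inclusive) divided by
#' the mean over the central window (default radii 0--9 px). Values well
#' below 1 indicate concentration at the synapse; values close to 1
#' indicate a spread-out distribution. On a spatially uniform image the
#' ratio is exactly 1.
#'
#' @param profile a [radial_profile()].
#' @param config a [pipeline_config()] supplying `ring_range_px` and
#'   `centre_radius_px`.
#' @return numeric scalar ratio.
#' @export
periphery_centre_ratio <- function(profile, config = pipeline_config()) {
  stopifnot(inherits(profile, "radial_profile"))
  ring <- config$ring_range_px
  if (profile$r_max < ring[2])
    stop("profile only reaches radius ", profile$r_max,
         " but the ring ends at ", ring[2])
  mi <- profile$profile$mean_intensity
  centre_mean <- mean(mi[1:config$centre_radius_px])        # radii 0..c-1
  ring_mean <- mean(mi[(ring[1] + 1L):(ring[2] + 1L)])      # radii inclusive
  if (centre_mean == 0)
    stop("undefined ratio: centre window mean intensity is zero")
  ring_mean / centre_mean
}

#' Per-bin periphery/centre ratios and their bin-5 minus bin-1 delta
#'
#' Applies [radial_profile()] and [periphery_centre_ratio()] to one average
#' image per intensity bin and reports the ratio trend across bins together
#' with `delta`, the highest-bin ratio minus the lowest-bin ratio -- the
#' single number used to summarize how strongly marker intensity modulates
#' the spatial spread of the protein of interest.
#'
#' @param avg_images list of [average_image()] objects, one per bin, in bin
#'   order (or carrying `bin_index`).
#' @param config a [pipeline_config()].
#' @return list with `ratios` (data frame `bin_index`, `ratio`, `n_members`)
#'   and `delta`.
#' @export
ratio_trend <- function(avg_images, config = pipeline_config()) {
  if (length(avg_images) == 0L) stop("no average images supplied")
  bins <- vapply(seq_along(avg_images), function(i) {
    b <- avg_images[[i]]$bin_index
    if (is.na(b)) i else as.integer(b)
  }, integer(1))
  if (anyDuplicated(bins) || !setequal(bins, seq_len(config$n_bins)))
    stop("expected exactly one average image per bin 1..", config$n_bins,
         ", got bins: ", paste(sort(bins), collapse = ", "))
  ord <- order(bins)
  ratios <- vapply(avg_images[ord], function(ai)
    periphery_centre_ratio(radial_profile(ai$data), config), numeric(1))
  n_mem <- vapply(avg_images[ord], function(ai) ai$n_members, integer(1))
  list(ratios = data.frame(bin_index = sort(bins), ratio = ratios,
                           n_members = n_mem),
       delta = ratios[length(ratios)] - ratios[1])
}
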