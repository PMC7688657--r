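SPINE_POINTS <- c("head_top", "head_bottom", "head_left", "head_right",
                  "neck_top", "neck_bottom", "shaft_junction")

#' Manually placed spine landmarks
#'
#' Landmark set for one spine crop: the four borders of the spine head,
#' the top and bottom of the neck (mushroom spines only) and the junction
#' between the dendritic shaft and the spine. Points are `c(row, col)`
#' pixel coordinates inside the crop.
#'
#' @param crop_id identifier of the crop the landmarks belong to.
#' @param spine_class "mushroom" or "stubby".
#' @param head_top,head_bottom,head_left,head_right `c(row, col)` points.
#' @param neck_top,neck_bottom `c(row, col)` points, required for mushroom
#'   spines, `NULL` for stubby.
#' @param shaft_junction `c(row, col)` point.
#' @return object of class `spine_landmarks`.
#' @export
spine_landmarks <- function(crop_id, spine_class,
                            head_top, head_bottom, head_left, head_right,
                            neck_top = NULL, neck_bottom = NULL,
                            shaft_junction) {
  if (!spine_class %in% c("mushroom", "stubby"))
    stop("spine_class must be 'mushroom' or 'stubby'")
  pts <- list(head_top = head_top, head_bottom = head_bottom,
              head_left = head_left, head_right = head_right,
              neck_top = neck_top, neck_bottom = neck_bottom,
              shaft_junction = shaft_junction)
  required <- if (spine_class == "mushroom") SPINE_POINTS else
    setdiff(SPINE_POINTS, c("neck_top", "neck_bottom"))
  for (nm in required) {
    p <- pts[[nm]]
    if (is.null(p) || length(p) != 2L || anyNA(p))
      stop("landmark '", nm, "' missing or malformed for ", spine_class,
           " spine '", crop_id, "'")
  }
  structure(c(list(crop_id = as.character(crop_id),
                   spine_class = spine_class), pts),
            class = "spine_landmarks")
}

#' Read a spine landmark table from CSV
#'
#' Expected columns: `crop_id`, `spine_class`, then `<point>_x`,
#' `<point>_y` for each of `head_top`, `head_bottom`, `head_left`,
#' `head_right`, `neck_top`, `neck_bottom`, `shaft_junction` (`x` = column,
#' `y` = row; neck columns empty for stubby spines).
#'
#' @param path CSV file.
#' @return list of [spine_landmarks()] objects.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    getp <- function(nm) {
      x <- df[[paste0(nm, "_x")]][i]; y <- df[[paste0(nm, "_y")]][i]
      if (is.null(x) || is.na(x) || is.na(y)) NULL else c(y, x)
    }
    spine_landmarks(df$crop_id[i], df$spine_class[i],
                    head_top = getp("head_top"),
                    head_bottom = getp("head_bottom"),
                    head_left = getp("head_left"),
                    head_right = getp("head_right"),
                    neck_top = getp("neck_top"),
                    neck_bottom = getp("neck_bottom"),
                    shaft_junction = getp("shaft_junction"))
  })
}

#' Centroid of the four spine-head border points
#'
#' @param landmarks a [spine_landmarks()].
#' @return `c(row, col)` of the head centre.
#' @export
head_centre <- function(landmarks) {
  stopifnot(inherits(landmarks, "spine_landmarks"))
  pts <- rbind(landmarks$head_top, landmarks$head_bottom,
               landmarks$head_left, landmarks$head_right)
  colMeans(pts)
}

# inverse-mapping bilinear sampler; coordinates outside the source give NA
bilinear_sample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  # clamp indices for the arithmetic; invalid entries overwritten with NA
  r0c <- pmin(pmax(r0, 1), nr - 1); c0c <- pmin(pmax(c0, 1), nc - 1)
  i00 <- img[cbind(r0c, c0c)];     i10 <- img[cbind(r0c + 1, c0c)]
  i01 <- img[cbind(r0c, c0c + 1)]; i11 <- img[cbind(r0c + 1, c0c + 1)]
  val <- (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
  val[!ok] <- NA_real_
  val
}

#' Rigidly align a spine crop to the canonical frame
#'
#' Applies the rotation + translation (no scaling) that maps the spine
#' head centre to the central pixel of the crop and the head-to-shaft
#' direction to "straight down" (increasing row). Pixels are resampled
#' with bilinear interpolation; output pixels whose pre-image falls outside
#' the source are set to `NA` (missing), never zero, so that downstream
#' averaging can weight by coverage.
#'
#' @param crop a `synapse_crop` (all channel arrays are aligned) or a
#'   single numeric matrix.
#' @param landmarks a [spine_landmarks()] for this crop.
#' @return same shape as `crop`: matrix or `synapse_crop` with aligned
#'   arrays (class gains "aligned"), with attribute `rotation_deg`.
#' @export
align_spine_crop <- function(crop, landmarks) {
  single <- is.matrix(crop)
  arrays <- if (single) list(x = crop) else {
    if (!isTRUE(crop$valid)) stop("cannot align an invalid crop")
    crop$arrays
  }
  d <- dim(arrays[[1]])
  hc <- head_centre(landmarks)
  sj <- as.numeric(landmarks$shaft_junction)
  v <- sj - hc
  if (sqrt(sum(v^2)) < 1e-9)
    stop("undefined orientation: head centre coincides with shaft junction")
  # angle of the shaft direction; target direction is (1, 0) = straight down
  theta <- atan2(v[2], v[1])        # angle from +row axis toward +col axis
  ct <- cos(theta); st <- sin(theta)
  centre_out <- (d + 1) / 2
  out_r <- row(arrays[[1]]) - centre_out[1]
  out_c <- col(arrays[[1]]) - centre_out[2]
  # output frame = source rotated by -theta about the head centre:
  # source = R(theta) %*% out + head_centre
  src_r <- ct * out_r - st * out_c + hc[1]
  src_c <- st * out_r + ct * out_c + hc[2]
  aligned <- lapply(arrays, function(a) {
    m <- matrix(bilinear_sample(a, as.numeric(src_r), as.numeric(src_c)),
                d[1], d[2])
    m
  })
  if (single) {
    res <- aligned[[1]]
    attr(res, "rotation_deg") <- theta * 180 / pi
    return(res)
  }
  out <- crop
  out$arrays <- aligned
  out$mean_intensity <- vapply(aligned, function(a) mean(a, na.rm = TRUE),
                               numeric(1))
  attr(out, "rotation_deg") <- theta * 180 / pi
  class(out) <- c("aligned_spine_crop", class(crop))
  out
}

#' Average aligned spine crops, ignoring missing pixels
#'
#' Pixelwise mean over aligned crops of one spine class, where pixels that
#' fell outside the source during alignment (`NA`) simply do not
#' contribute; the per-pixel member count is retained so coverage can be
#' inspected. Pixels covered by no crop are `NA` in the average.
#'
#' @param aligned_crops list of outputs of [align_spine_crop()] (matrices
#'   or aligned `synapse_crop`s).
#' @param role channel role to average when crops are `synapse_crop`s.
#' @param spine_class label carried along.
#' @return an [average_image()]-classed object with additional element
#'   `counts` (per-pixel member counts) and `spine_class`.
#' @export
average_aligned <- function(aligned_crops, role = "poi",
                            spine_class = NA_character_) {
  if (length(aligned_crops) == 0L) stop("empty aligned crop set")
  arrs <- lapply(aligned_crops, function(cr)
    if (is.matrix(cr)) cr else cr$arrays[[role]])
  d <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), d), logical(1))))
    stop("aligned crops have mixed dimensions")
  sums <- matrix(0, d[1], d[2])
  counts <- matrix(0L, d[1], d[2])
  for (a in arrs) {
    ok <- !is.na(a)
    sums[ok] <- sums[ok] + a[ok]
    counts <- counts + ok
  }
  avg <- sums / counts
  avg[counts == 0L] <- NA_real_
  structure(list(data = avg, counts = counts,
                 n_members = length(arrs), role = role,
                 bin_index = NA_integer_, spine_class = spine_class),
            class = "average_image")
}
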