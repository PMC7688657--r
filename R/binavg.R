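#' Exclude outliers beyond mean +/- k standard deviations
#'
#' Single-pass exclusion: the mean and (sample) standard deviation are
#' computed once on all values, and values outside `mean +/- k * sd` are
#' dropped. With fewer than two values, or zero spread, everything is kept.
#' The rule is deliberately weak at small n (a single extreme value inflates
#' the SD enough to retain itself); it mirrors common practice in imaging
#' statistics rather than a robust estimator.
#'
#' @param values numeric vector.
#' @param k exclusion width in standard deviations (default 3).
#' @return list with `kept` (integer indices retained), `lower`, `upper`
#'   (the bounds applied).
#' @export
exclude_outliers <- function(values, k = 3) {
  stopifnot(is.numeric(values), k > 0)
  if (length(values) < 2L) {
    warning("fewer than 2 values; nothing excluded")
    return(list(kept = seq_along(values), lower = -Inf, upper = Inf))
  }
  m <- mean(values)
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    return(list(kept = seq_along(values), lower = m, upper = m))
  lower <- m - k * s
  upper <- m + k * s
  list(kept = which(values >= lower & values <= upper),
       lower = lower, upper = upper)
}

#' Normalize intensities to the median of their experiment
#'
#' Divides each per-synapse value by the median of all values from the same
#' experiment, removing per-experiment intensity scale differences
#' (staining efficiency, laser power drift between sessions). After
#' normalization every experiment has median 1, so values pool across
#' experiments.
#'
#' @param values numeric vector, one value per synapse.
#' @param experiment_ids vector of the same length assigning each synapse
#'   to an experiment.
#' @return numeric vector of normalized values.
#' @export
normalize_to_experiment_median <- function(values, experiment_ids) {
  stopifnot(length(values) == length(experiment_ids))
  experiment_ids <- as.character(experiment_ids)
  meds <- tapply(values, experiment_ids, median)
  if (any(meds == 0))
    stop("experiment median is zero for: ",
         paste(names(meds)[meds == 0], collapse = ", "))
  as.numeric(values / meds[experiment_ids])
}

#' Assign crops to equal-size ordinal intensity bins
#'
#' Values are ranked ascending (ties broken by stable input order) and
#' split into `n_bins` contiguous groups whose sizes differ by at most one;
#' when the count does not divide evenly, the spare crops go to the lowest
#' bins. Bin 1 holds the lowest intensities, bin `n_bins` the highest.
#'
#' @param values numeric vector of marker intensities, length >= `n_bins`.
#' @param n_bins number of bins (default 5).
#' @return integer vector of bin indices (1..n_bins) parallel to `values`,
#'   with attribute `sizes` (bin occupancies).
#' @export
assign_quantile_bins <- function(values, n_bins = 5L) {
  n <- length(values)
  if (n < n_bins)
    stop("need at least ", n_bins, " values to form ", n_bins,
         " bins, got ", n)
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- base + as.integer(seq_len(n_bins) <= rem)
  ord <- order(values)                # stable for ties (radix/shell)
  bins <- integer(n)
  bins[ord] <- rep.int(seq_len(n_bins), sizes)
  attr(bins, "sizes") <- sizes
  bins
}

#' Pixelwise average of equally sized crops
#'
#' Computes the per-pixel arithmetic mean of one channel over a set of
#' valid crops, the representation of "the average synapse" within an
#' intensity bin. Averages are formed on raw (un-normalized) crop arrays so
#' the image contrast stays physical; median normalization applies only to
#' the scalar intensity statistics.
#'
#' @param crops list of valid [extract_crop()] objects with equal `side_px`.
#' @param role channel role to average (default "poi").
#' @param bin_index optional bin label carried along.
#' @return object of class `average_image`: `data` (matrix), `n_members`,
#'   `role`, `bin_index`.
#' @export
average_image <- function(crops, role = "poi", bin_index = NA_integer_) {
  if (length(crops) == 0L) stop("empty crop set")
  if (!all(vapply(crops, function(cr) isTRUE(cr$valid), logical(1))))
    stop("all crops must be valid (border crops are excluded upstream)")
  sides <- vapply(crops, function(cr) cr$side_px, integer(1))
  if (length(unique(sides)) != 1L)
    stop("crops have mixed side lengths: ", paste(unique(sides), collapse = ", "))
  arrs <- lapply(crops, function(cr) {
    a <- cr$arrays[[role]]
    if (is.null(a)) stop("role '", role, "' missing from a crop")
    a
  })
  avg <- Reduce(`+`, arrs) / length(arrs)
  structure(list(data = avg, n_members = length(arrs), role = role,
                 bin_index = bin_index),
            class = "average_image")
}

#' @export
print.average_image <- function(x, ...) {
  cat(sprintf("average_image (%s, bin %s): %d x %d px over %d member(s)\n",
              x$role, x$bin_index, nrow(x$data), ncol(x$data), x$n_members))
  invisible(x)
}
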