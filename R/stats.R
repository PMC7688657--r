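#' Spearman rank correlation with tie-corrected ranks
#'
#' Computes Spearman's rho as the Pearson correlation of average (midrank)
#' ranks. The two-sided p-value uses the exact permutation distribution of
#' rho (holding the observed ranks fixed) for n <= 9, and the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` with n-2 degrees of
#' freedom otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p_value`, `n`, `method` ("exact" or
#'   "t-approximation"). Constant input yields `rho = NA` with a warning.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("rho undefined: constant input")
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "none"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9L) {
    perms <- e1071::permutations(n)
    # rho for each permutation of the y-ranks against fixed x-ranks
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- as.numeric((matrix(ryc[perms], nrow(perms)) %*% rxc) / denom)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Per-bin mean and standard error
#'
#' @param values numeric vector.
#' @param bins integer bin assignment parallel to `values` (e.g. from
#'   [assign_quantile_bins()]).
#' @return data frame `bin_index`, `n`, `mean`, `sem` (SEM is `NA` for
#'   singleton bins).
#' @export
bin_summary <- function(values, bins) {
  stopifnot(length(values) == length(bins))
  ub <- sort(unique(bins))
  out <- lapply(ub, function(b) {
    v <- values[bins == b]
    data.frame(bin_index = b, n = length(v), mean = mean(v),
               sem = if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v)))
  })
  do.call(rbind, out)
}

#' Ordinary least-squares line
#'
#' Thin wrapper around [stats::lm()] returning just the slope and
#' intercept; used for the dashed linear-fit lines over bin means in the
#' intensity-correlation summaries.
#'
#' @param x,y numeric vectors, `x` not constant, length >= 2.
#' @return list with `slope`, `intercept`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(x)) == 1L) stop("x is constant; fit undefined")
  co <- coef(lm(y ~ x))
  list(slope = unname(co[2]), intercept = unname(co[1]))
}

#' Significance label for a p-value
#'
#' Maps p to the conventional star labels with strict thresholds:
#' `p < 0.05` = `*`, `p < 0.01` = `**`, `p < 0.001` = `***`,
#' `p < 0.0001` = `****`, otherwise `ns.`.
#'
#' @param p numeric p-value(s) in \[0, 1\].
#' @return character vector of labels.
#' @export
significance_stars <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-value outside [0, 1]")
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns."
  }, character(1))
}

#' Correlate protein-of-interest intensity with a synaptic marker
#'
#' Pools per-synapse normalized intensities, computes Spearman's rho and
#' its p-value at the crop level, and fits an OLS line to the per-bin means
#' (matching how binned data are usually plotted). Returns a one-row data
#' frame shaped like a supplementary correlation table.
#'
#' @param poi_values,marker_values normalized per-synapse intensities.
#' @param bins bin assignment from [assign_quantile_bins()].
#' @param marker label of the marker role.
#' @return data frame: `marker`, `n`, `spearman_rho`, `p_value`, `stars`,
#'   `fit_slope`, `fit_intercept`.
#' @export
correlate_intensities <- function(poi_values, marker_values, bins,
                                  marker = "post_marker") {
  sp <- spearman_cor(marker_values, poi_values)
  bm <- bin_summary(marker_values, bins)
  bp <- bin_summary(poi_values, bins)
  fit <- linear_fit(bm$mean, bp$mean)
  data.frame(marker = marker, n = sp$n,
             spearman_rho = sp$rho, p_value = sp$p_value,
             stars = significance_stars(sp$p_value),
             fit_slope = fit$slope, fit_intercept = fit$intercept)
}
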