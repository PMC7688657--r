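#' Run the full synapse analysis pipeline
#'
#' Orchestrates every stage for one marker mode: localize puncta in the
#' chosen synaptic marker channel, excise 3 x 3 um crops, exclude outlier
#' marker intensities (mean +/- k SD), normalize intensities to each
#' experiment's median, sort crops into equal-size ordinal bins, build the
#' per-bin average POI images, compute the radial periphery/centre ratio
#' trend, detect POI spots per crop, and correlate POI with marker
#' intensity.
#'
#' @param config a [pipeline_config()].
#' @param input directory containing multichannel TIFFs written by
#'   [write_multichannel_tiff()] (ignored when `synth` is given).
#' @param synth a [synth_config()]; when supplied, fields are simulated
#'   instead of read from disk.
#' @param marker_mode "post" (bin by the post-synaptic marker) or "pre"
#'   (bin by the pre-synaptic marker), mirroring the separate
#'   homer-centred and vGLUT1/SYT1-centred analyses.
#' @param out_prefix optional path prefix; when given, result tables, the
#'   manifest and per-bin average-image TIFFs are written.
#' @return list with `per_synapse`, `per_bin`, `correlations` (data
#'   frames), `avg_images`, `ratio_trend`, `spot_summary`, `config`,
#'   `n_excluded`, and `truth` when simulated.
#' @export
run_pipeline <- function(config = pipeline_config(), input = NULL,
                         synth = NULL, marker_mode = c("post", "pre"),
                         out_prefix = NULL) {
  marker_mode <- match.arg(marker_mode)
  marker_role <- c(post = "post_marker", pre = "pre_marker")[[marker_mode]]
  truth <- NULL
  if (!is.null(synth)) {
    truth <- sample_synapse_population(synth)
    images <- render_experiment(truth, synth)
  } else {
    if (is.null(input)) stop("either 'input' or 'synth' must be given")
    paths <- list.files(input, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(paths)) stop("no input images in '", input, "'")
    images <- lapply(paths, read_multichannel_tiff,
                     pixel_size_nm = config$pixel_size_nm)
  }

  crops <- list()
  for (img in images) {
    ch <- img$channels[[marker_role]]
    if (is.null(ch)) stop("channel role '", marker_role,
                          "' missing from field ", img$field_id)
    mask <- threshold_marker(ch, config$synapse_threshold)
    centres <- find_synapse_centres(mask, ch, config$min_punctum_area_px)
    for (j in seq_len(nrow(centres))) {
      cr <- extract_crop(img, c(centres$row[j], centres$col[j]), config)
      if (cr$valid) crops[[length(crops) + 1L]] <- cr
    }
  }
  if (length(crops) < config$n_bins)
    stop("only ", length(crops), " valid crops found; need at least ",
         config$n_bins)
  analyse_crops(crops, config, marker_role = marker_role,
                out_prefix = out_prefix, truth = truth)
}

#' Analyse an existing set of synapse crops
#'
#' The binning/averaging/radial/spot/correlation stages of
#' [run_pipeline()], callable directly on crops (e.g. a synthetic fixture
#' or crops re-loaded from a previous stage).
#'
#' @param crops list of valid `synapse_crop` objects.
#' @param config a [pipeline_config()].
#' @param marker_role channel role used for binning.
#' @param out_prefix optional output path prefix (see [run_pipeline()]).
#' @param truth optional ground truth carried into the result.
#' @return see [run_pipeline()].
#' @export
analyse_crops <- function(crops, config = pipeline_config(),
                          marker_role = "post_marker", out_prefix = NULL,
                          truth = NULL) {
  marker_mean <- vapply(crops, function(cr) cr$mean_intensity[[marker_role]],
                        numeric(1))
  poi_mean <- vapply(crops, function(cr) cr$mean_intensity[["poi"]],
                     numeric(1))
  exp_ids <- vapply(crops, function(cr) cr$experiment_id, character(1))

  keep <- exclude_outliers(marker_mean, config$outlier_k)$kept
  keep <- intersect(keep, exclude_outliers(poi_mean, config$outlier_k)$kept)
  n_excluded <- length(crops) - length(keep)
  crops <- crops[keep]
  marker_mean <- marker_mean[keep]; poi_mean <- poi_mean[keep]
  exp_ids <- exp_ids[keep]

  marker_norm <- normalize_to_experiment_median(marker_mean, exp_ids)
  poi_norm <- normalize_to_experiment_median(poi_mean, exp_ids)
  bins <- assign_quantile_bins(marker_norm, config$n_bins)

  avg_images <- lapply(seq_len(config$n_bins), function(b)
    average_image(crops[bins == b], role = "poi", bin_index = b))
  trend <- ratio_trend(avg_images, config)

  spot_sets <- lapply(crops, detect_spots, config = config)
  spot_summary <- spot_stats(spot_sets, groups = bins)

  correlations <- correlate_intensities(poi_norm, marker_norm, bins,
                                        marker = marker_role)

  bm <- bin_summary(marker_norm, bins)
  bp <- bin_summary(poi_norm, bins)
  per_bin <- data.frame(bin_index = bm$bin_index, n = bm$n,
                        marker_mean = bm$mean, marker_sem = bm$sem,
                        poi_mean = bp$mean, poi_sem = bp$sem,
                        ratio = trend$ratios$ratio)
  per_synapse <- data.frame(
    crop_id = sprintf("crop%04d", seq_along(crops)),
    experiment_id = exp_ids,
    field_id = vapply(crops, function(cr) cr$field_id, character(1)),
    row = vapply(crops, function(cr) cr$centre[1], numeric(1)),
    col = vapply(crops, function(cr) cr$centre[2], numeric(1)),
    marker_mean = marker_mean, marker_norm = marker_norm,
    poi_mean = poi_mean, poi_norm = poi_norm,
    bin_index = bins,
    n_spots = vapply(spot_sets, function(s) s$n_spots, integer(1)))

  results <- list(per_synapse = per_synapse, per_bin = per_bin,
                  correlations = correlations, avg_images = avg_images,
                  ratio_trend = trend, spot_summary = spot_summary,
                  config = config, seed = config$seed,
                  n_excluded = n_excluded, truth = truth)
  if (!is.null(out_prefix)) {
    write_results(results, out_prefix)
    for (ai in avg_images) {
      m <- ai$data
      tiff::writeTIFF(m / max(m, 1e-12),
                      sprintf("%s_avg_poi_bin%d.tif", out_prefix,
                              ai$bin_index), bits.per.sample = 32L)
    }
  }
  results
}

#' Recovery benchmark against generator ground truth
#'
#' Runs two self-contained simulations and checks that the pipeline
#' recovers what the generator put in: (1) the spread-gradient fixture,
#' where per-bin periphery/centre ratios must increase strictly and the
#' bin-5 minus bin-1 delta must sit within `delta_tol` of the analytic
#' prediction of [analytic_spread_ratio()]; (2) a null population with the
#' POI decoupled from the synapse, where the POI-marker Spearman rho must
#' stay inside `rho_tol` of zero and the ratio delta inside
#' `null_delta_tol` of zero.
#'
#' @param config a [pipeline_config()].
#' @param synth a [synth_config()] used as the base for both simulations.
#' @param n_per_bin crops per bin in the gradient fixture.
#' @param sigma_list_nm spread gradient (nm).
#' @param n_null synapses in the null population.
#' @param delta_tol,rho_tol,null_delta_tol pass bands of the three checks.
#' @return data frame with one row per check: `check`, `value`, `target`,
#'   `tolerance`, `pass`.
#' @export
run_recovery_benchmark <- function(config = pipeline_config(),
                                   synth = synth_config(),
                                   n_per_bin = 100L,
                                   sigma_list_nm = c(150, 250, 350, 450, 550),
                                   n_null = 500L,
                                   delta_tol = 0.05, rho_tol = 0.1,
                                   null_delta_tol = 0.03) {
  fx <- make_spread_gradient_fixture(n_per_bin, sigma_list_nm, synth)
  res <- analyse_crops(fx$crops, config)
  ratios <- res$ratio_trend$ratios$ratio
  analytic <- analytic_spread_ratio(sigma_list_nm, synth, config)
  analytic_delta <- analytic[5] - analytic[1]
  measured_delta <- res$ratio_trend$delta

  null_synth <- synth
  null_synth$spot_model$lambda0 <-
    null_synth$spot_model$lambda0 + null_synth$spot_model$lambda_slope
  null_synth$spot_model$lambda_slope <- 0
  null_synth$spot_model$sigma0_nm <- mean(sigma_list_nm)
  null_synth$spot_model$sigma_slope_nm <- 0
  null_synth$n_synapses <- as.integer(n_null)
  null_truth <- sample_synapse_population(null_synth)
  null_crops <- render_truth_crops(null_truth, null_synth)
  null_res <- analyse_crops(null_crops, config)
  null_rho <- null_res$correlations$spearman_rho
  null_delta <- null_res$ratio_trend$delta

  data.frame(
    check = c("gradient: ratios strictly increasing",
              "gradient: delta vs analytic",
              "null: |spearman rho|",
              "null: ratio delta"),
    value = c(as.numeric(all(diff(ratios) > 0)), measured_delta,
              abs(null_rho), null_delta),
    target = c(1, analytic_delta, 0, 0),
    tolerance = c(0, delta_tol, rho_tol, null_delta_tol),
    pass = c(all(diff(ratios) > 0),
             abs(measured_delta - analytic_delta) <= delta_tol,
             abs(null_rho) <= rho_tol,
             abs(null_delta) <= null_delta_tol))
}
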