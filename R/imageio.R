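#' @importFrom stats median sd mad rnorm rpois rlnorm runif cor pt lm coef quantile setNames
#' @importFrom utils write.csv read.csv packageVersion modifyList
#' @importFrom tools file_path_sans_ext
NULL

CHANNEL_ROLES <- c("poi", "post_marker", "pre_marker", "actin")

#' Multichannel fluorescence image
#'
#' Container for one imaged field: a named list of 2-D intensity matrices,
#' one per marker role, sharing identical dimensions, together with the
#' pixel size and identifiers of the experiment and field it came from.
#'
#' Roles follow the four-colour acquisition scheme used for synapse
#' imaging: `poi` (protein of interest, STED), `post_marker` (post-synaptic
#' scaffold, e.g. homer, STED), `pre_marker` (pre-synaptic vesicle marker,
#' e.g. vGLUT1 or live-labelled SYT1, STED) and `actin`
#' (phalloidin/morphology, confocal). Not every role has to be present.
#'
#' @param channels named list of numeric matrices (non-negative), names
#'   drawn from `poi`, `post_marker`, `pre_marker`, `actin`.
#' @param pixel_size_nm positive scalar, physical pixel pitch in nm.
#' @param experiment_id,field_id character identifiers.
#' @return object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, pixel_size_nm = 30,
                               experiment_id = "exp1", field_id = "field1") {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)))
    stop("'channels' must be a non-empty named list of matrices")
  bad <- setdiff(names(channels), CHANNEL_ROLES)
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("all channels must be matrices")
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1))))
    stop("all channels must share identical dimensions")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.numeric(ch) || anyNA(ch) || any(ch < 0))
      stop("channel '", nm, "' contains negative or missing intensities")
    storage.mode(channels[[nm]]) <- "double"
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0)
    stop("pixel_size_nm must be a positive scalar")
  structure(list(channels = channels,
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 experiment_id = as.character(experiment_id),
                 field_id = as.character(field_id)),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("multichannel_image %s/%s: %d x %d px @ %g nm/px, roles: %s\n",
              x$experiment_id, x$field_id, d[1], d[2], x$pixel_size_nm,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Write a multichannel image as multi-page TIFF plus JSON sidecar
#'
#' Each channel is stored as one 32-bit float page, scaled into \[0,1\] by a
#' per-channel factor recorded in the sidecar (`<path>.json`) together with
#' the channel order, pixel size and identifiers, so that
#' [read_multichannel_tiff()] restores intensities on their original scale.
#'
#' @param img a [multichannel_image()].
#' @param path output TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_multichannel_tiff <- function(img, path) {
  stopifnot(inherits(img, "multichannel_image"))
  roles <- names(img$channels)
  scales <- vapply(img$channels, function(ch) max(ch, 1e-12), numeric(1))
  pages <- lapply(roles, function(r) img$channels[[r]] / scales[[r]])
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write TIFF to '", path, "'")
  sidecar <- list(channel_order = roles,
                  intensity_scale = as.list(setNames(scales, roles)),
                  pixel_size_nm = img$pixel_size_nm,
                  experiment_id = img$experiment_id,
                  field_id = img$field_id)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multichannel TIFF
#'
#' Reads a multi-page TIFF and assembles a [multichannel_image()]. If a JSON
#' sidecar written by [write_multichannel_tiff()] is present it supplies the
#' channel order, per-channel intensity scales, pixel size and identifiers;
#' otherwise `channel_map` must assign a page index (1-based) to each role,
#' and the pixel size falls back to `pixel_size_nm` with a warning.
#'
#' @param path TIFF path.
#' @param channel_map named integer vector, role -> page index; ignored when
#'   a sidecar is found.
#' @param pixel_size_nm fallback pixel size in nm when no metadata is found.
#' @return a [multichannel_image()].
#' @export
read_multichannel_tiff <- function(path, channel_map = NULL,
                                   pixel_size_nm = 30) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse grey-stored-as-RGB
    p
  })
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    roles <- sc$channel_order
    if (length(roles) != length(pages))
      stop("format error: ", length(pages), " TIFF pages but sidecar lists ",
           length(roles), " channels")
    channels <- setNames(lapply(seq_along(roles), function(i)
      pages[[i]] * as.numeric(sc$intensity_scale[[roles[i]]])), roles)
    return(multichannel_image(channels,
                              pixel_size_nm = sc$pixel_size_nm,
                              experiment_id = sc$experiment_id,
                              field_id = sc$field_id))
  }
  if (is.null(channel_map))
    stop("no sidecar found; 'channel_map' is required")
  if (max(channel_map) > length(pages) || min(channel_map) < 1L)
    stop("format error: channel_map refers to page ", max(channel_map),
         " but file has ", length(pages), " page(s)")
  channels <- setNames(lapply(channel_map, function(i) pages[[i]]),
                       names(channel_map))
  warning("no pixel size metadata for '", basename(path),
          "'; falling back to ", pixel_size_nm, " nm")
  multichannel_image(channels, pixel_size_nm = pixel_size_nm,
                     experiment_id = "unknown",
                     field_id = tools::file_path_sans_ext(basename(path)))
}

#' Pipeline configuration
#'
#' Validated bundle of every tunable analysis parameter. Defaults follow
#' the published analysis settings: 3 x 3 um crops, five intensity bins,
#' a periphery/centre ratio computed from radii 35--45 px over radii
#' 0--9 px, outlier exclusion at mean +/- 3 SD, wavelet spot detection at
#' scale 2 with 80% sensitivity.
#'
#' @param crop_side_um crop side length in micrometres (default 3).
#' @param n_bins number of ordinal intensity bins (default 5).
#' @param centre_radius_px number of central radial bins (radii
#'   `0..centre_radius_px-1`) in the ratio denominator (default 10).
#' @param ring_range_px inclusive radius window of the peripheral ring
#'   (default `c(35, 45)`).
#' @param outlier_k exclusion width in standard deviations (default 3).
#' @param wavelet_scale a-trous detail scale used for spot detection
#'   (default 2).
#' @param wavelet_threshold_pct detection sensitivity in (0, 100]
#'   (default 80).
#' @param synapse_threshold list with `type` ("quantile" or "absolute") and
#'   `value`; replaces the manual thresholding of the marker channel by an
#'   explicit, logged rule.
#' @param min_punctum_area_px minimum connected-component area for a
#'   synaptic punctum (default 4).
#' @param min_spot_area_px minimum area of a detected wavelet spot;
#'   `NULL` (default) resolves to `2^wavelet_scale + 1` (5 at scale 2),
#'   the smallest component exceeding the correlation footprint of
#'   thresholded noise in that detail plane (supra-threshold noise at
#'   scale j clusters into blobs of up to ~2^j pixels, so a fixed
#'   single-pixel rule does not suppress it).
#' @param pixel_size_nm nominal pixel size in nm used for geometry checks
#'   and as fallback for files without metadata (default 30).
#' @param seed integer seed controlling all stochastic stages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(crop_side_um = 3.0,
                            n_bins = 5L,
                            centre_radius_px = 10L,
                            ring_range_px = c(35L, 45L),
                            outlier_k = 3,
                            wavelet_scale = 2L,
                            wavelet_threshold_pct = 80,
                            synapse_threshold = list(type = "quantile",
                                                     value = 0.98),
                            min_punctum_area_px = 4L,
                            min_spot_area_px = NULL,
                            pixel_size_nm = 30,
                            seed = 1L) {
  if (is.null(min_spot_area_px))
    min_spot_area_px <- 2L^wavelet_scale + 1L
  stopifnot(is.numeric(crop_side_um), crop_side_um > 0,
            n_bins >= 1, centre_radius_px >= 1,
            length(ring_range_px) == 2L,
            outlier_k > 0, wavelet_scale >= 1,
            min_punctum_area_px >= 1, min_spot_area_px >= 1,
            pixel_size_nm > 0)
  ring_range_px <- as.integer(ring_range_px)
  if (ring_range_px[1] >= ring_range_px[2])
    stop("invalid config: ring_range_px must be increasing, got (",
         ring_range_px[1], ",", ring_range_px[2], ")")
  if (centre_radius_px > ring_range_px[1])
    stop("invalid config: centre window (centre_radius_px = ",
         centre_radius_px, ") must end before the ring starts ",
         "(ring_range_px[1] = ", ring_range_px[1], ")")
  if (!(wavelet_threshold_pct > 0 && wavelet_threshold_pct <= 100))
    stop("invalid config: wavelet_threshold_pct must be in (0, 100]")
  if (!is.list(synapse_threshold) ||
      !synapse_threshold$type %in% c("quantile", "absolute"))
    stop("invalid config: synapse_threshold$type must be 'quantile' or 'absolute'")
  if (synapse_threshold$type == "quantile" &&
      !(synapse_threshold$value > 0 && synapse_threshold$value < 1))
    stop("invalid config: quantile threshold must lie in (0, 1)")
  side <- crop_side_px(crop_side_um, pixel_size_nm)
  half <- (side - 1L) %/% 2L
  if (half < ring_range_px[2])
    stop("invalid config: crop radius ", half, " px (crop_side_um = ",
         crop_side_um, " at ", pixel_size_nm, " nm/px) is smaller than the ",
         "outer ring radius ", ring_range_px[2], " px")
  structure(list(crop_side_um = crop_side_um,
                 n_bins = as.integer(n_bins),
                 centre_radius_px = as.integer(centre_radius_px),
                 ring_range_px = ring_range_px,
                 outlier_k = outlier_k,
                 wavelet_scale = as.integer(wavelet_scale),
                 wavelet_threshold_pct = wavelet_threshold_pct,
                 synapse_threshold = synapse_threshold,
                 min_punctum_area_px = as.integer(min_punctum_area_px),
                 min_spot_area_px = as.integer(min_spot_area_px),
                 pixel_size_nm = pixel_size_nm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Missing fields take the package defaults (see [pipeline_config()]); an
#' empty document yields the full default configuration. Invariants are
#' enforced on load so a malformed configuration fails before any image is
#' touched.
#'
#' @param path YAML or JSON file.
#' @return a validated [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(doc), known)
  if (length(extra))
    warning("ignoring unknown config field(s): ", paste(extra, collapse = ", "))
  do.call(pipeline_config, doc[intersect(names(doc), known)])
}

#' Write result tables and a run manifest
#'
#' Emits `*_synapses.csv` (one row per synapse crop), `*_bins.csv` (one row
#' per bin), `*_correlations.csv`, and `*_manifest.json` carrying the
#' complete effective configuration, its hash, the seed and the package
#' version, so a run can be reproduced from its outputs alone.
#'
#' @param results list with elements `per_synapse`, `per_bin`,
#'   `correlations` (data frames; missing ones are written as header-only
#'   files) and optionally `config` (a [pipeline_config()]) and `seed`.
#' @param path_prefix path prefix for the four output files.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(results, path_prefix) {
  dir.create(dirname(path_prefix), recursive = TRUE, showWarnings = FALSE)
  empty <- function(cols) as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  tabs <- list(
    synapses = results$per_synapse %||%
      empty(c("crop_id", "experiment_id", "field_id", "row", "col")),
    bins = results$per_bin %||% empty(c("bin_index", "n")),
    correlations = results$correlations %||%
      empty(c("marker", "n", "spearman_rho", "p_value")))
  files <- character(0)
  for (nm in names(tabs)) {
    f <- paste0(path_prefix, "_", nm, ".csv")
    write.csv(tabs[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  cfg <- results$config
  manifest <- list(
    config = if (is.null(cfg)) NULL else unclass(cfg),
    config_hash = if (is.null(cfg)) NULL else digest::digest(unclass(cfg)),
    seed = results$seed %||% (if (!is.null(cfg)) cfg$seed else NULL),
    package_version = as.character(packageVersion("stedsynapse")),
    files = basename(files),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mf <- paste0(path_prefix, "_manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, mf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
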