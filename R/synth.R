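FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))   # 0.42466

#' Gaussian PSF width in pixels
#' @param fwhm_nm full width at half maximum in nm.
#' @param pixel_size_nm pixel pitch in nm.
#' @return standard deviation in pixels.
#' @export
psf_sigma_px <- function(fwhm_nm, pixel_size_nm) {
  fwhm_nm * FWHM_TO_SIGMA / pixel_size_nm
}

#' Configuration of the synthetic STED image generator
#'
#' Defines the statistical model the generator samples from. Each synapse
#' carries two latent variables: a strength `S` (post-synaptic size, read
#' out by the homer-like marker) and an activity `A` (recycling-vesicle
#' level, read out by the SYT1-like marker), log-normal and independent by
#' default. The protein of interest (POI) is rendered as discrete spots
#' whose expected count is `lambda0 + lambda_slope * latent` and whose
#' isotropic Gaussian spread around the synapse is
#' `sigma0_nm + sigma_slope_nm * latent`; both latent hooks are
#' configurable, and slope 0 decouples the POI from the synapse entirely
#' (the null model). Channels are blurred with channel-specific Gaussian
#' PSFs (STED-like for the three protein channels, confocal-like for
#' actin), then corrupted with Poisson noise at the given gain followed by
#' additive Gaussian read noise; each experiment gets a log-normal
#' multiplicative intensity factor emulating staining/alignment batch
#' effects.
#'
#' @param image_size_px integer pair, field size (default 512 x 512).
#' @param pixel_size_nm pixel pitch in nm (default 30).
#' @param n_synapses total number of synapses in the population.
#' @param n_experiments number of independent experiments (default 4).
#' @param synapses_per_field how many synapses share one rendered field.
#' @param latent_model list: `s_meanlog`, `s_sdlog`, `a_meanlog`,
#'   `a_sdlog`, `sa_cor` (Gaussian-copula correlation of S and A),
#'   `homer_gain`, `pre_gain`, `amp_sdlog` (log-normal amplitude noise),
#'   `poi_amp` (mean integrated intensity per POI spot), `poi_amp_sdlog`.
#' @param spot_model list: `lambda0`, `lambda_slope`, `count_latent`
#'   ("S", "A" or "none"), `sigma0_nm`, `sigma_slope_nm`, `spread_latent`.
#' @param psf_fwhm_nm named vector of per-role PSF FWHM in nm (defaults:
#'   60 for the STED channels, 250 for confocal actin).
#' @param noise list: `gain` (Poisson scaling; 0 disables shot noise),
#'   `read_sd` (Gaussian read noise, counts), `background` (counts).
#' @param batch_sdlog sdlog of the per-experiment intensity factor.
#' @param spine_fracs named probabilities for classes `mushroom`, `stubby`,
#'   `none`.
#' @param seed integer seed; every sampling function derives its stream
#'   from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(image_size_px = c(512L, 512L),
                         pixel_size_nm = 30,
                         n_synapses = 120L,
                         n_experiments = 4L,
                         synapses_per_field = 12L,
                         latent_model = list(),
                         spot_model = list(),
                         psf_fwhm_nm = c(poi = 60, post_marker = 60,
                                         pre_marker = 60, actin = 250),
                         noise = list(),
                         batch_sdlog = 0.15,
                         spine_fracs = c(mushroom = 0.25, stubby = 0.15,
                                         none = 0.6),
                         seed = 1L) {
  lm_def <- list(s_meanlog = 0, s_sdlog = 0.5, a_meanlog = 0, a_sdlog = 0.5,
                 sa_cor = 0, homer_gain = 5000, pre_gain = 5000,
                 amp_sdlog = 0.2, poi_amp = 400, poi_amp_sdlog = 0.2,
                 marker_size_nm = 100)
  sm_def <- list(lambda0 = 1.5, lambda_slope = 1.75, count_latent = "S",
                 sigma0_nm = 150, sigma_slope_nm = 100, spread_latent = "A")
  ns_def <- list(gain = 1, read_sd = 2, background = 2)
  latent_model <- utils::modifyList(lm_def, latent_model)
  spot_model <- utils::modifyList(sm_def, spot_model)
  noise <- utils::modifyList(ns_def, noise)
  stopifnot(length(image_size_px) == 2L, all(image_size_px > 0),
            pixel_size_nm > 0, n_experiments >= 1L,
            synapses_per_field >= 1L,
            all(psf_fwhm_nm > 0), noise$gain >= 0, noise$read_sd >= 0,
            noise$background >= 0, batch_sdlog >= 0)
  if (n_synapses < 1L)
    stop("invalid config: n_synapses must be positive")
  if (!all(CHANNEL_ROLES %in% names(psf_fwhm_nm)))
    stop("invalid config: psf_fwhm_nm must name all roles: ",
         paste(CHANNEL_ROLES, collapse = ", "))
  if (any(psf_fwhm_nm < pixel_size_nm / 2))
    warning("PSF FWHM below half a pixel; spots will be undersampled")
  if (spot_model$lambda0 < 0 || spot_model$lambda_slope < 0)
    stop("invalid config: spot count rate must be monotone non-decreasing ",
         "(lambda0, lambda_slope >= 0)")
  if (spot_model$sigma0_nm <= 0 || spot_model$sigma_slope_nm < 0)
    stop("invalid config: spot spread must be positive and non-decreasing")
  if (abs(sum(spine_fracs) - 1) > 1e-9 ||
      !all(c("mushroom", "stubby", "none") %in% names(spine_fracs)))
    stop("invalid config: spine_fracs must name mushroom/stubby/none and sum to 1")
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_nm = pixel_size_nm,
                 n_synapses = as.integer(n_synapses),
                 n_experiments = as.integer(n_experiments),
                 synapses_per_field = as.integer(synapses_per_field),
                 latent_model = latent_model,
                 spot_model = spot_model,
                 psf_fwhm_nm = psf_fwhm_nm,
                 noise = noise,
                 batch_sdlog = batch_sdlog,
                 spine_fracs = spine_fracs,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# rendered width of a marker punctum: object size convolved with the PSF
marker_sigma_px <- function(config, role) {
  sqrt(psf_sigma_px(config$psf_fwhm_nm[[role]], config$pixel_size_nm)^2 +
         (config$latent_model$marker_size_nm / config$pixel_size_nm)^2)
}

latent_value <- function(which, S, A) {
  switch(which, S = S, A = A, none = rep(1, length(S)),
         stop("latent hook must be 'S', 'A' or 'none'"))
}

# draw n isotropic Gaussian offsets (px), redrawn until within +/- (bound) px
draw_offsets <- function(n, sigma_px, bound) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  out <- matrix(rnorm(2 * n, 0, sigma_px), n, 2)
  bad <- which(pmax(abs(out[, 1]), abs(out[, 2])) > bound)
  guard <- 0L
  while (length(bad) && guard < 1000L) {
    out[bad, ] <- matrix(rnorm(2 * length(bad), 0, sigma_px),
                         length(bad), 2)
    bad <- which(pmax(abs(out[, 1]), abs(out[, 2])) > bound)
    guard <- guard + 1L
  }
  out
}

#' Sample a synthetic synapse population with ground truth
#'
#' Draws the latent strength/activity variables, marker amplitudes, POI
#' spot counts, spreads and positions, spine classes and landmarks for
#' `config$n_synapses` synapses, split over experiments and fields. With
#' independent latents (the default), homer-like and pre-synaptic
#' amplitudes are uncorrelated across the population.
#'
#' @param config a [synth_config()].
#' @return object of class `ground_truth`: a data frame (one row per
#'   synapse) with columns `synapse_id`, `experiment_id`, `field_id`,
#'   `centre_row`, `centre_col`, `S`, `A`, `homer_amp`, `pre_amp`,
#'   `poi_spot_count`, `poi_spread_nm`, `spine_class`, `batch_factor`,
#'   and attributes `spots` (list of per-synapse matrices with columns
#'   `d_row`, `d_col`, `amp`, offsets in px from the centre), `landmarks`
#'   (list of offset landmark sets, `NULL` for class "none") and `config`.
#' @export
sample_synapse_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_synapses
  lm <- config$latent_model
  sm <- config$spot_model
  px <- config$pixel_size_nm

  # latents via Gaussian copula so sa_cor = 0 gives exact independence
  z1 <- rnorm(n)
  z2 <- lm$sa_cor * z1 + sqrt(1 - lm$sa_cor^2) * rnorm(n)
  S <- exp(lm$s_meanlog + lm$s_sdlog * z1)
  A <- exp(lm$a_meanlog + lm$a_sdlog * z2)

  experiment_id <- sprintf("exp%02d", rep_len(seq_len(config$n_experiments), n))
  batch <- rlnorm(config$n_experiments, 0, config$batch_sdlog)
  batch_factor <- batch[match(experiment_id,
                              sprintf("exp%02d", seq_len(config$n_experiments)))]
  # fields: consecutive synapses of one experiment share a field
  idx_in_exp <- stats::ave(seq_len(n), experiment_id, FUN = seq_along)
  field_id <- sprintf("%s_f%02d", experiment_id,
                      (idx_in_exp - 1L) %/% config$synapses_per_field + 1L)

  side <- crop_side_px(3.0, px)
  half <- (side - 1L) %/% 2L
  d <- config$image_size_px
  if (d[1] <= 2L * half + 2L || d[2] <= 2L * half + 2L)
    stop("invalid config: field too small to place crops of half-side ", half)
  centre_row <- runif(n, half + 1, d[1] - half)
  centre_col <- runif(n, half + 1, d[2] - half)

  homer_amp <- lm$homer_gain * S * rlnorm(n, 0, lm$amp_sdlog)
  pre_amp <- lm$pre_gain * A * rlnorm(n, 0, lm$amp_sdlog)
  lambda <- sm$lambda0 + sm$lambda_slope * latent_value(sm$count_latent, S, A)
  poi_spot_count <- rpois(n, lambda)
  poi_spread_nm <- sm$sigma0_nm +
    sm$sigma_slope_nm * latent_value(sm$spread_latent, S, A)

  spine_class <- sample(names(config$spine_fracs), n, replace = TRUE,
                        prob = config$spine_fracs)
  # pre-synaptic bouton sits ~150 nm off the post-synaptic punctum
  pre_theta <- runif(n, 0, 2 * pi)
  pre_off_px <- 150 / px
  # spine geometry: orientation of the head -> shaft axis, head radius
  spine_theta <- runif(n, 0, 2 * pi)
  head_radius_px <- (250 + 60 * pmin(S, 4)) / px
  neck_len_px <- ifelse(spine_class == "mushroom", 250 / px, 60 / px)

  spots <- vector("list", n)
  landmarks <- vector("list", n)
  for (i in seq_len(n)) {
    k <- poi_spot_count[i]
    off <- draw_offsets(k, poi_spread_nm[i] / px, half - 2)
    if (spine_class[i] != "none" && k > 0L) {
      # secretory signal originates from the dendritic side: bias the
      # spot cloud half-way towards the shaft junction
      dvec <- c(cos(spine_theta[i]), sin(spine_theta[i]))
      shift <- 0.5 * (head_radius_px[i] + neck_len_px[i])
      off <- sweep(off, 2, shift * dvec, "+")
      out_of_crop <- pmax(abs(off[, 1]), abs(off[, 2])) > half - 2
      off[out_of_crop, ] <- 0
    }
    amp <- lm$poi_amp * rlnorm(k, 0, lm$poi_amp_sdlog)
    spots[[i]] <- cbind(d_row = off[, 1], d_col = off[, 2], amp = amp)
    if (spine_class[i] != "none") {
      dvec <- c(cos(spine_theta[i]), sin(spine_theta[i]))
      pvec <- c(-dvec[2], dvec[1])
      rh <- head_radius_px[i]
      lmk <- list(head_top = -rh * dvec, head_bottom = rh * dvec,
                  head_left = -rh * pvec, head_right = rh * pvec,
                  shaft_junction = (rh + neck_len_px[i] + 2) * dvec)
      if (spine_class[i] == "mushroom") {
        lmk$neck_top <- rh * dvec
        lmk$neck_bottom <- (rh + neck_len_px[i]) * dvec
      }
      landmarks[[i]] <- lmk
    }
  }

  truth <- data.frame(synapse_id = sprintf("syn%04d", seq_len(n)),
                      experiment_id = experiment_id,
                      field_id = field_id,
                      centre_row = centre_row, centre_col = centre_col,
                      S = S, A = A,
                      homer_amp = homer_amp, pre_amp = pre_amp,
                      poi_spot_count = poi_spot_count,
                      poi_spread_nm = poi_spread_nm,
                      spine_class = spine_class,
                      batch_factor = batch_factor,
                      stringsAsFactors = FALSE)
  attr(truth, "spots") <- spots
  attr(truth, "landmarks") <- landmarks
  attr(truth, "config") <- config
  class(truth) <- c("ground_truth", class(truth))
  truth
}

# add amp * normalized 2-D Gaussian at (row, col) onto canvas, in place-ish
render_points <- function(canvas, pts, sigma_px) {
  if (is.null(pts) || nrow(pts) == 0L) return(canvas)
  d <- dim(canvas)
  w <- max(3L, ceiling(5 * sigma_px))
  for (i in seq_len(nrow(pts))) {
    r0 <- pts[i, 1]; c0 <- pts[i, 2]; amp <- pts[i, 3]
    rr <- max(1L, floor(r0 - w)):min(d[1], ceiling(r0 + w))
    cc <- max(1L, floor(c0 - w)):min(d[2], ceiling(c0 + w))
    gr <- exp(-(rr - r0)^2 / (2 * sigma_px^2))
    gc <- exp(-(cc - c0)^2 / (2 * sigma_px^2))
    canvas[rr, cc] <- canvas[rr, cc] +
      (amp / (2 * pi * sigma_px^2)) * outer(gr, gc)
  }
  canvas
}

#' Render synthetic fields from a sampled ground truth
#'
#' Draws every channel of one (or all) fields of the ground truth:
#' post-synaptic puncta at the synapse centres, pre-synaptic puncta offset
#' by ~150 nm, POI spots at their ground-truth positions, and a coarse
#' actin channel marking the spine region; all PSF-blurred, scaled by the
#' experiment batch factor, then Poisson- and Gaussian-corrupted. The
#' render is deterministic given `seed` (default derived from the config
#' seed).
#'
#' @param truth a [sample_synapse_population()] result.
#' @param config the matching [synth_config()].
#' @param field_id field to render; `NULL` renders all fields.
#' @param seed RNG seed for the noise draw.
#' @return a [multichannel_image()] when a single field is requested,
#'   otherwise a named list of them.
#' @export
render_experiment <- function(truth, config, field_id = NULL, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "synth_config"))
  if (is.null(seed)) seed <- config$seed + 1000L
  set.seed(seed)
  fields <- if (is.null(field_id)) sort(unique(truth$field_id)) else field_id
  spots <- attr(truth, "spots")
  px <- config$pixel_size_nm
  sig <- vapply(CHANNEL_ROLES, function(r)
    psf_sigma_px(config$psf_fwhm_nm[[r]], px), numeric(1))
  d <- config$image_size_px
  out <- lapply(fields, function(fid) {
    sel <- which(truth$field_id == fid)
    if (!length(sel)) stop("unknown field_id: ", fid)
    bf <- truth$batch_factor[sel[1]]
    bg <- config$noise$background
    ch <- list()
    cr <- truth$centre_row[sel]; cc <- truth$centre_col[sel]
    ch$post_marker <- render_points(matrix(bg, d[1], d[2]),
                                    cbind(cr, cc, truth$homer_amp[sel] * bf),
                                    marker_sigma_px(config, "post_marker"))
    pre_theta <- runif(length(sel), 0, 2 * pi)
    ch$pre_marker <- render_points(matrix(bg, d[1], d[2]),
                                   cbind(cr + (150 / px) * cos(pre_theta),
                                         cc + (150 / px) * sin(pre_theta),
                                         truth$pre_amp[sel] * bf),
                                   marker_sigma_px(config, "pre_marker"))
    poi_pts <- do.call(rbind, lapply(seq_along(sel), function(j) {
      sp <- spots[[sel[j]]]
      if (nrow(sp) == 0L) return(NULL)
      cbind(cr[j] + sp[, "d_row"], cc[j] + sp[, "d_col"], sp[, "amp"] * bf)
    }))
    ch$poi <- render_points(matrix(bg, d[1], d[2]), poi_pts, sig[["poi"]])
    ch$actin <- render_points(matrix(bg, d[1], d[2]),
                              cbind(cr, cc, 400 * bf), sig[["actin"]])
    ch <- lapply(ch, function(m) {
      m2 <- m
      if (config$noise$gain > 0)
        m2 <- matrix(rpois(length(m2), pmax(m2, 0) * config$noise$gain) /
                       config$noise$gain, d[1], d[2])
      if (config$noise$read_sd > 0)
        m2 <- m2 + matrix(rnorm(length(m2), 0, config$noise$read_sd),
                          d[1], d[2])
      pmax(m2, 0)
    })
    exp_id <- truth$experiment_id[sel[1]]
    multichannel_image(ch, pixel_size_nm = px, experiment_id = exp_id,
                       field_id = fid)
  })
  names(out) <- fields
  if (length(out) == 1L && !is.null(field_id)) out[[1]] else out
}

# render each synapse of a ground truth directly as a centred crop
render_truth_crops <- function(truth, config, seed = NULL,
                               roles = c("poi", "post_marker")) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(seed)) seed <- config$seed + 2000L
  set.seed(seed)
  px <- config$pixel_size_nm
  side <- crop_side_px(3.0, px)
  centre <- (side + 1L) %/% 2L
  spots <- attr(truth, "spots")
  bg <- config$noise$background
  lapply(seq_len(nrow(truth)), function(i) {
    bf <- truth$batch_factor[i]
    arrays <- list()
    if ("post_marker" %in% roles)
      arrays$post_marker <- render_points(
        matrix(bg, side, side), cbind(centre, centre, truth$homer_amp[i] * bf),
        marker_sigma_px(config, "post_marker"))
    if ("pre_marker" %in% roles)
      arrays$pre_marker <- render_points(
        matrix(bg, side, side), cbind(centre, centre, truth$pre_amp[i] * bf),
        marker_sigma_px(config, "pre_marker"))
    if ("poi" %in% roles) {
      sp <- spots[[i]]
      pts <- if (nrow(sp)) cbind(centre + sp[, "d_row"],
                                 centre + sp[, "d_col"], sp[, "amp"] * bf)
      else NULL
      arrays$poi <- render_points(matrix(bg, side, side), pts,
                                  psf_sigma_px(config$psf_fwhm_nm[["poi"]], px))
    }
    arrays <- lapply(arrays, function(m) {
      if (config$noise$gain > 0)
        m <- matrix(rpois(length(m), pmax(m, 0) * config$noise$gain) /
                      config$noise$gain, side, side)
      if (config$noise$read_sd > 0)
        m <- m + matrix(rnorm(length(m), 0, config$noise$read_sd), side, side)
      pmax(m, 0)
    })
    structure(list(arrays = arrays, centre = c(centre, centre),
                   side_px = side,
                   mean_intensity = vapply(arrays, mean, numeric(1)),
                   valid = TRUE,
                   field_id = truth$field_id[i],
                   experiment_id = truth$experiment_id[i]),
              class = "synapse_crop")
  })
}

#' Spread-gradient fixture: five bins of known, increasing POI spread
#'
#' Builds `5 * n_per_bin` synthetic crops in which the POI spot spread is
#' fixed per bin at `sigma_list_nm` and the marker amplitude increases
#' strictly with the bin index, so that quantile binning by marker
#' intensity recovers the intended grouping and the per-bin
#' periphery/centre ratios should rise along the analytic curve returned
#' by [analytic_spread_ratio()].
#'
#' @param n_per_bin crops per bin (0 gives an empty fixture with warning).
#' @param sigma_list_nm strictly increasing vector of 5 spreads in nm.
#' @param config a [synth_config()]; noise, PSF, amplitudes and seed come
#'   from here.
#' @param noise logical; `FALSE` renders noise-free crops.
#' @param strict require strictly increasing `sigma_list_nm` (default);
#'   set `FALSE` to allow the degenerate equal-spread control.
#' @return list with `crops` (list of `synapse_crop`), `truth` (data frame
#'   `bin`, `sigma_nm`, `homer_amp`, `poi_spot_count`).
#' @export
make_spread_gradient_fixture <- function(n_per_bin, sigma_list_nm,
                                         config = synth_config(),
                                         noise = TRUE, strict = TRUE) {
  if (length(sigma_list_nm) != 5L)
    stop("invalid config: sigma_list_nm must have length 5")
  if (strict && any(diff(sigma_list_nm) <= 0))
    stop("invalid config: sigma_list_nm must be strictly increasing")
  if (!strict && any(diff(sigma_list_nm) < 0))
    stop("invalid config: sigma_list_nm must be non-decreasing")
  if (n_per_bin == 0L) {
    warning("n_per_bin = 0: empty fixture")
    return(list(crops = list(),
                truth = data.frame(bin = integer(0), sigma_nm = numeric(0),
                                   homer_amp = numeric(0),
                                   poi_spot_count = integer(0))))
  }
  set.seed(config$seed)
  lm <- config$latent_model
  sm <- config$spot_model
  px <- config$pixel_size_nm
  side <- crop_side_px(3.0, px)
  centre <- (side + 1L) %/% 2L
  half <- (side - 1L) %/% 2L
  sig_poi <- psf_sigma_px(config$psf_fwhm_nm[["poi"]], px)
  sig_post <- marker_sigma_px(config, "post_marker")
  lambda <- sm$lambda0 + sm$lambda_slope  # rate at the reference latent S = 1
  bg <- config$noise$background
  ns <- if (noise) config$noise else list(gain = 0, read_sd = 0,
                                          background = bg)
  crops <- list()
  truth <- NULL
  for (b in 1:5) {
    for (i in seq_len(n_per_bin)) {
      homer_amp <- lm$homer_gain * (0.5 + 0.5 * b) * rlnorm(1, 0, 0.05)
      k <- rpois(1, lambda)
      off <- draw_offsets(k, sigma_list_nm[b] / px, half - 2)
      amp <- lm$poi_amp * rlnorm(k, 0, lm$poi_amp_sdlog)
      poi <- render_points(matrix(bg, side, side),
                           if (k) cbind(centre + off[, 1], centre + off[, 2],
                                        amp) else NULL, sig_poi)
      post <- render_points(matrix(bg, side, side),
                            cbind(centre, centre, homer_amp), sig_post)
      arrays <- lapply(list(poi = poi, post_marker = post), function(m) {
        if (ns$gain > 0)
          m <- matrix(rpois(length(m), pmax(m, 0) * ns$gain) / ns$gain,
                      side, side)
        if (ns$read_sd > 0)
          m <- m + matrix(rnorm(length(m), 0, ns$read_sd), side, side)
        pmax(m, 0)
      })
      crops[[length(crops) + 1L]] <-
        structure(list(arrays = arrays, centre = c(centre, centre),
                       side_px = side,
                       mean_intensity = vapply(arrays, mean, numeric(1)),
                       valid = TRUE, field_id = sprintf("bin%d_%03d", b, i),
                       experiment_id = "exp01"),
                  class = "synapse_crop")
      truth <- rbind(truth, data.frame(bin = b, sigma_nm = sigma_list_nm[b],
                                       homer_amp = homer_amp,
                                       poi_spot_count = k))
    }
  }
  list(crops = crops, truth = truth)
}

#' Analytic periphery/centre ratio of the generator's average image
#'
#' For crops whose POI consists of Poisson-count spots scattered as an
#' isotropic Gaussian (sd `sigma_nm`) around the centre, blurred by a
#' Gaussian PSF and sitting on a flat background, the expected average
#' image is `background + C * G(d; sigma_eff)`, with
#' `sigma_eff^2 = sigma_nm^2 + sigma_psf^2`, `C` the expected total spot
#' intensity per crop, and `G` the unit-mass 2-D Gaussian. This function
#' evaluates that expectation on the pixel lattice, applies the same
#' integer-radius binning as [radial_profile()], and returns the
#' periphery/centre ratio -- the generator-side prediction the measured
#' fixture ratios are compared against. The prediction includes the
#' measurement chain: the zero-clip of the Poisson + read-noise model
#' (averaged over the sparse per-crop deposit distribution, not the
#' ensemble-mean image) and the renormalization from in-crop truncation
#' of the spot scatter; see the methods vignette.
#'
#' @param sigma_nm spot-scatter sd in nm (vectorized).
#' @param config a [synth_config()] supplying PSF, amplitudes, spot rate
#'   and background.
#' @param pipeline a [pipeline_config()] supplying the ratio windows.
#' @return numeric vector of ratios, one per `sigma_nm`.
#' @export
analytic_spread_ratio <- function(sigma_nm, config = synth_config(),
                                  pipeline = pipeline_config()) {
  px <- config$pixel_size_nm
  lm <- config$latent_model
  sm <- config$spot_model
  side <- crop_side_px(pipeline$crop_side_um, px)
  half <- (side - 1L) %/% 2L
  offs <- seq(-half, half)
  dmat <- sqrt(outer(offs^2, offs^2, "+"))
  rmat <- round(dmat)
  lambda <- sm$lambda0 + sm$lambda_slope
  C <- lambda * lm$poi_amp * exp(lm$poi_amp_sdlog^2 / 2)
  bg <- config$noise$background
  sig_psf_px <- config$psf_fwhm_nm[["poi"]] * FWHM_TO_SIGMA / px
  amp_bar <- lm$poi_amp * exp(lm$poi_amp_sdlog^2 / 2)
  # zero-clip bonus of the noise chain at the background level, and the
  # per-spot area over which a deposit suppresses that bonus (see vignette:
  # the per-crop pixel distribution is background almost everywhere with
  # sparse bright deposits, so the clip correction is b(bg) minus its
  # suppression where a spot lands -- not b() of the ensemble-mean image)
  b_bg <- expected_recorded_intensity(bg, config$noise) - bg
  a_eff <- 0
  if (b_bg > 1e-10) {
    rho <- seq(0, 6 * sig_psf_px, by = 0.05)
    dep <- amp_bar * exp(-rho^2 / (2 * sig_psf_px^2)) / (2 * pi * sig_psf_px^2)
    b_dep <- expected_recorded_intensity(bg + dep, config$noise) - (bg + dep)
    a_eff <- sum(2 * pi * rho * (1 - b_dep / b_bg)) * 0.05
  }
  vapply(sigma_nm, function(s) {
    sc_px <- s / px                       # scatter sd
    se_px <- sqrt(s^2 + (sig_psf_px * px)^2) / px
    trunc_p <- (2 * stats::pnorm((half - 2) / sc_px) - 1)^2
    gauss_se <- exp(-dmat^2 / (2 * se_px^2)) / (2 * pi * se_px^2)
    gauss_sc <- exp(-dmat^2 / (2 * sc_px^2)) / (2 * pi * sc_px^2)
    v <- bg + (C / trunc_p) * gauss_se
    p_spot <- 1 - exp(-lambda * (gauss_sc / trunc_p) * a_eff)
    img <- v + b_bg * (1 - p_spot)
    ring_means <- tapply(img, rmat, mean)
    r <- as.integer(names(ring_means))
    centre_mean <- mean(ring_means[r <= pipeline$centre_radius_px - 1L])
    ring <- pipeline$ring_range_px
    peri_mean <- mean(ring_means[r >= ring[1] & r <= ring[2]])
    peri_mean / centre_mean
  }, numeric(1))
}

# expectation of the recorded intensity for true intensity mu under the
# generator's noise chain: Poisson at gain g, Gaussian read noise sd r,
# clipped at zero (detector counts are non-negative). The clip makes the
# expectation slightly super-linear near zero, which matters for the
# near-background periphery of the average images.
expected_recorded_intensity <- function(mu, noise) {
  g <- noise$gain; r <- noise$read_sd
  relu_mean <- function(m) {            # E[max(0, m + r Z)]
    if (r == 0) return(pmax(m, 0))
    m * stats::pnorm(m / r) + r * stats::dnorm(m / r)
  }
  if (g == 0) return(relu_mean(mu))
  kmax <- max(20, ceiling(max(mu) * g + 12 * sqrt(max(mu) * g + 1)))
  out <- numeric(length(mu))
  for (k in 0:kmax)
    out <- out + stats::dpois(k, mu * g) * relu_mean(k / g)
  out
}

#' Fixture of isolated spots for detector benchmarking
#'
#' Renders crops containing a known number of PSF-sized spots at random
#' positions with a minimum pairwise separation, over pure Gaussian read
#' noise, with peak amplitude `snr * read_sd`. Used to measure detection
#' recall and false-positive rate against ground truth.
#'
#' @param n_crops number of crops.
#' @param snr peak amplitude over read-noise sd.
#' @param n_spots_per_crop spots per crop.
#' @param side_px crop side.
#' @param min_sep_px minimum centre-to-centre spot distance.
#' @param config a [synth_config()] (PSF, read noise, seed).
#' @return list with `crops` (matrices) and `truth` (list of position
#'   matrices, columns `row`, `col`).
#' @export
make_detection_fixture <- function(n_crops = 200L, snr = 8,
                                   n_spots_per_crop = 5L, side_px = 64L,
                                   min_sep_px = 8, config = synth_config()) {
  set.seed(config$seed)
  sig <- psf_sigma_px(config$psf_fwhm_nm[["poi"]], config$pixel_size_nm)
  read_sd <- config$noise$read_sd
  if (read_sd <= 0) stop("detection fixture needs read noise > 0")
  peak <- snr * read_sd
  amp <- peak * 2 * pi * sig^2          # integrated intensity giving that peak
  margin <- ceiling(5 * sig) + 2
  crops <- vector("list", n_crops)
  truth <- vector("list", n_crops)
  for (i in seq_len(n_crops)) {
    pos <- matrix(numeric(0), 0, 2)
    guard <- 0L
    while (nrow(pos) < n_spots_per_crop && guard < 10000L) {
      cand <- c(runif(1, margin, side_px - margin),
                runif(1, margin, side_px - margin))
      if (nrow(pos) == 0L ||
          min(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2)) >=
            min_sep_px)
        pos <- rbind(pos, cand)
      guard <- guard + 1L
    }
    img <- render_points(matrix(0, side_px, side_px),
                         cbind(pos[, 1], pos[, 2], amp), sig)
    img <- img + matrix(rnorm(side_px^2, 0, read_sd), side_px, side_px)
    crops[[i]] <- img
    truth[[i]] <- pos
  }
  list(crops = crops, truth = truth)
}

#' Landmarks of a synthetic spine in its crop frame
#'
#' Converts the offset landmark set stored in a [sample_synapse_population()]
#' ground truth into a [spine_landmarks()] object in the coordinate frame
#' of the crop rendered for that synapse (punctum at the central pixel).
#'
#' @param truth a `ground_truth` object.
#' @param i synapse index (row of `truth`); must have a spine class.
#' @param side_px crop side in px (default: the 3 um crop at the
#'   generator's pixel size).
#' @return a [spine_landmarks()].
#' @export
crop_spine_landmarks <- function(truth, i, side_px = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  lmk <- attr(truth, "landmarks")[[i]]
  if (is.null(lmk))
    stop("synapse ", i, " has spine_class 'none': no landmarks")
  config <- attr(truth, "config")
  if (is.null(side_px)) side_px <- crop_side_px(3.0, config$pixel_size_nm)
  centre <- (side_px + 1L) %/% 2L
  args <- lapply(lmk, function(p) centre + p)
  do.call(spine_landmarks,
          c(list(crop_id = truth$synapse_id[i],
                 spine_class = truth$spine_class[i]), args))
}
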