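test_that("config invariants are enforced", {
  expect_error(synth_config(n_synapses = 0), "n_synapses")
  expect_error(synth_config(psf_fwhm_nm = c(poi = 60)), "all roles")
  expect_warning(synth_config(psf_fwhm_nm = c(poi = 10, post_marker = 60,
                                              pre_marker = 60, actin = 250)),
                 "undersampled")
  expect_error(synth_config(spot_model = list(lambda_slope = -1)), "monotone")
  expect_error(synth_config(spot_model = list(sigma0_nm = 0)), "positive")
})

test_that("population sampling honours the latent model", {
  # degenerate rate: zero spots everywhere
  cfg0 <- synth_config(n_synapses = 50,
                       spot_model = list(lambda0 = 0, lambda_slope = 0),
                       seed = 71)
  expect_true(all(sample_synapse_population(cfg0)$poi_spot_count == 0))

  cfg <- synth_config(n_synapses = 200, seed = 72)
  truth <- sample_synapse_population(cfg)
  expect_equal(nrow(truth), 200)
  # independent latents leave the two marker amplitudes uncorrelated
  expect_lt(abs(cor(truth$homer_amp, truth$pre_amp)), 0.2)
  # monotone sigma(A): rank correlation with the latent is exactly 1
  expect_equal(cor(rank(truth$A), rank(truth$poi_spread_nm)), 1)
  # moment recovery of the homer amplitude against the latent model
  lmod <- cfg$latent_model
  mu_target <- lmod$homer_gain *
    exp(lmod$s_meanlog + (lmod$s_sdlog^2 + lmod$amp_sdlog^2) / 2)
  sd_target <- mu_target *
    sqrt(exp(lmod$s_sdlog^2 + lmod$amp_sdlog^2) - 1)
  expect_lt(abs(mean(truth$homer_amp) - mu_target),
            3 * sd_target / sqrt(200))
  # spot offsets stay inside the crop half-side
  spots <- attr(truth, "spots")
  offs <- do.call(rbind, spots[vapply(spots, nrow, integer(1)) > 0])
  expect_true(all(abs(offs[, 1:2]) <= 48))
})

test_that("constant spread reproduces the target offset SD", {
  cfg <- synth_config(n_synapses = 400, seed = 73,
                      spot_model = list(sigma0_nm = 240, sigma_slope_nm = 0),
                      spine_fracs = c(mushroom = 0, stubby = 0, none = 1))
  truth <- sample_synapse_population(cfg)
  offs <- do.call(rbind, attr(truth, "spots"))
  sd_px <- 240 / cfg$pixel_size_nm
  n <- nrow(offs)
  se <- sd_px / sqrt(2 * (n - 1))                # SE of a Gaussian SD estimate
  expect_lt(abs(sd(offs[, "d_row"]) - sd_px), 3 * se)
  expect_lt(abs(sd(offs[, "d_col"]) - sd_px), 3 * se)
})

test_that("rendering is deterministic and conserves point mass", {
  cfg <- synth_config(n_synapses = 8, synapses_per_field = 4,
                      n_experiments = 1, image_size_px = c(256L, 256L),
                      seed = 74)
  truth <- sample_synapse_population(cfg)
  f1 <- render_experiment(truth, cfg)
  f2 <- render_experiment(sample_synapse_population(cfg), cfg)
  expect_identical(f1[[1]]$channels$poi, f2[[1]]$channels$poi)
  expect_identical(f1[[2]]$channels$post_marker, f2[[2]]$channels$post_marker)

  # a single unit point with no noise integrates to its amplitude within 1%
  pt <- stedsynapse:::render_points(matrix(0, 64, 64),
                                    cbind(32.3, 31.6, 1),
                                    psf_sigma_px(60, 30))
  expect_lt(abs(sum(pt) - 1), 0.01)
  # zero spots, zero background, zero noise: an all-zero channel
  cfg0 <- synth_config(n_synapses = 4, synapses_per_field = 4,
                       n_experiments = 1, image_size_px = c(256L, 256L),
                       spot_model = list(lambda0 = 0, lambda_slope = 0),
                       noise = list(gain = 0, read_sd = 0, background = 0),
                       seed = 75)
  t0 <- sample_synapse_population(cfg0)
  img0 <- render_experiment(t0, cfg0)[[1]]
  expect_equal(max(img0$channels$poi), 0)
})

test_that("spread-gradient fixture validates input and labels bins", {
  cfg <- synth_config(seed = 76)
  expect_error(make_spread_gradient_fixture(5, c(150, 250, 350), cfg),
               "length 5")
  expect_error(make_spread_gradient_fixture(5, c(150, 140, 350, 450, 550),
                                            cfg), "increasing")
  expect_warning(fx0 <- make_spread_gradient_fixture(0, c(1, 2, 3, 4, 5) * 100,
                                                     cfg), "empty")
  expect_length(fx0$crops, 0)
  fx <- make_spread_gradient_fixture(3, c(150, 250, 350, 450, 550), cfg)
  expect_length(fx$crops, 15)
  expect_equal(fx$truth$bin, rep(1:5, each = 3))
  expect_true(all(diff(tapply(fx$truth$homer_amp, fx$truth$bin, mean)) > 0))
  # degenerate equal spreads allowed only with strictness off
  fxe <- make_spread_gradient_fixture(2, rep(300, 5), cfg, strict = FALSE)
  expect_equal(unique(fxe$truth$sigma_nm), 300)
})

test_that("equal spreads give statistically indistinguishable bin ratios", {
  cfg <- synth_config(seed = 77)
  fx <- make_spread_gradient_fixture(100, rep(300, 5), cfg, strict = FALSE)
  res <- analyse_crops(fx$crops, pipeline_config())
  # per-bin ratio SE at n = 100 crops/bin is ~0.025 (position sampling);
  # 3-sigma bands on the delta (sd ~0.035) and the 5-bin range
  expect_lt(abs(res$ratio_trend$delta), 0.105)
  expect_lt(diff(range(res$ratio_trend$ratios$ratio)), 0.16)
})
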