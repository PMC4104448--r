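test_that("sliding 2x2 binning quadruples interior counts of a constant image", {
  cfg <- tcspc_config(0.02, 10, 10)
  a <- array(3, dim = c(5, 6, 10))
  stk <- flimfret:::flim_stack(a, cfg, irf_delta(1))
  b <- spatial_bin_2x2(stk)
  expect_equal(dim(b$counts), dim(a))
  expect_true(all(b$counts[1:4, 1:5, ] == 12))  # interior: 4c
  expect_true(all(b$counts[5, 1:5, ] == 6))     # bottom edge: 2c
  expect_true(all(b$counts[1:4, 6, ] == 6))     # right edge: 2c
  expect_true(all(b$counts[5, 6, ] == 3))       # corner: c
})

test_that("a single bright pixel spreads exactly over its 2x2 neighbourhood", {
  cfg <- tcspc_config(0.02, 4, 4)
  a <- array(0, dim = c(6, 6, 4))
  a[4, 4, ] <- 7
  b <- spatial_bin_2x2(flimfret:::flim_stack(a, cfg, irf_delta(1)))
  nz <- which(apply(b$counts, c(1, 2), sum) > 0, arr.ind = TRUE)
  expect_setequal(paste(nz[, 1], nz[, 2]), paste(c(3, 4, 3, 4), c(3, 3, 4, 4)))
  expect_true(all(b$counts[3:4, 3:4, 2] == 7))
})

test_that("block binning conserves photons exactly", {
  cfg <- tcspc_config(0.02, 20, 20)
  set.seed(42)
  a <- array(rpois(8 * 8 * 20, 5), dim = c(8, 8, 20))
  stk <- flimfret:::flim_stack(a, cfg, irf_delta(1))
  b <- spatial_bin_block2(stk)
  expect_equal(dim(b$counts)[1:2], c(4L, 4L))
  expect_equal(sum(b$counts), sum(a))
  # per-block oracle
  expect_equal(b$counts[2, 3, 7], sum(a[3:4, 5:6, 7]))
})

test_that("one-pixel-wide stacks cannot be binned", {
  cfg <- tcspc_config(0.02, 5, 5)
  a <- array(1, dim = c(1, 8, 5))
  stk <- flimfret:::flim_stack(a, cfg, irf_delta(1))
  expect_error(spatial_bin_2x2(stk), "at least 2 pixels")
  expect_error(spatial_bin_block2(stk), "at least 2 pixels")
})

test_that("barycenter of a noiseless exponential matches the truncated closed form", {
  cfg <- cfg_std()
  mu <- model_decay(two_species_params(0, total_intensity = 1e6), cfg,
                    irf_delta(1))
  stk <- uniform_stack(mu, config = cfg)
  lmap <- mean_lifetime_map(stk)
  # truncated-exponential mean: tau - T exp(-T/tau)/(1 - exp(-T/tau))
  T_win <- cfg$analysis_channels * cfg$channel_width
  oracle <- 2.65 - T_win * exp(-T_win / 2.65) / (1 - exp(-T_win / 2.65))
  expect_lt(abs(lmap$tau_mean[1, 1] / oracle - 1), 0.005)
})

test_that("degenerate decay shapes give the textbook barycenters", {
  cfg <- tcspc_config(0.02, 100, 100)
  # all photons in one channel at time t0
  d <- numeric(100); d[40] <- 500
  stk <- uniform_stack(d, config = cfg)
  lmap <- mean_lifetime_map(stk, origin_channel = 1)
  expect_equal(lmap$tau_mean[1, 1], (40 - 0.5) * 0.02)
  # uniform counts over the window: T/2 within half a channel
  stku <- uniform_stack(rep(10, 100), config = cfg)
  lmapu <- mean_lifetime_map(stku, origin_channel = 1)
  expect_lt(abs(lmapu$tau_mean[1, 1] - 1), 0.011)
})

test_that("pixels under the photon threshold are masked, not errored", {
  cfg <- tcspc_config(0.02, 50, 50)
  a <- array(0, dim = c(2, 2, 50))
  a[1, 1, ] <- 10  # 500 photons
  a[2, 2, 5] <- 30 # 30 photons: below threshold
  stk <- flimfret:::flim_stack(a, cfg, irf_delta(1))
  lmap <- mean_lifetime_map(stk, photon_threshold = 150)
  expect_true(lmap$valid_mask[1, 1])
  expect_false(lmap$valid_mask[2, 2])
  expect_false(lmap$valid_mask[1, 2])  # all-zero pixel: masked
  expect_true(is.na(lmap$tau_mean[2, 2]))
  expect_true(is.na(lmap$tau_mean[1, 2]))
})

test_that("fraction estimators agree at the endpoints and on hand-computed values", {
  tau_D <- 2.65; tau_F <- 0.83
  lm_ends <- make_lifetime_map(matrix(c(tau_D, tau_F), 1))
  for (est in c("linear", "intensity-weighted-inversion")) {
    fm <- fraction_map(lm_ends, tau_D, tau_F, estimator = est)
    expect_equal(fm$f_D[1, 1], 0)
    expect_equal(fm$f_D[1, 2], 1)
  }
  lm252 <- make_lifetime_map(matrix(2.52))
  lin <- fraction_map(lm252, tau_D, tau_F, "linear")$f_D[1, 1]
  inv <- fraction_map(lm252, tau_D, tau_F, "intensity-weighted-inversion")$f_D[1, 1]
  expect_equal(lin, (2.65 - 2.52) / (2.65 - 0.83))
  expect_equal(round(lin, 4), 0.0714)
  expect_equal(inv, 2.65 * (2.65 - 2.52) / ((2.65 - 0.83) * (2.65 + 0.83 - 2.52)))
  expect_equal(round(inv, 3), 0.197)
})

test_that("both fraction estimators are strictly decreasing in the mean lifetime", {
  taus <- seq(0.84, 2.64, length.out = 40)
  lm <- make_lifetime_map(matrix(taus, 1))
  for (est in c("linear", "intensity-weighted-inversion")) {
    f <- fraction_map(lm, estimator = est)$f_D[1, ]
    expect_true(all(diff(f) < 0))
  }
})

test_that("out-of-range lifetimes are clipped and flagged, masked pixels stay NA", {
  lm <- make_lifetime_map(matrix(c(2.9, 0.5, 1.5, NA), 2))
  fm <- fraction_map(lm)
  expect_equal(fm$f_D[1, 1], 0) # tau above tau_D clips to 0
  expect_equal(fm$f_D[2, 1], 1) # tau below tau_F clips to 1
  expect_true(fm$out_of_range[1, 1])
  expect_true(fm$out_of_range[2, 1])
  expect_false(fm$out_of_range[1, 2])
  expect_true(is.na(fm$f_D[2, 2]))
  expect_error(fraction_map(lm, tau_D = 0.8, tau_F = 0.83), "tau_F < tau_D")
})

test_that("the inversion estimator recovers the truth fraction on noiseless stacks", {
  cfg <- cfg_std()
  fvals <- c(0.05, 0.17, 0.28, 0.5)
  mus <- sapply(fvals, function(f) {
    model_decay(two_species_params(f, total_intensity = 1e6), cfg, irf_delta(1))
  })
  a <- array(t(mus)[rep(1:4, 1), ], dim = c(4, 1, cfg$n_channels))
  stk <- flimfret:::flim_stack(a, cfg, irf_delta(1))
  lmap <- mean_lifetime_map(stk)
  inv <- fraction_map(lmap, estimator = "intensity-weighted-inversion")$f_D[, 1]
  lin <- fraction_map(lmap, estimator = "linear")$f_D[, 1]
  expect_lt(max(abs(inv - fvals)), 0.01)
  # linear estimator applied to a barycenter lifetime underestimates
  expect_true(all(fvals - lin >= 0))
})

test_that("the decay origin lands on the flash", {
  cfg <- cfg_std()
  expect_identical(decay_origin(rep(1, 10), irf_delta(9), cfg), 9L)
  expect_identical(decay_origin(rep(1, 10), irf_gaussian(0.5, 0.1), cfg), 25L)
  # from counts alone the origin falls on the count peak, which for a
  # 100 ps-fwhm flash sits a few channels after the IRF peak (the signal
  # keeps rising while the flash still delivers); noisy estimates stay
  # within 2 channels of the noiseless count peak
  p <- two_species_params(0, total_intensity = 1e6)
  mu <- model_decay(p, cfg, irf_std())
  peak0 <- which.max(mu)
  expect_gt(peak0, 25L)
  expect_lte(peak0, 35L)
  hits <- vapply(1:30, function(s) {
    d <- simulate_decay(p, cfg, irf_std(), seed = 3100 + s)
    abs(decay_origin(d) - peak0) <= 2L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the barycenter is robust at ~100 photons per pixel", {
  # pixels that pass a 100-photon mask (as the pipeline applies) have a
  # mean-lifetime spread below 10% of its value
  cfg <- cfg_std()
  p <- two_species_params(0, total_intensity = 100)
  taus <- vapply(1:300, function(s) {
    d <- simulate_decay(p, cfg, irf_std(), seed = 4000 + s)
    if (sum(d) < 100) return(NA_real_)
    stk <- flimfret:::flim_stack(array(d, c(1, 1, cfg$n_channels)), cfg,
                                 irf_std())
    mean_lifetime_map(stk, photon_threshold = 100)$tau_mean[1, 1]
  }, numeric(1))
  expect_gt(sum(!is.na(taus)), 100)
  expect_lt(stats::sd(taus, na.rm = TRUE) / mean(taus, na.rm = TRUE), 0.10)
})
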