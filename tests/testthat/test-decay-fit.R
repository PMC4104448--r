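test_that("noiseless single-exponential decays are recovered to < 0.1%", {
  cfg <- cfg_std()
  for (irf in list(irf_delta(1), irf_std())) {
    mu <- model_decay(two_species_params(0, total_intensity = 5000), cfg, irf)
    fit <- fit_one_exp(mu, cfg, irf)
    expect_true(fit$converged)
    expect_lt(abs(fit$estimates[["tau"]] / 2.65 - 1), 0.001)
    expect_lt(abs(fit$estimates[["total_intensity"]] / 5000 - 1), 0.01)
  }
})

test_that("low-signal decays raise an explicit error", {
  cfg <- cfg_std()
  d <- simulate_decay(two_species_params(0, total_intensity = 50), cfg,
                      irf_std(), seed = 1)
  expect_lt(sum(d), 150)
  expect_error(fit_one_exp(d, cfg, irf_std()), class = "flimfret_low_signal")
  expect_error(
    fit_two_species(d, cfg, irf_std(),
                    fit_spec("two-species", fixed = list(tau_D = 2.65))),
    class = "flimfret_low_signal"
  )
  # threshold is configurable
  expect_s3_class(
    fit_one_exp(d, cfg, irf_std(), fit_spec("one-exp", photon_threshold = 10)),
    "flim_fit"
  )
})

test_that("a simulated high-photon donor decay is recovered within 1%", {
  cfg <- cfg_std()
  d <- simulate_decay(two_species_params(0, total_intensity = 1e5), cfg,
                      irf_std(), seed = 1)
  fit <- fit_one_exp(d, cfg, irf_std(),
                     fit_spec("one-exp", objective = "poisson-mle"))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["tau"]] / 2.65 - 1), 0.01)
})

test_that("Neyman-weighted least squares shows its known low-count lifetime bias", {
  # with most channels holding < 10 counts the 1/max(c,1) weights pull the
  # lifetime down relative to the Poisson likelihood; this is documented
  # behaviour, and the reason low-count analyses use poisson-mle
  cfg <- cfg_std()
  d <- simulate_decay(two_species_params(0, total_intensity = 1e5), cfg,
                      irf_std(), seed = 1)
  wls <- fit_one_exp(d, cfg, irf_std())
  mle <- fit_one_exp(d, cfg, irf_std(),
                     fit_spec("one-exp", objective = "poisson-mle"))
  expect_lt(wls$estimates[["tau"]], mle$estimates[["tau"]])
})

test_that("noiseless two-species decays are recovered across the parameter grid", {
  cfg <- cfg_std()
  irf <- irf_std()
  spec <- fit_spec("two-species", fixed = list(tau_D = 2.65))
  for (f in seq(0, 1, by = 0.1)) {
    mu <- model_decay(two_species_params(f, total_intensity = 5000), cfg, irf)
    fit <- suppressWarnings(fit_two_species(mu, cfg, irf, spec))
    expect_true(fit$converged)
    expect_lt(abs(fit$estimates[["f_D"]] - f), 1e-3)
    if (f >= 0.1 && f <= 0.9) {
      expect_lt(abs(fit$estimates[["tau_F"]] - 0.83), 1e-2)
    }
  }
  for (tau_F in c(0.5, 0.83, 1.2)) {
    mu <- model_decay(two_species_params(0.3, tau_F = tau_F,
                                         total_intensity = 5000), cfg, irf)
    fit <- fit_two_species(mu, cfg, irf, spec)
    expect_lt(abs(fit$estimates[["f_D"]] - 0.3), 1e-3)
    expect_lt(abs(fit$estimates[["tau_F"]] - tau_F), 1e-2)
  }
})

test_that("donor-only decays fitted with the two-species model stay near zero", {
  cfg <- cfg_std()
  irf <- irf_std()
  spec <- fit_spec("two-species", fixed = list(tau_D = 2.65, tau_F = 0.83),
                   objective = "poisson-mle")
  p <- two_species_params(0, total_intensity = 600)
  fhat <- vapply(seq_len(40), function(s) {
    d <- simulate_decay(p, cfg, irf, seed = 500 + s)
    fit_two_species(d, cfg, irf, spec)$estimates[["f_D"]]
  }, numeric(1))
  expect_lte(stats::median(fhat), 0.05)
  expect_true(all(fhat >= 0 & fhat <= 1))
})

test_that("interacting-fraction estimates are calibrated at realistic photon counts", {
  cfg <- cfg_std()
  irf <- irf_std()
  spec <- fit_spec("two-species", fixed = list(tau_D = 2.65, tau_F = 0.83),
                   objective = "poisson-mle")
  p <- two_species_params(0.17, total_intensity = 600)
  fits <- lapply(seq_len(60), function(s) {
    fit_two_species(simulate_decay(p, cfg, irf, seed = 800 + s), cfg, irf, spec)
  })
  fhat <- vapply(fits, function(f) f$estimates[["f_D"]], numeric(1))
  sehat <- vapply(fits, function(f) f$standard_errors[["f_D"]], numeric(1))
  expect_lt(abs(mean(fhat) - 0.17), 0.04)
  # reported standard errors agree with the replicate spread within 2x
  ratio <- mean(sehat, na.rm = TRUE) / stats::sd(fhat)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("the least-squares objective never increases across accepted iterations", {
  cfg <- cfg_std()
  d <- simulate_decay(two_species_params(0.3, total_intensity = 2000), cfg,
                      irf_std(), seed = 77)
  fit <- fit_two_species(d, cfg, irf_std(),
                         fit_spec("two-species", fixed = list(tau_D = 2.65)))
  expect_gt(length(fit$objective_trace), 1)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
})

test_that("the IRF is genuinely used: mismatched IRF biases the lifetime", {
  cfg <- cfg_std()
  # data generated with a delta flash, fitted assuming a wide late IRF
  mu <- model_decay(two_species_params(0, total_intensity = 2e4), cfg,
                    irf_delta(1))
  wrong <- fit_one_exp(mu, cfg, irf_gaussian(center = 0.5, fwhm = 0.5))
  right <- fit_one_exp(mu, cfg, irf_delta(1))
  expect_lt(abs(right$estimates[["tau"]] / 2.65 - 1), 0.001)
  expect_gt(abs(wrong$estimates[["tau"]] / 2.65 - 1), 0.005)
})

test_that("a FRET lifetime collapsing onto the donor lifetime is flagged", {
  cfg <- cfg_std()
  mu <- model_decay(two_species_params(0.3, tau_F = 2.6, tau_D = 2.65,
                                       total_intensity = 5000), cfg, irf_std())
  expect_warning(
    fit <- fit_two_species(mu, cfg, irf_std(),
                           fit_spec("two-species", fixed = list(tau_D = 2.65))),
    "identifiable"
  )
  expect_true("tau_F-collapsed-onto-tau_D" %in% fit$flags)
})

test_that("two-species fitting requires the fixed donor lifetime", {
  cfg <- cfg_std()
  d <- simulate_decay(two_species_params(0.2, total_intensity = 1000), cfg,
                      irf_std(), seed = 2)
  expect_error(fit_two_species(d, cfg, irf_std(), fit_spec("two-species")),
               "tau_D")
})

test_that("closed-form mean lifetimes match hand evaluation", {
  # amplitude-weighted: linear interpolation between the species lifetimes
  expect_equal(amplitude_mean_lifetime(two_species_params(0)), 2.65)
  expect_equal(amplitude_mean_lifetime(two_species_params(1)), 0.83)
  expect_equal(amplitude_mean_lifetime(two_species_params(0.0714)),
               0.0714 * 0.83 + (1 - 0.0714) * 2.65)
  expect_equal(round(amplitude_mean_lifetime(two_species_params(0.0714)), 3),
               2.520)
  # intensity-weighted: photon-weighted, always at or above the amplitude mean
  expect_equal(intensity_mean_lifetime(two_species_params(0)), 2.65)
  expect_equal(intensity_mean_lifetime(two_species_params(1)), 0.83)
  expect_equal(round(intensity_mean_lifetime(two_species_params(0.28)), 3),
               2.452)
  for (f in seq(0.1, 0.9, by = 0.2)) {
    p <- two_species_params(f)
    expect_gt(intensity_mean_lifetime(p), amplitude_mean_lifetime(p))
  }
})
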