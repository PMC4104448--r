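test_that("cell summaries average only valid ROI pixels", {
  lm <- make_lifetime_map(matrix(2.5, 4, 4))
  fm <- fraction_map(lm)
  roi <- matrix(TRUE, 4, 4)
  s <- summarize_cell(lm, fraction_map(make_lifetime_map(matrix(2.195, 4, 4))),
                      roi, cell_id = "u")
  expect_equal(s$mean_f_D, (2.65 - 2.195) / (2.65 - 0.83))
  expect_equal(s$n_valid_pixels, 16)

  # half the pixels masked: mean over the remaining half only
  tau <- matrix(2.65, 4, 4); tau[, 3:4] <- NA
  tau[, 1:2] <- 2.1
  lm2 <- make_lifetime_map(tau)
  fm2 <- fraction_map(lm2)
  s2 <- summarize_cell(lm2, fm2, roi, cell_id = "half")
  expect_equal(s2$n_valid_pixels, 8)
  expect_equal(s2$mean_tau, 2.1)

  # empty intersection names the cell
  expect_error(summarize_cell(lm2, fm2, matrix(FALSE, 4, 4), cell_id = "c9"),
               "c9")
})

test_that("intensity ratio is present only when an acceptor image is given", {
  lm <- make_lifetime_map(matrix(2.4, 3, 3), photons = 200)
  fm <- fraction_map(lm)
  roi <- matrix(TRUE, 3, 3)
  s <- summarize_cell(lm, fm, roi)
  expect_true(is.na(s$intensity_ratio))
  acc <- matrix(100, 3, 3)
  s2 <- summarize_cell(lm, fm, roi, acceptor_image = acc)
  expect_equal(s2$intensity_ratio, (200 * 9) / (100 * 9))
})

test_that("summaries of a synthetic scene track its truth map", {
  cfg <- cfg_std()
  sc <- scene_preset("coexpression", image_shape = c(24, 24), seed = 31)
  stk <- simulate_flim_image(sc, two_species_params(0), cfg, irf_std(),
                             seed = 31)
  res <- analyze_flim_stack(stk, estimator = "intensity-weighted-inversion",
                            cell_id = "truth-check")
  truth_mean <- mean(spatial_bin_2x2(stk)$truth$f_D[sc$cell_mask], na.rm = TRUE)
  expect_lt(abs(res$summary$mean_f_D - truth_mean), 0.03)
})

test_that("pooled-variance t-test matches a hand-coded oracle", {
  pooled_t <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    p <- 2 * stats::pt(-abs(t), nx + ny - 2)
    c(t = t, p = p)
  }
  # fixed case resembling per-cell lifetimes
  a <- c(2.60, 2.64, 2.68, 2.66)
  b <- c(2.48, 2.52, 2.55, 2.53)
  cmp <- compare_groups(a, b)
  oracle <- pooled_t(a, b)
  expect_equal(cmp$t_statistic, unname(oracle["t"]), tolerance = 1e-12)
  expect_equal(cmp$p_value, unname(oracle["p"]), tolerance = 1e-12)
  # property: random small samples
  set.seed(14)
  for (i in 1:100) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), mean = runif(1))
    cmpi <- compare_groups(x, y)
    oi <- pooled_t(x, y)
    expect_equal(cmpi$t_statistic, unname(oi["t"]), tolerance = 1e-10)
    expect_equal(cmpi$p_value, unname(oi["p"]), tolerance = 1e-10)
  }
})

test_that("identical distributions give t = 0, p = 1; degenerate input errors", {
  cmp <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_error(compare_groups(c(1, 1), c(1, 1)), "identical")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
  # welch variant differs from student under unequal variances
  x <- c(1, 2, 3, 4); y <- c(10, 30, 50, 70, 90)
  expect_false(isTRUE(all.equal(compare_groups(x, y, "student")$p_value,
                                compare_groups(x, y, "welch")$p_value)))
})

test_that("perfect monotone dependence yields rho = 1 and the minimal p", {
  s <- data.frame(mean_f_D = (1:8) / 10, intensity_ratio = 2^(1:8))
  chk <- independence_check(s, n_perm = 999, seed = 3)
  expect_equal(chk$rho, 1)
  expect_equal(chk$p_value, 1 / 1000)
})

test_that("independence holds under the null and p-values are reproducible", {
  set.seed(77)
  s <- data.frame(mean_f_D = rnorm(20, 0.2, 0.03),
                  intensity_ratio = runif(20, 0.5, 2))
  a <- independence_check(s, n_perm = 999, seed = 5)
  b <- independence_check(s, n_perm = 999, seed = 5)
  expect_identical(a$p_value, b$p_value)
  expect_gte(a$p_value, 1 / 1000)
  expect_lte(a$p_value, 1)
  # under the null, p is roughly uniform: its mean over replicates sits
  # near 0.5
  ps <- vapply(1:20, function(i) {
    si <- data.frame(
      mean_f_D = flimfret:::with_seed(100 + i, rnorm(12, 0.2, 0.05)),
      intensity_ratio = flimfret:::with_seed(200 + i, runif(12, 0.5, 2))
    )
    independence_check(si, n_perm = 499, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("degenerate and incomplete summaries are handled explicitly", {
  s <- data.frame(mean_f_D = rep(0.2, 6), intensity_ratio = runif(6))
  chk <- independence_check(s, n_perm = 99, seed = 1)
  expect_false(chk$assessable)
  expect_true(is.na(chk$rho))
  # missing ratios are excluded with a message
  s2 <- data.frame(mean_f_D = (1:7) / 10,
                   intensity_ratio = c(1, 2, 3, NA, 5, 6, 7))
  expect_message(chk2 <- independence_check(s2, n_perm = 99, seed = 1),
                 "excluding 1")
  expect_equal(chk2$n_used, 6)
  expect_error(independence_check(data.frame(mean_f_D = 1:3,
                                             intensity_ratio = 1:3)),
               "at least 5")
})
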