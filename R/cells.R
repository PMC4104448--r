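# Per-cell aggregation and population-level statistics.

#' Summarize one cell ROI
#'
#' Aggregates a mean-lifetime map and an interacting-fraction map over a
#' whole-cell region of interest: unweighted means over the pixels that are
#' both inside the ROI and above the photon threshold (photon-weighted
#' means are available via `weighted = TRUE`). Donor intensity defaults to
#' the photon totals of the lifetime map; an acceptor intensity image, when
#' supplied, yields the donor/acceptor intensity ratio used by the
#' expression-level independence check.
#'
#' @param lmap A [mean_lifetime_map()] result.
#' @param fmap A [fraction_map()] result on the same grid.
#' @param roi_mask Logical matrix selecting the cell's pixels.
#' @param donor_image Optional donor-intensity matrix (defaults to
#'   `lmap$photon_count`).
#' @param acceptor_image Optional acceptor-intensity matrix.
#' @param cell_id Identifier carried into the summary.
#' @param weighted If `TRUE`, photon-weight the per-pixel means.
#' @return A one-row data frame of class `cell_summary` with columns
#'   `cell_id`, `mean_tau`, `mean_f_D`, `donor_intensity`,
#'   `acceptor_intensity`, `intensity_ratio`, `n_valid_pixels`.
#' @export
summarize_cell <- function(lmap, fmap, roi_mask, donor_image = NULL,
                           acceptor_image = NULL, cell_id = "cell",
                           weighted = FALSE) {
  stopifnot(inherits(lmap, "lifetime_map"), inherits(fmap, "fraction_map"))
  if (!is.logical(roi_mask) || !all(dim(roi_mask) == dim(lmap$tau_mean))) {
    stop("`roi_mask` must be a logical matrix matching the map")
  }
  sel <- roi_mask & lmap$valid_mask & fmap$valid_mask
  if (!any(sel)) {
    stop(sprintf("cell '%s': ROI contains no valid pixels", cell_id))
  }
  if (is.null(donor_image)) donor_image <- lmap$photon_count
  w <- if (weighted) lmap$photon_count[sel] else rep(1, sum(sel))
  mean_tau <- sum(lmap$tau_mean[sel] * w) / sum(w)
  mean_f_D <- sum(fmap$f_D[sel] * w) / sum(w)
  donor_total <- sum(donor_image[roi_mask])
  acceptor_total <- if (is.null(acceptor_image)) NA_real_ else
    sum(acceptor_image[roi_mask])
  out <- data.frame(
    cell_id = cell_id,
    mean_tau = mean_tau,
    mean_f_D = mean_f_D,
    donor_intensity = donor_total,
    acceptor_intensity = acceptor_total,
    intensity_ratio = donor_total / acceptor_total,
    n_valid_pixels = sum(sel),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_summary", class(out))
  out
}

#' Two-sample comparison of per-cell statistics
#'
#' Two-sided two-sample t-test between per-cell values (e.g. mean lifetimes
#' or mean interacting fractions of two expression conditions). The default
#' `"student"` variant uses the classical pooled-variance statistic; the
#' `"welch"` variant drops the equal-variance assumption.
#'
#' @param groupA,groupB Numeric vectors of per-cell values (>= 2 finite
#'   values each, not all identical).
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @param labels Length-2 character vector naming the groups.
#' @return An object of class `group_comparison` with per-group mean, sd
#'   and n, the t statistic, degrees of freedom and two-sided p-value.
#' @examples
#' compare_groups(c(2.60, 2.64, 2.68, 2.66), c(2.48, 2.52, 2.55, 2.53))
#' @export
compare_groups <- function(groupA, groupB, variant = c("student", "welch"),
                           labels = c("A", "B")) {
  variant <- match.arg(variant)
  groupA <- groupA[is.finite(groupA)]
  groupB <- groupB[is.finite(groupB)]
  if (length(groupA) < 2L || length(groupB) < 2L) {
    stop("each group needs at least 2 finite values")
  }
  if (stats::sd(c(groupA, groupB)) == 0) {
    stop("degenerate input: all values identical, no variance to test against")
  }
  tt <- stats::t.test(groupA, groupB, var.equal = (variant == "student"))
  structure(list(
    labels = labels,
    mean = c(mean(groupA), mean(groupB)),
    sd = c(stats::sd(groupA), stats::sd(groupB)),
    n = c(length(groupA), length(groupB)),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    test_variant = variant
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4g (df = %.4g), p = %.3g\n",
              x$test_variant, x$t_statistic, x$df, x$p_value))
  for (i in 1:2) {
    cat(sprintf("  %s: mean %.4g, sd %.4g, n = %d\n",
                x$labels[i], x$mean[i], x$sd[i], x$n[i]))
  }
  invisible(x)
}

#' Independence of the interacting fraction from expression level
#'
#' Tests whether per-cell interacting fractions depend on the
#' donor/acceptor intensity ratio — they should not if the measured
#' fraction reflects the interaction rather than acceptor abundance.
#' A scatter of f_D against the intensity ratio with no trend is the
#' qualitative claim; here it is operationalized as the Spearman rank
#' correlation with a two-sided permutation p-value (f_D values permuted
#' against the ratios, seeded and reproducible).
#'
#' @param summaries A data frame of per-cell summaries (rows of
#'   [summarize_cell()], e.g. via `rbind`) with columns `mean_f_D` and
#'   `intensity_ratio`.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Seed for the permutations.
#' @return A list of class `independence_check` with `rho`, `p_value`,
#'   `n_used`, `n_excluded` and `assessable`; when either variable is
#'   constant the correlation is undefined and `assessable` is `FALSE`.
#' @export
independence_check <- function(summaries, n_perm = 9999L, seed = 1L) {
  if (!all(c("mean_f_D", "intensity_ratio") %in% names(summaries))) {
    stop("`summaries` needs columns `mean_f_D` and `intensity_ratio`")
  }
  ok <- is.finite(summaries$mean_f_D) & is.finite(summaries$intensity_ratio)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(sprintf("independence_check: excluding %d cell(s) without intensity ratios",
                    n_excluded))
  }
  f <- summaries$mean_f_D[ok]
  r <- summaries$intensity_ratio[ok]
  if (length(f) < 5L) stop("need at least 5 cells with intensity ratios")
  if (stats::sd(f) == 0 || stats::sd(r) == 0) {
    return(structure(list(rho = NA_real_, p_value = NA_real_,
                          n_used = length(f), n_excluded = n_excluded,
                          n_perm = n_perm, assessable = FALSE),
                     class = "independence_check"))
  }
  rho <- stats::cor(r, f, method = "spearman")
  perm_rho <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stats::cor(r, sample(f), method = "spearman")
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm_rho) >= abs(rho) - 1e-12)) / (n_perm + 1)
  structure(list(rho = rho, p_value = p, n_used = length(f),
                 n_excluded = n_excluded, n_perm = n_perm, assessable = TRUE),
            class = "independence_check")
}

#' @export
print.independence_check <- function(x, ...) {
  if (!x$assessable) {
    cat("f_D vs intensity ratio: not assessable (constant values)\n")
  } else {
    cat(sprintf(
      "f_D vs intensity ratio: Spearman rho = %.3f, permutation p = %.4g (%d cells, %d permutations)\n",
      x$rho, x$p_value, x$n_used, x$n_perm
    ))
  }
  invisible(x)
}
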