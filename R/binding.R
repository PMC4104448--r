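# Equilibrium one-site saturation binding analysis (SPR).

#' Concentration–response series
#'
#' Container for an equilibrium surface-plasmon-resonance series: analyte
#' concentrations (µM) against steady-state responses (resonance units),
#' optionally tagged with a condition label (e.g. a competing sugar in the
#' running buffer). Rows are sorted by concentration.
#'
#' @param concentrations Non-negative analyte concentrations, µM.
#' @param responses Responses, RU; same length as `concentrations`.
#' @param condition_label Free-text condition tag.
#' @return A data frame of class `binding_series`.
#' @export
binding_series <- function(concentrations, responses,
                           condition_label = "") {
  if (length(concentrations) != length(responses)) {
    stop("`concentrations` and `responses` must have the same length")
  }
  if (any(!is.finite(concentrations)) || any(!is.finite(responses))) {
    stop("concentrations and responses must be finite")
  }
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  o <- order(concentrations)
  out <- data.frame(concentration = concentrations[o],
                    response = responses[o],
                    condition = condition_label,
                    stringsAsFactors = FALSE)
  class(out) <- c("binding_series", class(out))
  out
}

#' One-site saturation binding model
#'
#' The rectangular hyperbola `R = rmax * C / (kd + C)`: zero response at
#' zero concentration, half-maximal response at `C = kd`, saturating at
#' `rmax`.
#'
#' @param concentration Analyte concentration(s), >= 0.
#' @param kd Dissociation constant, > 0 (same units as `concentration`).
#' @param rmax Maximal response, response units.
#' @return Response(s).
#' @examples
#' one_site_model(2.2, kd = 2.2, rmax = 100) # 50
#' @export
one_site_model <- function(concentration, kd, rmax) {
  if (any(concentration < 0)) stop("`concentration` must be >= 0")
  if (any(kd <= 0)) stop("`kd` must be > 0")
  rmax * concentration / (kd + concentration)
}

#' Fit the one-site saturation binding model
#'
#' Nonlinear least-squares (Levenberg–Marquardt) fit of
#' `R = rmax * C / (kd + C)` to a [binding_series()], with deterministic
#' initialization: `kd` starts at the concentration nearest the
#' half-maximal response and `rmax` at the maximal response. Standard
#' errors come from the local curvature; R² is computed against the mean
#' response. Diagnostics flag series that sample fewer than 4 distinct
#' concentrations, do not straddle the fitted `kd`, place `kd` more than
#' 10x outside the sampled range, or fail to converge (e.g. a flat,
#' non-binding series) — the latter return `converged = FALSE` with `NA`
#' estimates rather than an error.
#'
#' @param series A [binding_series()].
#' @return An object of class `binding_fit` with fields `kd`, `rmax`,
#'   `standard_errors`, `r_squared`, `converged`, `flags`, `series`.
#' @examples
#' s <- simulate_binding_series(2.2, 100, c(0.1, 0.3, 1, 3, 10, 30))
#' fit_one_site(s)
#' @export
fit_one_site <- function(series) {
  stopifnot(inherits(series, "binding_series"))
  C <- series$concentration
  R <- series$response
  flags <- character(0)
  if (length(unique(C)) < 4L) {
    flags <- c(flags, "fewer-than-4-distinct-concentrations")
    warning("fewer than 4 distinct concentrations; Kd is weakly constrained",
            call. = FALSE)
  }
  rmax0 <- max(R)
  kd0 <- if (rmax0 > 0) C[which.min(abs(R - rmax0 / 2))] else stats::median(C)
  kd0 <- max(kd0, min(C[C > 0], na.rm = TRUE) / 10, .Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ rmax * concentration / (kd + concentration),
      data = series,
      start = list(kd = kd0, rmax = max(rmax0, .Machine$double.eps)),
      lower = c(kd = .Machine$double.eps, rmax = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, rmax = NA_real_,
                          standard_errors = c(kd = NA_real_, rmax = NA_real_),
                          r_squared = NA_real_, converged = FALSE,
                          flags = c(flags, "non-convergence"),
                          series = series),
                     class = "binding_fit"))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kd = NA_real_, rmax = NA_real_))
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((R - mean(R))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  pos <- C[C > 0]
  if (length(pos) && (est[["kd"]] > 10 * max(pos) || est[["kd"]] < min(pos) / 10)) {
    flags <- c(flags, "kd-outside-sampled-range")
  }
  if (length(pos) && (min(pos) > est[["kd"]] || max(pos) < est[["kd"]])) {
    flags <- c(flags, "concentrations-do-not-straddle-kd")
  }
  structure(list(kd = unname(est["kd"]), rmax = unname(est["rmax"]),
                 standard_errors = se, r_squared = r2, converged = TRUE,
                 flags = flags, series = series),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat("One-site binding fit: NOT CONVERGED (flags:",
        paste(x$flags, collapse = ", "), ")\n")
    return(invisible(x))
  }
  cat(sprintf("One-site binding fit: Kd = %.3g +/- %.2g uM, Rmax = %.3g +/- %.2g RU, R^2 = %.4f\n",
              x$kd, x$standard_errors[["kd"]], x$rmax,
              x$standard_errors[["rmax"]], x$r_squared))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Detectability call for a binding series
#'
#' Classifies a series as `"binding"` or `"not-detectable"`. A series is
#' not detectable when the saturation fit fails, when the fitted response
#' is statistically indistinguishable from zero — assessed by the F-test of
#' the two-parameter one-site model against the zero-response model at
#' level `alpha` — or when the maximal response stays below an optional
#' absolute `threshold`. This mirrors the qualitative ND calls made for
#' deglycosylated or M6P-competed conditions.
#'
#' @param series A [binding_series()].
#' @param threshold Optional absolute response threshold (RU).
#' @param alpha Significance level of the model-vs-zero F-test (default
#'   0.05).
#' @return `"binding"` or `"not-detectable"`, with the underlying
#'   `binding_fit` attached as attribute `fit`.
#' @export
detectability_call <- function(series, threshold = NULL, alpha = 0.05) {
  stopifnot(inherits(series, "binding_series"))
  fit <- fit_one_site(series)
  n <- nrow(series)
  rss0 <- sum(series$response^2)
  call <- "binding"
  if (!fit$converged || rss0 <= 0) {
    call <- "not-detectable"
  } else {
    rss1 <- sum((series$response -
                   one_site_model(series$concentration, fit$kd, fit$rmax))^2)
    if (rss1 > 0) {
      Fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 2))
      p <- stats::pf(Fstat, 2, n - 2, lower.tail = FALSE)
      if (!is.finite(p) || p >= alpha) call <- "not-detectable"
    }
  }
  if (call == "binding" && !is.null(threshold) &&
      max(series$response) < threshold) {
    call <- "not-detectable"
  }
  structure(call, fit = fit)
}
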