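#' TCSPC time-base configuration
#'
#' Describes the time axis shared by the simulator, the decay fitters and the
#' pixel-wise maps: channel width, number of channels per excitation period,
#' and the leading analysis window used for fitting and mean-lifetime
#' estimation. The defaults correspond to 20 ps channels over one 25 ns
#' period of a 40 MHz pulsed laser, with the first 1200 channels analysed.
#'
#' All times in this package are expressed in nanoseconds.
#'
#' @param channel_width Width of one TCSPC channel in ns (default 0.02, i.e.
#'   20 ps).
#' @param n_channels Number of channels spanning one repetition period
#'   (default 1250; `channel_width * n_channels` is the repetition period,
#'   25 ns at the defaults).
#' @param analysis_channels Number of leading channels used by the fitters
#'   and the barycenter mean lifetime (default 1200, a 24 ns window).
#'
#' @return An object of class `tcspc_config` with fields `channel_width`,
#'   `n_channels`, `analysis_channels` and the derived `repetition_period`.
#' @examples
#' cfg <- tcspc_config()
#' cfg$repetition_period # 25 ns
#' @export
tcspc_config <- function(channel_width = 0.02, n_channels = 1250L,
                         analysis_channels = 1200L) {
  if (!is.numeric(channel_width) || length(channel_width) != 1L ||
      !is.finite(channel_width) || channel_width <= 0) {
    stop("`channel_width` must be a single positive number (ns)")
  }
  n_channels <- as.integer(n_channels)
  analysis_channels <- as.integer(analysis_channels)
  if (is.na(n_channels) || n_channels < 2L) {
    stop("`n_channels` must be an integer >= 2")
  }
  if (is.na(analysis_channels) || analysis_channels < 1L ||
      analysis_channels > n_channels) {
    stop("`analysis_channels` must lie in [1, n_channels]")
  }
  structure(
    list(
      channel_width = channel_width,
      n_channels = n_channels,
      analysis_channels = analysis_channels,
      repetition_period = channel_width * n_channels
    ),
    class = "tcspc_config"
  )
}

#' @export
print.tcspc_config <- function(x, ...) {
  cat(sprintf(
    "TCSPC config: %d channels x %g ns (period %g ns), analysis window %d channels (%g ns)\n",
    x$n_channels, x$channel_width, x$repetition_period,
    x$analysis_channels, x$analysis_channels * x$channel_width
  ))
  invisible(x)
}

# Channel midpoint times (ns), measured from the start of the window.
channel_times <- function(config) {
  (seq_len(config$n_channels) - 0.5) * config$channel_width
}

# Channel edge times (ns), length n_channels + 1.
channel_edges <- function(config) {
  (0:config$n_channels) * config$channel_width
}

#' Instrument response function specifications
#'
#' The instrument response function (IRF) is the detection system's response
#' to an instantaneous flash; model decays are convolved with it before
#' comparison with data (iterative reconvolution). Two forms are supported:
#' a parametric Gaussian (the default used by the simulator: fwhm 100 ps,
#' centred 0.5 ns into the window) and a tabulated per-channel histogram as
#' measured on a real instrument. `irf_delta()` is a convenience for an
#' ideal instantaneous IRF concentrated in a single channel, useful in tests
#' and closed-form checks.
#'
#' @param center Centre of the Gaussian IRF in ns from the window start.
#' @param fwhm Full width at half maximum in ns (must be > 0).
#' @return An object of class `irf_spec`.
#' @examples
#' irf <- irf_gaussian(center = 0.5, fwhm = 0.1)
#' prof <- irf_profile(irf, tcspc_config())
#' sum(prof) # 1
#' @export
irf_gaussian <- function(center = 0.5, fwhm = 0.1) {
  if (!is.finite(center) || !is.finite(fwhm) || fwhm <= 0) {
    stop("Gaussian IRF requires finite `center` and `fwhm` > 0")
  }
  structure(list(kind = "gaussian", center = center, fwhm = fwhm),
            class = "irf_spec")
}

#' @rdname irf_gaussian
#' @param counts_per_channel Non-negative per-channel histogram of a measured
#'   IRF; it is normalized to unit area when used.
#' @export
irf_tabulated <- function(counts_per_channel) {
  counts_per_channel <- as.numeric(counts_per_channel)
  if (length(counts_per_channel) < 1L || any(!is.finite(counts_per_channel))) {
    stop("tabulated IRF must be a finite numeric vector")
  }
  if (any(counts_per_channel < 0)) {
    stop("tabulated IRF counts must be non-negative")
  }
  if (sum(counts_per_channel) <= 0) {
    stop("tabulated IRF must have a positive total")
  }
  structure(list(kind = "tabulated", counts_per_channel = counts_per_channel),
            class = "irf_spec")
}

#' @rdname irf_gaussian
#' @param channel Channel index (1-based) holding the delta IRF.
#' @export
irf_delta <- function(channel = 1L) {
  channel <- as.integer(channel)
  if (is.na(channel) || channel < 1L) stop("`channel` must be a positive integer")
  counts <- numeric(channel)
  counts[channel] <- 1
  irf_tabulated(counts)
}

#' Discretized, normalized IRF profile
#'
#' Integrates (Gaussian case) or renormalizes (tabulated case) the IRF onto
#' the configured channel grid. The result is non-negative and sums to 1.
#'
#' @param irf An [irf_gaussian()], [irf_tabulated()] or [irf_delta()] object.
#' @param config A [tcspc_config()].
#' @return Numeric vector of length `config$n_channels` summing to 1.
#' @export
irf_profile <- function(irf, config) {
  stopifnot(inherits(irf, "irf_spec"), inherits(config, "tcspc_config"))
  n <- config$n_channels
  if (irf$kind == "gaussian") {
    sd <- irf$fwhm / (2 * sqrt(2 * log(2)))
    edges <- channel_edges(config)
    p <- stats::pnorm(edges[-1], irf$center, sd) -
      stats::pnorm(edges[-length(edges)], irf$center, sd)
  } else {
    p <- irf$counts_per_channel
    if (length(p) > n) {
      p <- p[seq_len(n)]
    } else if (length(p) < n) {
      p <- c(p, numeric(n - length(p)))
    }
  }
  s <- sum(p)
  if (s <= 0) stop("IRF has no mass inside the acquisition window")
  p / s
}

#' Peak channel of an IRF
#'
#' The channel with maximal IRF mass, used as the default time origin for
#' the barycenter mean lifetime and as the default start channel for fits.
#' Ties resolve to the earliest channel.
#'
#' @inheritParams irf_profile
#' @return Integer channel index (1-based).
#' @export
irf_peak_channel <- function(irf, config) {
  p <- irf_profile(irf, config)
  # near-ties (e.g. a Gaussian centred on a channel edge) resolve to the
  # earlier channel
  which(p >= max(p) * (1 - 1e-9))[1]
}
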