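# On-disk formats: multi-page TIFF FLIM stacks with JSON metadata,
# delimited decay and binding tables, YAML run configuration.

irf_to_meta <- function(irf) {
  if (is.null(irf)) return(NULL)
  if (irf$kind == "gaussian") {
    list(kind = "gaussian", center = irf$center, fwhm = irf$fwhm)
  } else {
    list(kind = "tabulated", counts_per_channel = irf$counts_per_channel)
  }
}

irf_from_meta <- function(m) {
  if (is.null(m)) return(NULL)
  if (identical(m$kind, "gaussian")) {
    irf_gaussian(m$center, m$fwhm)
  } else {
    irf_tabulated(unlist(m$counts_per_channel))
  }
}

#' Read and write FLIM stacks as multi-page TIFF
#'
#' A stack is stored as one 16-bit grayscale page per time channel, with
#' the time base and IRF serialized as a JSON sidecar (`<path>.json`)
#' written and read together with the image file. Counts survive a
#' write/read round trip bit-exactly (they are stored as integers scaled
#' into the 16-bit range). Ground-truth maps of synthetic stacks are
#' in-memory only and are not persisted.
#'
#' @param stack A [flim_stack] (counts must be below 65536 per channel).
#' @param path Output/input file path.
#' @return `read_flim_stack()` returns a `flim_stack`;
#'   `write_flim_stack()` returns `path` invisibly.
#' @export
write_flim_stack <- function(stack, path) {
  stopifnot(inherits(stack, "flim_stack"))
  if (max(stack$counts) > 65535) {
    stop("counts exceed the 16-bit range of the TIFF container")
  }
  meta <- list(
    format = "flimfret-stack",
    channel_width = stack$config$channel_width,
    n_channels = stack$config$n_channels,
    analysis_channels = stack$config$analysis_channels,
    irf = irf_to_meta(stack$irf),
    seed = stack$provenance$seed
  )
  n <- stack$config$n_channels
  pages <- lapply(seq_len(n), function(k) stack$counts[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_flim_stack
#' @export
read_flim_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop("format error: no stack metadata beside ", path,
         " (expected ", meta_path,
         " with keys channel_width, n_channels, analysis_channels)")
  }
  meta <- tryCatch(jsonlite::fromJSON(meta_path, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.null(meta)) stop("format error: metadata sidecar is not valid JSON")
  for (key in c("channel_width", "n_channels", "analysis_channels")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("format error: missing metadata key '%s'", key))
    }
  }
  config <- tcspc_config(meta$channel_width, meta$n_channels,
                         meta$analysis_channels)
  if (length(pages) != config$n_channels) {
    stop(sprintf("format error: %d pages but n_channels = %d",
                 length(pages), config$n_channels))
  }
  d <- dim(pages[[1]])
  counts <- array(0L, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) {
    counts[, , k] <- as.integer(round(pages[[k]] * 65535))
  }
  prov <- if (!is.null(meta$seed)) list(seed = meta$seed) else NULL
  flim_stack(counts, config, irf_from_meta(meta$irf), provenance = prov)
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' Read and write decay histograms as delimited text
#'
#' Decay tables are CSV/TSV with a header and columns `channel`, `time`
#' (ns) and `counts`. Validation errors name the offending file line
#' (header is line 1).
#'
#' @param path File path.
#' @return `read_decay_table()` returns the counts as a numeric vector
#'   with `time` and `channel` attributes.
#' @export
read_decay_table <- function(path) {
  tab <- read_delim_auto(path)
  if (!"counts" %in% names(tab)) {
    stop("format error: decay table needs a 'counts' column")
  }
  bad <- which(!is.finite(tab$counts) | tab$counts < 0)
  if (length(bad)) {
    stop(sprintf("invalid counts at line %d of %s", bad[1] + 1L, path))
  }
  out <- as.numeric(tab$counts)
  if ("time" %in% names(tab)) attr(out, "time") <- tab$time
  if ("channel" %in% names(tab)) attr(out, "channel") <- tab$channel
  out
}

#' @rdname read_decay_table
#' @param decay Per-channel counts.
#' @param config A [tcspc_config()] supplying the time axis.
#' @export
write_decay_table <- function(decay, path, config) {
  stopifnot(inherits(config, "tcspc_config"))
  tab <- data.frame(channel = seq_along(decay),
                    time = channel_times(config)[seq_along(decay)],
                    counts = as.numeric(decay))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read and write binding series as delimited text
#'
#' Binding tables are CSV/TSV with a header and columns `concentration`
#' (µM), `response` (RU) and optionally `condition`. A file holding one
#' condition yields a [binding_series()]; several conditions yield a named
#' list of series. Negative concentrations are rejected with the file line
#' number.
#'
#' @param path File path.
#' @export
read_binding_table <- function(path) {
  tab <- read_delim_auto(path)
  for (col in c("concentration", "response")) {
    if (!col %in% names(tab)) {
      stop(sprintf("format error: binding table needs a '%s' column", col))
    }
  }
  bad <- which(!is.finite(tab$concentration) | tab$concentration < 0)
  if (length(bad)) {
    stop(sprintf("invalid concentration at line %d of %s", bad[1] + 1L, path))
  }
  if (!"condition" %in% names(tab)) tab$condition <- ""
  conds <- unique(tab$condition)
  series <- lapply(conds, function(cc) {
    sub <- tab[tab$condition == cc, ]
    binding_series(sub$concentration, sub$response, cc)
  })
  if (length(series) == 1L) series[[1]] else stats::setNames(series, conds)
}

#' @rdname read_binding_table
#' @param series A [binding_series()].
#' @export
write_binding_table <- function(series, path) {
  stopifnot(inherits(series, "binding_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' The resolved configuration of an analysis run: the TCSPC time base, the
#' IRF, the fixed lifetimes, the photon threshold, binning and estimator
#' choices, the Förster radius and the seed. It round-trips losslessly
#' through YAML so that every numerical output is reproducible from the
#' archived config.
#'
#' @param config A [tcspc_config()].
#' @param irf An `irf_spec`.
#' @param tau_D,tau_F Fixed lifetimes, ns.
#' @param photon_threshold Per-pixel photon threshold.
#' @param binning `"sliding-2x2"`, `"block-2x2"` or `"none"`.
#' @param estimator Interacting-fraction estimator (see [fraction_map()]).
#' @param R0 Förster radius, Å.
#' @param seed Integer seed.
#' @param output_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(config = tcspc_config(), irf = irf_gaussian(),
                       tau_D = 2.65, tau_F = 0.83, photon_threshold = 150,
                       binning = c("sliding-2x2", "block-2x2", "none"),
                       estimator = c("linear", "intensity-weighted-inversion"),
                       R0 = 57, seed = 1L, output_dir = ".") {
  binning <- match.arg(binning)
  estimator <- match.arg(estimator)
  stopifnot(inherits(config, "tcspc_config"), tau_F < tau_D)
  structure(list(config = config, irf = irf, tau_D = tau_D, tau_F = tau_F,
                 photon_threshold = photon_threshold, binning = binning,
                 estimator = estimator, R0 = R0, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param rc A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(rc, path) {
  stopifnot(inherits(rc, "run_config"))
  lst <- list(
    tcspc = list(channel_width = rc$config$channel_width,
                 n_channels = rc$config$n_channels,
                 analysis_channels = rc$config$analysis_channels),
    irf = irf_to_meta(rc$irf),
    tau_D = rc$tau_D, tau_F = rc$tau_F,
    photon_threshold = rc$photon_threshold,
    binning = rc$binning, estimator = rc$estimator,
    R0 = rc$R0, seed = rc$seed, output_dir = rc$output_dir
  )
  writeLines(yaml::as.yaml(lst, precision = 15), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  for (key in c("tcspc", "tau_D", "tau_F")) {
    if (is.null(lst[[key]])) {
      stop(sprintf("format error: missing config key '%s'", key))
    }
  }
  run_config(
    config = tcspc_config(lst$tcspc$channel_width, lst$tcspc$n_channels,
                          lst$tcspc$analysis_channels),
    irf = irf_from_meta(lst$irf),
    tau_D = lst$tau_D, tau_F = lst$tau_F,
    photon_threshold = lst$photon_threshold,
    binning = lst$binning, estimator = lst$estimator,
    R0 = lst$R0, seed = lst$seed, output_dir = lst$output_dir
  )
}
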