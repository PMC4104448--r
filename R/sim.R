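# Synthetic TCSPC / FLIM data generation with known ground truth.

# Evaluate code with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Discrete convolution of a normalized IRF profile h with per-channel decay
# mass x. Linear (tail truncated at the window end) or circular (periodic,
# for repetition-period wraparound). Both preserve total mass over the
# infinite support; tiny FFT negatives are clamped.
conv_irf <- function(h, x, circular = FALSE) {
  n <- length(x)
  stopifnot(length(h) == n)
  if (circular) {
    y <- Re(stats::fft(stats::fft(h) * stats::fft(x), inverse = TRUE)) / n
  } else {
    m <- stats::nextn(2L * n, 2)
    hp <- c(h, numeric(m - n))
    xp <- c(x, numeric(m - n))
    y <- Re(stats::fft(stats::fft(hp) * stats::fft(xp), inverse = TRUE))[seq_len(n)] / m
  }
  pmax(y, 0)
}

# Per-channel probability mass of an exponential decay with lifetime tau:
# exact integral of the density over each channel. With wraparound, the
# masses of all later excitation periods fold back into the window, which
# amounts to dividing by (1 - exp(-T/tau)).
exp_channel_mass <- function(tau, config, wraparound = FALSE) {
  edges <- channel_edges(config)
  p <- exp(-edges[-length(edges)] / tau) - exp(-edges[-1] / tau)
  if (wraparound) p <- p / (1 - exp(-config$repetition_period / tau))
  p
}

#' Expected TCSPC decay of the two-species donor model
#'
#' Computes the noise-free expected photon count per channel for the
#' two-species model
#' \deqn{I(t) = I_0 [f_D e^{-t/\tau_F} + (1 - f_D) e^{-t/\tau_D}]}
#' convolved with the instrument response function, plus a uniform
#' background. The exponential mass per channel is the exact integral over
#' the channel, so the total (over an unbounded window, before truncation)
#' equals `total_intensity` plus `background * n_channels`. With `f_D = 0`
#' the model reduces exactly to the single-exponential donor decay.
#'
#' @param params A [two_species_params()] object.
#' @param config A [tcspc_config()].
#' @param irf An `irf_spec` (see [irf_gaussian()]).
#' @param wraparound If `TRUE`, fold the decay tail of previous excitation
#'   periods back into the window (periodic convolution). Off by default:
#'   with a 2.65 ns lifetime in a 25 ns period the wrapped tail is ~8e-5 of
#'   the total and negligible.
#' @return Numeric vector of expected counts, length `config$n_channels`.
#' @examples
#' cfg <- tcspc_config()
#' mu <- model_decay(two_species_params(0.25, total_intensity = 600),
#'                   cfg, irf_gaussian())
#' sum(mu)
#' @export
model_decay <- function(params, config, irf, wraparound = FALSE) {
  stopifnot(inherits(params, "two_species_params"),
            inherits(config, "tcspc_config"))
  h <- irf_profile(irf, config)
  mix <- two_species_channel_mass(params$f_D, params$tau_D, params$tau_F,
                                  config, wraparound)
  params$total_intensity * conv_irf(h, mix, circular = wraparound) +
    params$background
}

# Per-channel photon mass of the two-species decay, normalized to sum 1
# over the unbounded window. f_D is the pre-exponential (species) fraction:
# the photon share of the FRET species is f_D tau_F / (f_D tau_F +
# (1 - f_D) tau_D), since photons per species scale with its lifetime.
two_species_channel_mass <- function(f_D, tau_D, tau_F, config,
                                     wraparound = FALSE) {
  pD <- exp_channel_mass(tau_D, config, wraparound)
  if (f_D <= 0) return(pD)
  pF <- exp_channel_mass(tau_F, config, wraparound)
  wF <- f_D * tau_F
  wD <- (1 - f_D) * tau_D
  (wF * pF + wD * pD) / (wF + wD)
}

#' Simulate a photon-counting decay histogram
#'
#' Draws independent Poisson counts per channel around the expected decay of
#' [model_decay()] — the standard noise model for TCSPC detection. The same
#' seed always yields the same histogram.
#'
#' @inheritParams model_decay
#' @param seed Integer seed (required; simulation is a pure function of
#'   parameters and seed).
#' @return Integer vector of counts, length `config$n_channels`.
#' @export
simulate_decay <- function(params, config, irf, seed, wraparound = FALSE) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  mu <- model_decay(params, config, irf, wraparound)
  with_seed(seed, stats::rpois(length(mu), mu))
}

#' Scene description for synthetic FLIM images
#'
#' Describes an endosome-like scene: hard-disk puncta (bright spots with
#' their own interacting fraction) over a diffuse cytoplasmic background,
#' restricted to a cell mask. Geometry is configuration, not science; it
#' exists to give the simulator the punctate spatial structure of
#' membrane-protein FLIM images.
#'
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param puncta Data frame with columns `row`, `col` (centre, pixels),
#'   `radius` (pixels, > 0), `intensity` (expected photons/pixel added on
#'   top of the diffuse level, >= 0) and `f_D` (interacting fraction inside
#'   the punctum). May have zero rows.
#' @param diffuse_intensity Expected photons per pixel outside puncta
#'   (inside the cell mask).
#' @param diffuse_f_D Interacting fraction outside puncta.
#' @param cell_mask Logical matrix of `image_shape`; `NULL` means the whole
#'   image is cell.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape, puncta = NULL, diffuse_intensity = 0,
                       diffuse_f_D = 0, cell_mask = NULL) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(is.na(image_shape)) || any(image_shape < 1L)) {
    stop("`image_shape` must be c(rows, cols) with positive entries")
  }
  if (is.null(puncta)) {
    puncta <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0),
                         intensity = numeric(0), f_D = numeric(0))
  }
  need <- c("row", "col", "radius", "intensity", "f_D")
  if (!all(need %in% names(puncta))) {
    stop("`puncta` needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(puncta) > 0) {
    if (any(puncta$row < 1 | puncta$row > image_shape[1] |
            puncta$col < 1 | puncta$col > image_shape[2])) {
      stop("puncta centers must lie inside `image_shape`")
    }
    if (any(puncta$radius <= 0)) stop("puncta radii must be > 0")
    if (any(puncta$intensity < 0)) stop("puncta intensities must be >= 0")
    if (any(puncta$f_D < 0 | puncta$f_D > 1)) stop("puncta f_D must lie in [0, 1]")
  }
  if (diffuse_intensity < 0) stop("`diffuse_intensity` must be >= 0")
  if (diffuse_f_D < 0 || diffuse_f_D > 1) stop("`diffuse_f_D` must lie in [0, 1]")
  if (is.null(cell_mask)) {
    cell_mask <- matrix(TRUE, image_shape[1], image_shape[2])
  }
  if (!is.logical(cell_mask) || !all(dim(cell_mask) == image_shape)) {
    stop("`cell_mask` must be a logical matrix of `image_shape`")
  }
  if (!any(cell_mask)) stop("empty scene: cell mask covers no pixels")
  if (diffuse_intensity == 0 && (nrow(puncta) == 0 || all(puncta$intensity == 0))) {
    stop("empty scene: no expected photons anywhere")
  }
  structure(list(image_shape = image_shape, puncta = puncta,
                 diffuse_intensity = diffuse_intensity,
                 diffuse_f_D = diffuse_f_D, cell_mask = cell_mask),
            class = "scene_spec")
}

# Rasterize a scene into per-pixel expected-intensity and f_D maps.
# Inside a punctum the punctum's f_D overrides the diffuse value (later
# puncta win on overlap); intensity is diffuse + punctum. Outside the cell
# mask intensity is 0 and f_D is NA.
scene_maps <- function(scene) {
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  intensity <- matrix(scene$diffuse_intensity, nr, nc)
  f_D <- matrix(scene$diffuse_f_D, nr, nc)
  if (nrow(scene$puncta) > 0) {
    for (i in seq_len(nrow(scene$puncta))) {
      p <- scene$puncta[i, ]
      inside <- (rows - p$row)^2 + (cols - p$col)^2 <= p$radius^2
      intensity[inside] <- intensity[inside] + p$intensity
      f_D[inside] <- p$f_D
    }
  }
  intensity[!scene$cell_mask] <- 0
  f_D[!scene$cell_mask] <- NA_real_
  list(intensity = intensity, f_D = f_D)
}

#' Built-in scene presets
#'
#' Two ready-made scenes mirroring the study conditions the simulator
#' emulates: `"donor-only"` (punctate donor expression with no FRET
#' anywhere) and `"coexpression"` (donor plus acceptor: puncta with
#' `f_D = 0.35` over a diffuse `f_D = 0.15`, roughly 600 expected photons
#' per 2x2-binned pixel). Punctum placement is randomized within a central
#' disk-shaped cell mask, reproducibly from `seed`.
#'
#' @param name `"donor-only"` or `"coexpression"`.
#' @param image_shape Image size, default `c(32, 32)`.
#' @param n_puncta Number of puncta (default 6).
#' @param seed Seed for punctum placement.
#' @param f_D_puncta,f_D_diffuse Optional overrides of the preset fractions
#'   (used e.g. to build cells with a uniform truth fraction).
#' @return A [scene_spec()].
#' @export
scene_preset <- function(name = c("donor-only", "coexpression"),
                         image_shape = c(32L, 32L), n_puncta = 6L, seed = 1L,
                         f_D_puncta = NULL, f_D_diffuse = NULL) {
  name <- match.arg(name)
  image_shape <- as.integer(image_shape)
  if (name == "donor-only") {
    if (is.null(f_D_puncta)) f_D_puncta <- 0
    if (is.null(f_D_diffuse)) f_D_diffuse <- 0
  } else {
    if (is.null(f_D_puncta)) f_D_puncta <- 0.35
    if (is.null(f_D_diffuse)) f_D_diffuse <- 0.15
  }
  nr <- image_shape[1]; nc <- image_shape[2]
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  cell_r <- 0.45 * min(nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cell_mask <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= cell_r^2
  pts <- with_seed(seed, {
    ang <- stats::runif(n_puncta, 0, 2 * pi)
    rad <- cell_r * 0.8 * sqrt(stats::runif(n_puncta))
    data.frame(row = round(ctr[1] + rad * sin(ang)),
               col = round(ctr[2] + rad * cos(ang)))
  })
  puncta <- data.frame(row = pmin(pmax(pts$row, 1), nr),
                       col = pmin(pmax(pts$col, 1), nc),
                       radius = 2.2, intensity = 150, f_D = f_D_puncta)
  # diffuse 150 expected photons/pixel -> ~600 per interior 2x2-binned pixel
  scene_spec(image_shape, puncta, diffuse_intensity = 150,
             diffuse_f_D = f_D_diffuse, cell_mask = cell_mask)
}

#' FLIM image stack container
#'
#' Holds per-pixel photon-count histograms `counts[row, col, channel]`
#' together with the TCSPC time base, the IRF and — for synthetic stacks —
#' per-pixel ground-truth maps and the generation provenance (seed, scene,
#' parameters). Produced by [simulate_flim_image()] and
#' [read_flim_stack()]; constructible directly from an array, e.g. to
#' analyze noiseless expected decays.
#'
#' @param counts Non-negative array `(rows, cols, n_channels)`.
#' @param config A [tcspc_config()]; `n_channels` must match.
#' @param irf An `irf_spec` or `NULL`.
#' @param truth Optional list of ground-truth maps (`f_D`, `intensity`,
#'   `tau_D`, `tau_F`), each matching the spatial shape.
#' @param provenance Optional list recording how the stack was generated.
#' @return An object of class `flim_stack`.
#' @export
flim_stack <- function(counts, config, irf, truth = NULL, provenance = NULL) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L,
            inherits(config, "tcspc_config"))
  if (dim(counts)[3] != config$n_channels) {
    stop("third dimension of `counts` must equal `n_channels`")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(truth)) {
    for (m in truth) {
      if (is.matrix(m) && !all(dim(m) == dim(counts)[1:2])) {
        stop("truth maps must match the spatial shape of `counts`")
      }
    }
  }
  structure(list(counts = counts, config = config, irf = irf,
                 truth = truth, provenance = provenance),
            class = "flim_stack")
}

#' @export
print.flim_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("FLIM stack: %d x %d pixels x %d channels, %s photons total%s\n",
              d[1], d[2], d[3], format(sum(x$counts), big.mark = ","),
              if (!is.null(x$truth)) " (synthetic, truth attached)" else ""))
  invisible(x)
}

#' Simulate a FLIM image stack with ground truth
#'
#' Rasterizes a [scene_spec()] into per-pixel expected intensities and
#' interacting fractions, builds the expected two-species decay for every
#' pixel and draws Poisson counts per (pixel, channel). The returned
#' [flim_stack] carries truth maps (`f_D`, `tau_D`, `tau_F`, expected
#' `intensity`) and the generation provenance (seed, scene, parameters).
#'
#' @param scene A [scene_spec()] (see also [scene_preset()]).
#' @param donor_params A [two_species_params()] supplying `tau_D`, `tau_F`
#'   and the per-channel `background`; its `f_D` and `total_intensity` are
#'   ignored in favour of the per-pixel scene values.
#' @inheritParams simulate_decay
#' @return A `flim_stack`.
#' @examples
#' stk <- simulate_flim_image(scene_preset("coexpression", seed = 2),
#'                            two_species_params(0), tcspc_config(),
#'                            irf_gaussian(), seed = 7)
#' stk
#' @export
simulate_flim_image <- function(scene, donor_params, config, irf, seed,
                                wraparound = FALSE) {
  stopifnot(inherits(scene, "scene_spec"),
            inherits(donor_params, "two_species_params"),
            inherits(config, "tcspc_config"))
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  maps <- scene_maps(scene)
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  n <- config$n_channels
  fvals <- sort(unique(stats::na.omit(as.vector(maps$f_D))))
  # one unit-intensity, background-free expected decay per distinct f_D
  unit <- matrix(0, length(fvals), n)
  for (i in seq_along(fvals)) {
    p <- two_species_params(fvals[i], donor_params$tau_D, donor_params$tau_F,
                            total_intensity = 1, background = 0)
    unit[i, ] <- model_decay(p, config, irf, wraparound)
  }
  fidx <- match(as.vector(maps$f_D), fvals)
  fidx[is.na(fidx)] <- 1L # zero-intensity pixels; decay shape irrelevant
  mu <- unit[fidx, , drop = FALSE] * as.vector(maps$intensity) +
    donor_params$background
  counts_vec <- with_seed(seed, stats::rpois(length(mu), as.vector(mu)))
  counts <- array(counts_vec, dim = c(nr, nc, n))
  flim_stack(
    counts, config, irf,
    truth = list(
      f_D = maps$f_D,
      intensity = maps$intensity,
      tau_D = matrix(donor_params$tau_D, nr, nc),
      tau_F = matrix(donor_params$tau_F, nr, nc)
    ),
    provenance = list(seed = seed, scene = scene, donor_params = donor_params,
                      wraparound = wraparound)
  )
}

#' Simulate an equilibrium binding series
#'
#' Generates a saturation binding response series
#' `R = rmax * C / (kd + C)` with zero-mean Gaussian noise, either additive
#' (constant sd in response units) or proportional (sd as a fraction of the
#' response), reproducibly from `seed`.
#'
#' @param kd Dissociation constant (> 0, concentration units).
#' @param rmax Maximal response (> 0, response units).
#' @param concentrations Non-negative analyte concentrations.
#' @param noise_sd Noise standard deviation (response units, or fraction of
#'   the response when `noise = "proportional"`).
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @param noise `"additive"` or `"proportional"`.
#' @param condition_label Free-text condition tag (e.g. a buffer additive).
#' @return A [binding_series()].
#' @export
simulate_binding_series <- function(kd, rmax, concentrations, noise_sd = 0,
                                    seed = NULL,
                                    noise = c("additive", "proportional"),
                                    condition_label = "synthetic") {
  noise <- match.arg(noise)
  if (!is.finite(kd) || kd <= 0) stop("`kd` must be > 0")
  if (!is.finite(rmax) || rmax <= 0) stop("`rmax` must be > 0")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  r <- one_site_model(concentrations, kd, rmax)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("`seed` is required when `noise_sd` > 0")
    eps <- with_seed(seed, stats::rnorm(length(r)))
    r <- if (noise == "additive") r + noise_sd * eps else r * (1 + noise_sd * eps)
  }
  binding_series(concentrations, r, condition_label)
}
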