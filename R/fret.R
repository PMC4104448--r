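# FRET efficiency, Förster distance and first-order error propagation.

#' FRET efficiency from donor lifetimes
#'
#' The true FRET efficiency of the interacting population,
#' `E = 1 - tau_F / tau_D`: the fractional shortening of the donor lifetime
#' in the presence of the acceptor.
#'
#' @param tau_F FRET (quenched) donor lifetime, ns; `0 < tau_F <= tau_D`.
#' @param tau_D Unquenched donor lifetime, ns.
#' @return Efficiency in \[0, 1).
#' @examples
#' fret_efficiency(0.83, 2.65) # ~0.69
#' @export
fret_efficiency <- function(tau_F, tau_D) {
  if (any(!is.finite(tau_F)) || any(!is.finite(tau_D))) {
    stop("lifetimes must be finite")
  }
  if (any(tau_F <= 0) || any(tau_D <= 0)) stop("lifetimes must be > 0")
  if (any(tau_F > tau_D)) {
    stop("tau_F > tau_D would imply a negative FRET efficiency")
  }
  1 - tau_F / tau_D
}

#' Donor–acceptor distance from FRET efficiency
#'
#' Inverts the Förster relation `E = 1 / (1 + (r/R0)^6)`:
#' `r = R0 * ((1 - E) / E)^(1/6)`. The distance equals the Förster radius
#' exactly at half efficiency and decreases strictly with E.
#'
#' @param E FRET efficiency, strictly inside (0, 1).
#' @param R0 Förster radius in Å (default 57, the mTFP1/mVenus pair).
#' @return Distance in Å.
#' @examples
#' fret_distance(fret_efficiency(0.83, 2.65)) # ~49.9 A
#' @export
fret_distance <- function(E, R0 = 57) {
  if (any(!is.finite(E)) || any(E <= 0) || any(E >= 1)) {
    stop("`E` must lie strictly inside (0, 1): the distance is unbounded at 0 and zero at 1")
  }
  if (any(R0 <= 0)) stop("`R0` must be > 0")
  R0 * ((1 - E) / E)^(1 / 6)
}

# dr/dE of the inverse Förster relation (negative).
dr_dE <- function(E, R0) {
  -(R0 / 6) * ((1 - E) / E)^(1 / 6) / (E * (1 - E))
}

#' FRET efficiency and distance with propagated uncertainty
#'
#' Combines [fret_efficiency()] and [fret_distance()] with first-order
#' (delta-method) propagation of the lifetime uncertainties:
#' `var(E) = (sd_F/tau_D)^2 + (tau_F sd_D / tau_D^2)^2` and
#' `sd(r) = |dr/dE| sd(E)`. Exact inputs give exactly zero output sds.
#'
#' @inheritParams fret_efficiency
#' @param tau_F_sd,tau_D_sd Standard deviations of the lifetimes, ns
#'   (default 0).
#' @param R0 Förster radius in Å.
#' @return An object of class `fret_result` with fields `efficiency`,
#'   `efficiency_sd`, `distance`, `distance_sd`, `forster_radius`.
#' @examples
#' fret_propagate(0.83, 2.65, tau_F_sd = 0.05, tau_D_sd = 0.04)
#' @export
fret_propagate <- function(tau_F, tau_D, tau_F_sd = 0, tau_D_sd = 0, R0 = 57) {
  if (tau_F_sd < 0 || tau_D_sd < 0) stop("standard deviations must be >= 0")
  E <- fret_efficiency(tau_F, tau_D)
  E_sd <- sqrt((tau_F_sd / tau_D)^2 + (tau_F * tau_D_sd / tau_D^2)^2)
  r <- fret_distance(E, R0)
  r_sd <- abs(dr_dE(E, R0)) * E_sd
  structure(list(efficiency = E, efficiency_sd = E_sd,
                 distance = r, distance_sd = r_sd,
                 forster_radius = R0,
                 tau_F = tau_F, tau_D = tau_D),
            class = "fret_result")
}

#' Distance uncertainty from an efficiency uncertainty
#'
#' Delta-method standard deviation of the Förster distance given the
#' efficiency and its standard deviation.
#'
#' @inheritParams fret_distance
#' @param E_sd Standard deviation of E.
#' @return Standard deviation of the distance, Å.
#' @examples
#' fret_distance_sd(0.69, 0.06) # ~2.3 A
#' @export
fret_distance_sd <- function(E, E_sd, R0 = 57) {
  if (any(E_sd < 0)) stop("`E_sd` must be >= 0")
  fret_distance(E, R0) # validates E
  abs(dr_dE(E, R0)) * E_sd
}

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf("FRET efficiency E = %.3f +/- %.3f\n", x$efficiency, x$efficiency_sd))
  cat(sprintf("Donor-acceptor distance r = %.1f +/- %.1f A (R0 = %g A)\n",
              x$distance, x$distance_sd, x$forster_radius))
  invisible(x)
}
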