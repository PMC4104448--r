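# Shared fixtures: everything is generated in code at test time.

cfg_std <- function() tcspc_config()

irf_std <- function() irf_gaussian()

# Minimal lifetime_map built directly from a tau matrix, for testing the
# fraction-map closed forms in isolation.
make_lifetime_map <- function(tau, photons = 1000, threshold = 150,
                              config = tcspc_config()) {
  tau <- as.matrix(tau)
  valid <- !is.na(tau)
  structure(list(
    tau_mean = tau,
    photon_count = matrix(photons, nrow(tau), ncol(tau)),
    valid_mask = valid,
    origin_channel = 1L,
    photon_threshold = threshold,
    config = config
  ), class = "lifetime_map")
}

# Noiseless uniform stack: every pixel carries the expected decay `mu`.
uniform_stack <- function(mu, nr = 2, nc = 2, config = tcspc_config(),
                          irf = irf_delta(1)) {
  a <- array(rep(mu, each = nr * nc), dim = c(nr, nc, length(mu)))
  flimfret:::flim_stack(a, config, irf)
}

geom_concs <- function(n = 8, lo = 0.1, hi = 20) lo * (hi / lo)^((seq_len(n) - 1) / (n - 1))
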