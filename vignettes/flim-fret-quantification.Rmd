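---
title: "Quantifying protein-protein interaction by FLIM-FRET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein-protein interaction by FLIM-FRET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimfret)
```

# The measurement and the model

Time-domain fluorescence lifetime imaging (FLIM) records, for every image
pixel, a histogram of photon arrival times after a pulsed excitation
(time-correlated single photon counting, TCSPC). When a FRET acceptor sits
within ~10 nm of the donor fluorophore, energy transfer opens an extra
de-excitation channel and the donor lifetime shortens. In a cell where only
part of the donor population interacts, the donor decay is a two-species
mixture:

$$I(t) = I_0\left[f_D\, e^{-t/\tau_F} + (1 - f_D)\, e^{-t/\tau_D}\right],$$

where $\tau_D$ is the undisturbed donor lifetime, $\tau_F$ the quenched
(FRET) lifetime, and $f_D$ — the *fraction of interacting donor* — is the
pre-exponential amplitude fraction, i.e. the fraction of donor molecules in
the interacting state. With the total intensity normalized to 1 the
pre-exponential factors lie in $[0, 1]$. Because a molecule with lifetime
$\tau$ emits in proportion to $\tau$, the *photon* share of the FRET
species is $f_D \tau_F / (f_D \tau_F + (1 - f_D)\tau_D)$, which is much
smaller than $f_D$ itself: at $f_D = 0.17$ with the defaults below, only
~6% of detected photons come from the interacting population. This is the
fundamental reason per-pixel estimates of $f_D$ are noisy and the analysis
leans on fixed lifetimes, spatial binning and photon thresholds.

Two summary lifetimes of the mixture are used throughout:

* the **amplitude-weighted mean** $\bar\tau_a = f_D \tau_F + (1-f_D)\tau_D$
  (`amplitude_mean_lifetime()`), linear in $f_D$;
* the **intensity-weighted mean**
  $\bar\tau_i = (f_D \tau_F^2 + (1-f_D)\tau_D^2) / (f_D \tau_F + (1-f_D)\tau_D)$
  (`intensity_mean_lifetime()`), which is what the first temporal moment
  (barycenter) of the measured decay estimates in the long-window limit.

The distinction matters for the map-level estimators (below): the two are
equal only at $f_D \in \{0, 1\}$, and $\bar\tau_i \ge \bar\tau_a$
everywhere in between.

## Default parameters

| Parameter | Default | Meaning |
|---|---|---|
| `channel_width` | 0.02 ns | TCSPC channel (20 ps) |
| `n_channels` | 1250 | one 25 ns period of a 40 MHz laser |
| `analysis_channels` | 1200 | fit / barycenter window (24 ns) |
| `tau_D` | 2.65 ns | donor lifetime, from single-exponential fits of donor-only cells |
| `tau_F` | 0.83 ns | FRET lifetime, from two-species fits with `tau_F` free |
| IRF | Gaussian, fwhm 100 ps, centred 0.5 ns | parametric default; tabulated IRFs accepted |
| `photon_threshold` | 150 | minimum photons per (binned) pixel |
| `R0` | 57 Å | Förster radius of the mTFP1/mVenus pair (literature constant, not computed) |

The IRF shape is a modelling choice: instrument response functions are not
published with most studies, and a 100 ps Gaussian is typical of a
hybrid-detector confocal TCSPC system. Tabulated measured IRFs can be
supplied via `irf_tabulated()` wherever an IRF is accepted.

# The synthetic-data generator

No imaging data accompanies the analysis this package implements, so the
generator is a first-class module that produces data with the statistical
structure the estimators assume, plus known ground truth:

* `model_decay()` evaluates the expected counts per channel: the exact
  integral of each exponential over each 20 ps channel, mixed with the
  photon-share weights above, convolved with the discretized IRF, plus a
  uniform background. Repetition-period wraparound (the tail of previous
  pulses folding into the window) is available as a flag but off by
  default: with $\tau_D = 2.65$ ns in a 25 ns period the wrapped tail is
  $e^{-25/2.65} \approx 8\times10^{-5}$ of the total.
* `simulate_decay()` draws independent Poisson counts per channel — the
  standard TCSPC noise model (dead-time and afterpulsing artefacts are not
  modelled).
* `simulate_flim_image()` rasterizes a `scene_spec()` — hard-disk,
  endosome-like puncta with their own $f_D$ over a diffuse background,
  inside a cell mask — and simulates every pixel. `scene_preset()` ships a
  donor-only and a co-expression scene (puncta $f_D = 0.35$ over diffuse
  0.15, ~600 expected photons per 2×2-binned pixel, matching the photon
  economy of the imaging conditions the package targets).

What the generator does *not* emulate: detector dead time, afterpulsing,
spectral bleed-through, acceptor photophysics, cell-to-cell lifetime
variability, and motion during acquisition. Passing tests therefore
demonstrate correctness of the estimators under the model's own
assumptions, not robustness to every artefact of real microscopes.

# Decay fitting

`fit_one_exp()` and `fit_two_species()` perform *iterative reconvolution*:
the model decay is convolved with the IRF inside the objective and compared
to the data. The data are never deconvolved — direct deconvolution of
photon-counting histograms is numerically unstable and is deliberately not
offered.

Two objectives are available:

* `"wls"` (default): Levenberg–Marquardt least squares with Neyman weights
  $1/\max(c_i, 1)$, the classical TCSPC choice. Its known failure mode is
  a *downward* lifetime bias when many channels hold fewer than ~10
  counts, because empty channels are over-weighted. The test suite pins
  this behaviour down rather than hiding it.
* `"poisson-mle"`: the exact Poisson likelihood, maximized with L-BFGS-B.
  This is the statistically correct objective at low counts and is what
  the population-level analyses in this package use for ~600-photon
  decays.

Workflow, mirroring standard practice: the donor lifetime is estimated
once by `fit_one_exp()` on donor-only cells and then *fixed* in the
two-species fit (`fixed = list(tau_D = ...)`). With ample photons
(whole-cell ROI decays) `tau_F` is left free; for low-photon decays
`tau_F` is fixed too (at 0.83 ns by default), since a two-lifetime,
two-amplitude model is not identifiable from a few hundred photons.

Numerical choices:

* $f_D$ is box-constrained to $[0, 1]$ (the solver supports bounds
  directly, keeping estimates and standard errors on the natural scale);
  $\tau_F$ is bounded above by $0.99\,\tau_D$ so the species cannot swap.
* Initialization is deterministic: the lifetime starts at the barycenter
  estimate, the amplitude at the total count. When `tau_F` is free the fit
  runs from three deterministic starts ($f_D \in \{0.15, 0.5, 0.85\}$) and
  keeps the lowest objective — with a single start the objective can stall
  in a local minimum at high true $f_D$.
* Convergence: relative objective change below $10^{-8}$ or 500
  iterations; hitting the cap flags the result as non-converged, never a
  silent return. A fitted `tau_F` within 5% of the fixed `tau_D` raises an
  identifiability warning and a result flag.
* Decays under the photon threshold raise a typed low-signal error
  (`flimfret_low_signal`), so pipelines fail loudly rather than producing
  garbage estimates.

# Pixel-wise maps

`spatial_bin_2x2()` applies the sliding 2×2 sum (dimensions preserved,
edges use the neighbours that exist) used to raise per-pixel signal to
noise; `spatial_bin_block2()` is the stride-2 block sum, which exactly
conserves photons and serves as the conservation oracle in tests.

`mean_lifetime_map()` computes the per-pixel barycenter
$\langle\tau\rangle = \sum_i t_i c_i / \sum_i c_i$ over the first 1200
channels. The time origin is the IRF centroid shifted back by half a
channel (the left edge of the centroid channel): with this convention the
discrete barycenter of a channel-integrated exponential reproduces the
continuous mean to second order in the channel width, for delta and broad
IRFs alike. Over a finite window $T$ the barycenter of a pure exponential
is the truncated mean $\tau - T e^{-T/\tau} / (1 - e^{-T/\tau})$ — 2.647 ns
for $\tau = 2.65$ ns and $T = 24$ ns — and the tests hold the map to that
closed form. Pixels under the photon threshold are masked and carry `NA`
end-to-end; they never enter any downstream statistic.

`fraction_map()` converts $\langle\tau\rangle$ to $f_D$ with a choice of
two estimators, provided side by side because they answer subtly different
questions:

* **linear**: $f_D = (\tau_D - \langle\tau\rangle)/(\tau_D - \tau_F)$.
  This is the standard image formula; it inverts the *amplitude*-weighted
  mean. Applied to a barycenter $\langle\tau\rangle$ (which estimates the
  *intensity*-weighted mean) it systematically *underestimates* interior
  fractions — e.g. $\langle\tau\rangle = 2.52$ ns maps to 0.071.
* **intensity-weighted-inversion**:
  $f_D = \tau_D(\tau_D - \langle\tau\rangle) / ((\tau_D - \tau_F)(\tau_D + \tau_F - \langle\tau\rangle))$,
  the exact inverse of the intensity-weighted mean; the same
  $\langle\tau\rangle = 2.52$ ns maps to 0.197, and on noiseless synthetic
  stacks this estimator recovers the truth map to better than 0.01.

Published map-level fractions cannot always be reconciled with per-cell
fitted fractions under either formula, so the package reports both and
never asserts equality between map-derived and fit-derived values. Values
are clipped to $[0, 1]$; lifetimes outside $(\tau_F, \tau_D)$ are
additionally flagged per pixel.

# FRET efficiency and distance

For the interacting population, $E = 1 - \tau_F/\tau_D$ and the Förster
relation gives $r = R_0 ((1-E)/E)^{1/6}$. With the default lifetimes
$E = 0.687$; note that the sixth root makes $r$ sensitive to rounding in
$E$: the exact value gives $r = 50.0$ Å while the two-decimal efficiency
0.69 gives 49.9 Å. `fret_propagate()` and `fret_distance_sd()` carry
first-order (delta-method) uncertainties through both maps; an efficiency
spread of 0.06 maps to ~2.3 Å around these values. $R_0$ is a
configuration constant — computing it from spectral overlap is out of
scope.

# Per-cell statistics

`summarize_cell()` averages the masked maps over a whole-cell ROI
(unweighted by default; photon-weighted means are an option, and the
choice is surfaced because the two differ when expression is spatially
heterogeneous). `compare_groups()` performs the two-sample t-test between
per-cell values — pooled-variance ("student") by default, Welch as the
alternative, since published "Student's t-test" labels rarely state which
is meant. `independence_check()` operationalizes "the interaction measure
does not depend on expression level" as a Spearman correlation between
per-cell $f_D$ and the donor/acceptor intensity ratio with a seeded
permutation p-value (9999 permutations by default); a scatter with no
trend is a claim, a permutation test is a number.

# Equilibrium binding

`fit_one_site()` fits the saturation hyperbola
$R = R_{\max} C / (K_d + C)$ by Levenberg–Marquardt with deterministic
initialization ($K_d$ at the concentration nearest half-maximal response).
Diagnostics flag designs with fewer than four distinct concentrations,
concentrations that do not straddle the fitted $K_d$, or a $K_d$ more than
10× outside the sampled range. `detectability_call()` classifies a series
as `binding` or `not-detectable` by the F-test of the one-site model
against the zero-response model (plus an optional absolute response
threshold) — the operational reading of "response indistinguishable from
zero" used for competed or deglycosylated conditions. Competition
conditions are metadata labels on `binding_series()`, not mechanistic
models: each condition is analysed as an independent saturation (or ND)
series. Kinetic (on/off-rate) analysis is out of scope.

Noise conventions in the simulator: `simulate_binding_series()` offers
additive (constant in response units — the natural reading of instrument
noise) and proportional noise. Standard errors of the unweighted fit are
calibrated under additive noise; under strongly proportional noise they
are only approximate, which the test suite demonstrates by calibrating
coverage under the additive model.

# Problem sizes and reproducibility

The shipped tests and the acceptance script run at desk scale, chosen so
the whole suite completes in about a minute while keeping Monte-Carlo
error well inside the asserted tolerances: 200 simulated decays per
recovery setting at ~600 photons each, 10 + 10 simulated cells of 24×24
pixels for the population comparison, and 100 noise replicates per $K_d$
for the binding calibration. Every stochastic step takes an explicit seed,
simulators restore the global RNG state, and `run_config()` round-trips
the full analysis configuration through YAML so any numerical output is
reproducible from the archived config plus seed.

# Known limitations

* Single FRET lifetime per pixel: distance distributions and multi-state
  quenching are collapsed into one effective $\tau_F$.
* The Gaussian IRF default ignores detector afterpulsing tails; supply a
  tabulated IRF for quantitative work on real instruments.
* The linear fraction estimator inherits the amplitude/intensity
  mismatch described above; treat map-level $f_D$ values as relative
  unless the inversion estimator is used.
* Vendor TCSPC container formats are not parsed; the supported containers
  are the multi-page TIFF (+ JSON sidecar) and delimited text.
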