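Package: flimfret
Title: FLIM-FRET Quantification and Equilibrium Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantification pipeline for time-domain fluorescence lifetime
    imaging (FLIM) of Förster resonance energy transfer (FRET) between
    membrane-protein fusion constructs, together with equilibrium
    surface-plasmon-resonance binding analysis. Provides a synthetic
    time-correlated single photon counting (TCSPC) data generator with known
    ground truth, single- and two-species iterative reconvolution decay
    fitting with a fixed donor lifetime, pixel-wise barycenter mean-lifetime
    and interacting-fraction maps with photon-count masking, FRET
    efficiency and Förster distance calculation with first-order error
    propagation, per-cell aggregation with population-level t-tests and a
    permutation-based independence check, and one-site saturation binding
    (K_d) fitting with detectability calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
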