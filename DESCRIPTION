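Package: lgmdnet
Title: Looming-Detector Input Circuits: Retinotopic Network Simulation and
    Connectome Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the input organization of the locust lobula
    giant movement detectors (LGMD 1 and 2). Provides a discrete-time (1 ms)
    retinotopic network model of the photoreceptor to trans-medullary-afferent
    (TmA) to LGMD pathway with lateral (L-) and self (S-) inhibition, stimulus
    generators for looming, near-miss and translating objects on a hexagonal
    array of visual units, and quantification routines for electron-microscopy
    connectome tables: active-zone lengths, surface and linear synapse
    densities, per-facet metrics, reciprocity, TmA connectivity matrices,
    Mann-Whitney U comparisons with exact tie handling, and growth-scaled
    totals. A seeded synthetic-connectome generator emulates the reciprocal
    dyadic synapse structure of TmA terminals so that all metrics are testable
    without raw reconstructions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
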