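Package: midfit
Title: Correction of Superimposed Mass Isotopologue Distributions in
    GC-APCI-MS Tracer Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 13C metabolic flux experiments measured by soft
    ionization (GC-APCI-MS) where in-source fragmentation superimposes the
    mass isotopologue distributions (MIDs) of several ion species ([M-H]+,
    [M]+, [M+H]+, [M+H3O-CH4]+) of a derivatized metabolite. Given a
    measured intensity vector across consecutive nominal masses and the
    compound's sum formula, midfit jointly (or separately) estimates the
    in-source fragment distribution and the natural-abundance-corrected
    label distribution by greedy simplex grid search on a least-squares
    residual. Includes isotope-pattern computation by convolution, a
    synthetic spectrum generator, a two-stage calibrate-then-correct
    workflow for labeled sample series, delimited table readers and
    writers, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
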