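Package: oddlipid
Title: Targeted Odd-Chain Fatty Acyl Lipidomics by Scheduled MRM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Toolkit for targeted lipidomics of odd-chain fatty acyl lipids
    on triple-quadrupole instruments. Enumerates an in-silico lipid library
    with exact elemental formulas and monoisotopic masses, derives multiple
    reaction monitoring (MRM) precursor/product ion pairs from class-specific
    fragmentation rules (ammoniated neutral losses for glycerolipids,
    carboxylate anions for glycerophospholipids, head-group and long-chain
    base fragments for sphingolipids), fits the equivalent-carbon-number
    (ECN) quadratic retention-time model and predicts retention times for
    unmeasured species, designs scheduled-MRM acquisition lists with
    abundance-weighted dwell times under a cycle-time budget, applies
    internal-standard normalization with QC coefficient-of-variation, blank
    and signal-to-noise filters, and runs the differential pipeline
    (interquartile-range filtering, log transform, Pareto scaling, Welch
    tests with Bonferroni correction, PCA, PLS-DA with VIP scores, S-plot
    and SUS-plot coordinates, volcano and Venn selection). A synthetic-data
    generator produces internal-standard panels, calibration curves and
    three-group study peak tables so every step is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
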