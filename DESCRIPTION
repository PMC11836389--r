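Package: notet
Title: Nitric Oxide Donor Kinetics, Demethylase Inhibition Modelling, and
    oxRRBS Differential Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how diazeniumdiolate (NONOate) nitric oxide donors set
    steady-state free NO concentrations through first-order release and
    third-order autooxidation, converts donor-denominated IC50 values into
    NO-denominated ones, and couples simulated NO time courses to reversible
    inhibition of Fe(II)/2-oxoglutarate-dependent DNA demethylases (TET,
    ALKBH2). Also implements the downstream assay quantification used in such
    studies (four-parameter logistic dose-response fitting, MALDI adduct
    fractions, linear standard-curve calibration) and an oxidative-bisulfite
    (oxRRBS) differential-methylation stage: 5mC/5hmC beta-values from paired
    BS/oxBS counts, differential position calling with effect-size and p-value
    thresholds, CpG island/shore/shelf/open-sea and functional-element
    annotation, and promoter methylation versus expression correlation.
    Seeded generators produce synthetic dose-response tables and methylomes
    with known ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    limma,
    minpack.lm,
    S4Vectors,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
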