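Package: ptmstoich
Title: Histone PTM Stoichiometry, PRM Target Lists and SILAC Label-Swap
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for targeted and label-based proteomics of
    histone modifications and their regulators in yeast stress experiments.
    Provides monoisotopic mass arithmetic for modified peptides with a
    propionylation derivatization model and cleavage-blocking tryptic
    digestion; enumeration of differentially methylated H3K36 peptidoforms and
    generation of parallel-reaction-monitoring inclusion lists; phosphosite
    occupancy and methyl-state stoichiometry from extracted-ion-chromatogram
    areas, including multi-site and missed-cleavage grouping rules; a SILAC
    label-swap differential-abundance pipeline with filtering, median-centring
    normalization, orientation, one-sample testing and Benjamini-Hochberg
    correction, plus label incorporation and arginine-to-proline conversion
    estimators; growth-curve doubling times from the steepest sliding-window
    slope of log-transformed OD600; hypergeometric enrichment and a
    proportional-odds ordinal model for methyl-state comparisons; and seeded
    synthetic-data generators with persisted ground truth for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
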