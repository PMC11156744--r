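Package: epfscreen
Title: Bioefficacy Screening of Entomopathogenic Fungal Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening entomopathogenic fungal strain panels
    against insect pests from replicate-level bioassay and culture data.
    Implements Schneider-Orelli corrected mortality with arcsine
    transformation and CRD ANOVA/LSD comparisons, a weighted bioefficacy
    index with six-class virulence categorization, standardized PCA with
    varimax rotation for strain selection, Ward and UPGMA clustering on
    squared Euclidean distances, and an ITS-sequence pipeline (pairwise
    deletion, Tamura-Nei distances, neighbor joining, bootstrap support).
    A synthetic-data generator produces strain panels and alignments with
    known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    car,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
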