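Package: cniscore
Title: Copy Number Instability Scoring from Shallow Whole-Genome cfDNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide copy number instability (CNI) scoring of cell-free
    DNA from low-coverage whole-genome sequencing. Counts short (<170 bp)
    fragments in fixed autosomal windows, corrects GC and mappability
    biases, transforms to log2 ratios, condenses windows, computes
    per-window Z-scores against a panel of normals, and sums significant
    absolute Z-scores into a CNI-Score. Includes diagnostic cohort
    statistics (ROC/Youden analysis, cut-off sensitivity/specificity
    tables, rank-sum comparisons with Benjamini-Hochberg adjustment, a
    noncentral-t sample-size calculation), fragment-length analysis with
    the 120-150 bp short-fragment fraction, per-window alteration
    frequency tracks, and a synthetic cfDNA read-count and fragment-length
    simulator with segmental copy-number alterations so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
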