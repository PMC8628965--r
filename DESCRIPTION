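Package: shapeprobe
Title: Multi-Condition SHAPE Probing Analysis of RNA Tertiary Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-condition SHAPE (selective
    2'-hydroxyl acylation analyzed by primer extension) chemical probing of
    structured RNAs. Aggregates replicate reactivity tables with outlier
    filtering, calls differential reactivity between conditions (magnesium
    titration, temperature series) with a two-criterion threshold plus Welch
    t-test, clusters per-nucleotide temperature-reactivity profiles by
    k-means with elbow-based model selection and thermal-archetype labelling,
    detects melting transitions from fluorescence melt curves, computes sugar
    pucker pseudorotation phase/amplitude and family occupancies from ring
    dihedrals, and writes pseudoknot-revealing SHAPE constraint files for
    downstream secondary-structure prediction software. Includes a
    deterministic synthetic-data generator that emulates the statistical
    structure of probing, melting and trajectory data so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
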