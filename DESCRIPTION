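Package: teomics
Title: Transposable-Element Responses to Environmental Exposure Across Omics Layers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for measuring how transposable
    elements (TEs) respond to environmental exposures across chromatin
    accessibility, transcription and DNA methylation. Provides
    RepeatMasker/GTF annotation readers with evolutionary clade
    assignment, negative-binomial differential testing with tiered
    significance calls, peak-summit-to-TE assignment with subfamily and
    class enrichment, detection and four-way classification of TE-derived
    chimeric transcripts, position-weight-matrix motif scanning with exact
    p-values and consensus conservation profiles, per-TE methylation
    aggregation with exact paired Wilcoxon contrasts, and a fully
    deterministic synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
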