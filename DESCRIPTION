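Package: mbscall
Title: Molecular-Barcode Consensus Calling and Compound-Mutation Statistics for Amplicon Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates barcoded (UMI-tagged) amplicon deep sequencing of an
    EGFR-centric hotspot panel and implements the molecular-barcoding-system
    (MBS) analysis: reads are aligned to panel amplicons, grouped into
    molecular families by barcode, and collapsed to one consensus read per
    family so that PCR and sequencing errors private to a minority of a
    family are removed.  Variants are called down to 0.5% allele frequency
    on both the consensus (MBS) and raw-read arms, recurrent systematic
    artifacts shared by more than half of a cohort are filtered, and
    replicate libraries are compared through matched/orphan bookkeeping,
    reproducibility percentages and allele-frequency correlation.  A
    statistics layer provides exact minimum-likelihood Fisher 2x2 and
    Freeman-Halton r x c tests, Pearson chi-square, and pooled t-tests from
    group summaries, applied to compound-mutation contingency tables of
    EGFR-mutant lung adenocarcinoma cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
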