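Package: medipdmr
Title: Differential Methylation Analysis for MeDIP Promoter + CpG-Island Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for calling differentially methylated regions
    (DMRs) from MeDIP-chip two-colour tiling arrays. Probe log2 IP/input ratios
    are centred by Tukey biweight-mean subtraction, scored with a windowed
    one-sided Kolmogorov-Smirnov test (P score, the -log10 p-value of a 750-bp
    window against the rest of the array), and converted into methylation peaks
    (runs of consecutive high-scoring probes, nearby peaks merged). Replicate
    peaks are intersected into sample-level consensus peaks, partitioned across
    samples into atomic regions with presence patterns, and classified into
    tissue-specific (T-DMR) and developmental-stage-specific (DS-DMR) regions,
    including adult-unmethylated versus adult-methylated groupings and
    cross-tissue overlap accounting. Each DMR is assigned a prioritised genomic
    location category (CpG-island promoter, non-CpGi promoter, intragenic or
    intergenic CpGi, and tiling-only non-CpGi categories) and summarised into
    pattern-by-category count tables. A synthetic-data generator produces
    complete ground-truthed experiments for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
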