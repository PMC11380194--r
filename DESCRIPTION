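Package: codonweave
Title: Transcriptome-Weighted Codon, Codon-Pair and Dinucleotide Usage
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes transcriptome-weighted GC, dinucleotide, junction
    dinucleotide, codon and codon-pair usage from coding sequences and
    expression (TPM) tables, following the median-sample construction used
    by codon-usage resources for embryonic mouse tissue data. Provides
    group comparison statistics (two-sided Mann-Whitney U tests with
    Bonferroni control and unequal-variance Cohen's d effect sizes),
    stage-to-stage usage deltas, cross-species usage ratios, deterministic
    synthetic-data generators with known ground truth, heatmap and bar
    chart rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    grDevices,
    grid,
    pheatmap,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
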