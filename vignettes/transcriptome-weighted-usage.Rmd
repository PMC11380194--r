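---
title: "Transcriptome-weighted usage: model, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-weighted usage: model, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonweave)
```

## The model

A transcriptome's effective usage of a sequence feature is not the
genome average: it is dominated by what the tissue expresses. For a
feature family $F$ (codons, codon pairs, dinucleotides, junction
dinucleotides) with per-gene counts $c_{gf}$ and per-gene expression
$t_g$ (TPM), the transcriptome-weighted usage is

$$u_f = \frac{\sum_g t_g\, c_{gf}}{\sum_{f'} \sum_g t_g\, c_{gf'}}
        \cdot S_F,$$

with $S_F = 1{,}000$ for codons, dinucleotides and junction
dinucleotides and $S_F = 1{,}000{,}000$ for codon pairs. Weighted
positional GC is
$\mathrm{GC}k\% = 100\,\sum_g t_g\,\mathrm{gc}k_g \big/ \sum_g t_g\,L_g$
for codon positions $k = 1,2,3$ (where $L_g$ is the gene's codon count),
and overall $\mathrm{GC}\% = (\mathrm{GC1}\% + \mathrm{GC2}\% +
\mathrm{GC3}\%)/3$, an exact identity because the three positions share
the denominator.

For a group of samples — one strain, tissue and Theiler stage — the
published quantity is **median-first**: a virtual median sample (the
per-gene median TPM over the group, averaging the two central order
statistics for even group sizes) is built first and then weighted. The
alternative weight-first order (per-feature median of per-sample usage,
renormalized) is exposed via `group_usage(..., order = "weight_first")`
for sensitivity checks, but the median-first order is the convention all
outputs follow. Per-sample usage exists separately because the
comparison statistics need sample-level distributions.

### Counting conventions

* Frame 0 is assumed; sequences whose length is not a multiple of 3 are
  rejected at validation, never trimmed, and no ORF re-detection is
  attempted.
* Stop codons are counted like any other codon, in both the codon and
  codon-pair families.
* Codon pairs are the overlapping adjacent in-frame hexamers: a CDS of
  $L$ codons yields $L-1$ pairs.
* The dinucleotide family counts **every** overlapping base pair
  (length − 1 windows), codon junctions included; junction dinucleotides
  (last base of codon $i$, first base of codon $i+1$) are reported as
  their own family. This makes the subset property — junction counts
  never exceed dinucleotide counts, per key — a testable invariant and
  matches the two families being displayed as separate panels.
* `N` bases: windows containing an `N` are skipped, shrinking that
  gene's effective totals; genes with more than 5% `N` (configurable via
  `cds_policy()`) are rejected. This avoids inventing imputation. For
  positional GC an `N` counts as non-GC.
* Feature keys are ordered lexicographically with A < C < G < T in every
  matrix and output header.
* One transcript per gene is expected (RefSeq-Select-style input);
  duplicate ids are an error, never silently merged.

### Gene reconciliation and exclusions

Count-matrix genes and expression-table genes are matched by exact
case-insensitive symbol; genes present on only one side are reported and
excluded from weighting, because silent intersection hides data loss.
The packaged exclusion list holds the 22 pseudogene symbols removed from
the embryonic mouse expression tables before weighting; exclusion is
case-insensitive and idempotent, and TPM columns are *not* renormalized
afterwards (exclusion happens post-quantification). Zero-TPM genes stay
in the dot product, contributing nothing, so gene sets remain aligned
across samples. Whether a group's weighting should use only genes
detected in that group is an open choice; all reconciled genes are used.

## Comparison statistics

Per feature and group pair, a two-sided Mann–Whitney U test on
per-sample usage. The exact null distribution is used when the pooled
sample is tie-free and $n_a + n_b \le 20$ — embryo stage groups are
small, so exactness is usually feasible — otherwise the normal
approximation with continuity and tie correction. Degenerate input (all
pooled values identical) returns $p = 1$ with a warning. Raw p-values
are thresholded at the Bonferroni level $0.05/N$ and never rescaled;
$N$ is the number of tests actually performed in the emitted table (one
usage family, one comparison design), recorded in every row. Group pairs
with too few samples are emitted with `NA` statistics rather than
dropped, so the table always accounts for the full design.

Effect size is the unequal-variance Cohen's d,
$d = (\bar a - \bar b)\big/\sqrt{(s_a^2 + s_b^2)/2}$ with $n-1$
variances. The conventional magnitude labels come with gaps between the
printed bins (0.1–0.2, 0.35–0.36, 0.9–1.0); classification must be total
and deterministic, so the package uses contiguous half-open intervals
anchored at the printed lower bounds: very small $[0, 0.2)$, small
$[0.2, 0.36)$, medium $[0.36, 0.66)$, large $[0.66, 1)$, very large
$[1, \infty)$, applied to $|d|$.

## Comparative products

Stage deltas are consecutive differences along an ordered stage
sequence; `TS00` (the catch-all token for samples without a true Theiler
stage) is dropped from delta sequences by default. Deltas telescope
(their column sums equal last − first) and negate under order reversal —
both asserted in tests. Cross-species ratios divide mouse usage by a
reference profile of the same feature space; values above one mean mouse
usage exceeds the reference. Zero reference values yield flagged `NA`s,
never infinities, and are excluded from color scaling. Heatmaps use a
sequential white–blue palette for usage, a red–yellow–green diverging
palette centered at zero for deltas, and a purple–white–blue diverging
palette centered at one for ratios; codon-pair panels can be row
min–max scaled **for display only** — written tables are never scaled.
The mapping of reference (e.g. human) tissues onto the 15 embryonic
tissue categories is user-supplied configuration, not hard-coded.

## Synthetic data: what it emulates and what it does not

`simulation_config()` fixes the study conditions the test-suite and the
acceptance script run under:

* **CDS set** — 800 genes, 80–200 codons each, per-gene codon
  composition drawn from a symmetric Dirichlet (concentration 1), so
  genes differ substantially in codon bias, as real genes do. Sequences
  are assembled codon by codon and the sampled codons are tabulated
  directly into a ground-truth count matrix, giving the counting code an
  independent target.
* **Cohort** — two groups (strains) of 10 samples. Baseline per-gene
  abundance is log-normal with sdlog 0.6 (about 1.5 orders of magnitude
  between quiet and busy genes); samples add independent log-normal
  noise with sdlog 0.3 (≈30% CV, typical of biological replicates);
  columns are rescaled to TPM (sum $10^6$), which leaves weighted usage
  untouched since the weighting normalizes per sample.
* **Effects** — a usage difference is injected by multiplying the TPM of
  the genes most enriched for the target feature (top 15% by the gene's
  own normalized usage) by a fold in one group: the same mechanism by
  which transcriptome weighting creates usage differences in real data.
  The default recovery scenario uses fold 1.2 on one codon, which at
  these noise settings yields a per-sample Cohen's d of roughly 3–5 for
  the target codon (always ≥ 2), the regime the recovery check targets.

One seed governs every draw; a fixed seed reproduces each file byte for
byte.

Because effects travel through expression, they genuinely spill into
features correlated with the target: the boosted genes carry other
codons too, and normalized usage is compositional. The truth record
marks the injected target; the calibration claim for the other features
is therefore per-feature (each non-target feature is flagged in ≤ 5% of
replicates), while the across-replicate family-wise guarantee applies to
zero-effect cohorts, where Bonferroni control caps it at the nominal 5%.
Measured at the packaged conditions: power 100% over 50 replicates,
maximum per-feature non-target rate 4%, null-cohort family-wise rate
2.5–3% over 200 replicates.

What the generator does **not** emulate: real mouse codon composition
and amino-acid constraints (no reading-frame semantics beyond frame 0,
stop codons appear internally), gene length–expression correlations,
library-preparation batch effects, and count-level sampling noise.
Passing the recovery checks therefore demonstrates that the pipeline
detects expression-mediated usage shifts of the calibrated size under
log-normal replicate noise — not that every real strain/stage difference
of that size would be detected.

## Numerical choices

* Weighted sums use matrix cross-products (BLAS accumulation); the
  normalization invariant (row sums equal the family scale) is checked
  at 1e-6 relative tolerance.
* The GC identity holds exactly by construction and is asserted at
  1e-12.
* Heatmap color breaks get a 1e-6 floor on the half-range so that
  constant matrices (all-zero deltas, all-one ratios) still render with
  the center color.
* TSV writers emit doubles with 17 significant digits, so written tables
  read back bit-identically; end-to-end CLI runs are byte-deterministic.
* Problem sizes in the test suite: 1,000 random CDS for conservation,
  50 datasets for the weighting limits, 500 draws for the exact
  Mann–Whitney cross-check, 50 shifted and 200 null cohorts for recovery
  and calibration — sizes at which each property is sharply
  distinguishable while the full suite stays fast.

## Known limitations

* No RSCU, effective number of codons, or codon-optimization scoring;
  no amino-acid-level aggregation beyond labels.
* TPM is taken as given — no quantification, no re-normalization after
  exclusions.
* The Bonferroni family is per usage family per design by default;
  pooling families into one family is a caller decision.
* `species_ratio` requires identical feature spaces and scales on both
  sides; it does not attempt unit conversion.
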