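# codonweave

Transcriptome-weighted codon, codon-pair, dinucleotide and
junction-dinucleotide usage for embryonic mouse tissue expression data.

## The problem

Codon usage bias — which synonymous codons a transcriptome actually
uses — shapes translation efficiency, transcript design and
optimization/deoptimization projects. A genome-wide codon table treats
every gene equally, but a cell's effective usage is dominated by what it
expresses. `codonweave` computes **transcriptome-weighted usage**: each
gene's per-sequence feature counts are multiplied by that gene's
expression (TPM) and summed over genes, so highly expressed genes
dominate the profile. It targets bulk RNA-seq cohorts of embryonic mouse
tissues organized by strain (C57BL/6, C57BL/6J, C57BL/6N, CD-1), tissue
(15 categories) and Theiler stage, but works for any CDS FASTA plus TPM
table.

Five usage families are computed from each coding sequence:

| family | features | per-gene total (CDS of L nt) | scale |
|---|---|---|---|
| codon | 64 triplets, frame 0 | L/3 | 1,000 |
| codon pair | 4,096 in-frame hexamers (overlapping adjacent codons) | L/3 − 1 | 1,000,000 |
| dinucleotide | 16, every overlapping base pair | L − 1 | 1,000 |
| junction dinucleotide | 16, last base of codon *i* + first base of codon *i*+1 | L/3 − 1 | 1,000 |
| positional GC | GC1/GC2/GC3 percentages | — | percent |

For a group of samples (one strain/tissue/stage), the published quantity
is **median-first**: build a median sample (per-gene median TPM across
the group), weight the counts with it (`value_f = Σ_g tpm_g ×
count_{g,f}`), then normalize codon/dinucleotide/junction usage to one
thousand and codon-pair usage to one million. Weighted positional GC is
`GCk% = 100 · Σ_g tpm_g·gck_g / Σ_g tpm_g·codons_g`, with overall GC% =
(GC1% + GC2% + GC3%)/3.

Group differences are tested per feature with a two-sided Mann–Whitney U
test on per-sample usage (exact for small tie-free samples), thresholded
at the Bonferroni level 0.05/N, with an unequal-variance Cohen's d
(`d = (m_a − m_b)/√((s_a² + s_b²)/2)`) binned into
very small / small / medium / large / very large. Comparative products:
stage-to-stage usage deltas and mouse-over-reference (e.g. human tissue)
usage ratios, each with heatmap rendering.

## Worked example

```r
library(codonweave)

# a deterministic synthetic cohort: 2 strains x 10 samples, one injected
# expression shift that raises GAA usage in CD-1
cfg <- simulation_config(
  seed = 314,
  effects = list(list(feature = "GAA", family = "codon",
                      group = "CD-1", fold = 1.2, top_fraction = 0.15)))
cds_set <- generate_cds_set(cfg)
cohort  <- generate_cohort(cfg, cds_set)

counts <- build_count_matrix(cds_set$cds, "codon")
groups <- split(cohort$meta$sample_id, cohort$meta$strain)
usage  <- group_usage(cohort$tpm, counts, groups)
round(unclass(usage)[, "GAA"], 2)
#> C57BL/6    CD-1
#>   13.83   14.63
round(attr(usage, "gc"), 2)
#>            gc   gc1   gc2   gc3
#> C57BL/6 50.00 49.73 50.07 50.19
#> CD-1    49.98 49.76 50.07 50.10

psu <- per_sample_usage(cohort$tpm, counts)
cmp <- run_comparisons(psu, cohort$meta, "within_stage_across_strains")
subset(cmp, significant,
       select = c(feature, p_raw, alpha_adjusted, cohen_d, effect_label))
#>    feature        p_raw alpha_adjusted   cohen_d effect_label
#> 33     GAA 4.330035e-05     0.00078125 -2.542169   very large
```

GAA usage in CD-1 (14.63 per thousand) exceeds C57BL/6 (13.83); of the
64 codons tested (Bonferroni threshold 0.05/64 ≈ 7.8e-4) exactly the
injected codon is flagged, with a very large effect size.

The same pipeline is scriptable from a shell via the packaged CLI
(`Rscript $(Rscript -e 'cat(system.file("cli/codonweave.R",
package="codonweave"))')`), with subcommands `count`, `usage`,
`compare`, `delta`, `ratio` and `simulate`.

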