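# Deterministic generators of synthetic CDS sets and expression cohorts
# with known ground truth. They emulate the structure of the real data
# (one CDS per gene, TPM tables, strain/tissue/stage metadata) so that
# the whole pipeline is testable without downloads; usage differences
# between groups are injected through expression shifts, the same
# mechanism by which transcriptome weighting creates them in real data.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic generators. One seed governs all
#' stochastic draws: a fixed seed yields byte-identical FASTA/TSV
#' outputs.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param length_range Range of CDS lengths in codons (inclusive).
#' @param codon_alpha Dirichlet concentration vector over the 64 codons
#'   governing per-gene codon composition (default `rep(1, 64)`: genes
#'   differ substantially in codon bias, as real genes do).
#' @param group_labels Group (strain) labels of the cohort design.
#' @param samples_per_group Samples per group.
#' @param tissue,stage Metadata values shared by all samples (the cohort
#'   emulates one tissue/stage slice).
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of the
#'   per-gene baseline abundance (sdlog 0.6 spreads genes over roughly
#'   1.5 orders of magnitude of expression).
#' @param noise_sdlog Log-normal sample-to-sample TPM dispersion (0.3
#'   corresponds to ~30% coefficient of variation between biological
#'   replicates).
#' @param effects List of effects, each a list with `feature` (a feature
#'   key, or `"gc1"`/`"gc2"`/`"gc3"`), `family` (its usage family, or
#'   `"gc"`), `group` (a group label), `fold` (multiplicative TPM shift,
#'   > 0) and optional `top_fraction` (fraction of genes most enriched
#'   for the feature that receive the shift; default 0.1).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_genes = 800L,
                              length_range = c(80L, 200L),
                              codon_alpha = rep(1, 64),
                              group_labels = c("C57BL/6", "CD-1"),
                              samples_per_group = 10L,
                              tissue = "Central Nervous System",
                              stage = "TS20",
                              abundance_meanlog = log(50),
                              abundance_sdlog = 0.6,
                              noise_sdlog = 0.3,
                              effects = list()) {
  stopifnot(n_genes >= 2, length(length_range) == 2,
            length_range[1] >= 2, length_range[2] >= length_range[1],
            length(codon_alpha) == 64, all(codon_alpha > 0),
            samples_per_group >= 1, abundance_sdlog > 0, noise_sdlog >= 0,
            length(group_labels) >= 1, !anyDuplicated(group_labels))
  for (e in effects)
    stopifnot(is.list(e), !is.null(e$feature), !is.null(e$group),
              is.numeric(e$fold), e$fold > 0)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 length_range = as.integer(length_range),
                 codon_alpha = codon_alpha, group_labels = group_labels,
                 samples_per_group = as.integer(samples_per_group),
                 tissue = tissue, stage = stage,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 noise_sdlog = noise_sdlog, effects = effects),
            class = "simulation_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Generate a synthetic CDS set
#'
#' Per gene, a codon composition is drawn from the Dirichlet
#' concentration vector and the sequence assembled codon by codon; the
#' ground-truth per-gene codon counts (tabulated from the very codons
#' sampled) are recorded alongside so that counting code can be checked
#' against them.
#'
#' @param config A [simulation_config()].
#' @param fasta_path Optional path; when given, the set is also written
#'   as FASTA (deterministic bytes for a fixed seed).
#' @return List with `cds` (list of `coding_sequence`), `truth_codon`
#'   (gene x 64 ground-truth codon count matrix) and `fasta_path`.
#' @export
generate_cds_set <- function(config, fasta_path = NULL) {
  set.seed(config$seed)
  keys <- feature_keys("codon")
  ids <- sprintf("SYNGENE%04d", seq_len(config$n_genes))
  lens <- sample(seq(config$length_range[1], config$length_range[2]),
                 config$n_genes, replace = TRUE)
  truth <- matrix(0L, config$n_genes, 64L, dimnames = list(ids, keys))
  cds <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    p <- rdirichlet1(config$codon_alpha)
    codons <- sample(keys, lens[i], replace = TRUE, prob = p)
    truth[i, ] <- tabulate(match(codons, keys), nbins = 64L)
    cds[[i]] <- structure(list(gene_id = ids[i],
                               seq = paste(codons, collapse = "")),
                          class = "coding_sequence")
  }
  if (!is.null(fasta_path)) {
    lines <- unlist(lapply(cds, function(x) c(paste0(">", x$gene_id),
                                              x$seq)))
    writeLines(lines, fasta_path)
  }
  list(cds = cds, truth_codon = truth, fasta_path = fasta_path)
}

# Per-gene enrichment score for an effect target: the gene's own
# normalized usage of the feature (or positional GC fraction).
gene_feature_score <- function(cds_set, feature, family) {
  if (identical(family, "gc") || feature %in% c("gc1", "gc2", "gc3")) {
    pg <- positional_gc_matrix(vapply(cds_set$cds, `[[`, character(1),
                                      "seq"))
    rownames(pg) <- vapply(cds_set$cds, `[[`, character(1), "gene_id")
    if (!feature %in% c("gc1", "gc2", "gc3"))
      stop("unknown GC feature: ", feature)
    return(pg[, feature] / pg[, "codons"])
  }
  fam <- if (is.null(family)) {
    w <- nchar(feature)
    if (w == 3L) "codon" else if (w == 6L) "codon_pair" else "dinucleotide"
  } else family
  keys <- feature_keys(fam)
  if (!feature %in% keys)
    stop("effect references unknown feature '", feature, "' of family ",
         fam)
  m <- build_count_matrix(cds_set$cds, fam)
  unclass(m)[, feature] / pmax(rowSums(unclass(m)), 1L)
}

#' Generate a synthetic expression cohort
#'
#' Baseline per-gene abundance is log-normal; each sample adds
#' independent log-normal noise; each configured effect multiplies the
#' TPM of the genes most enriched for its target feature (top
#' `top_fraction`, by the gene's own normalized usage) in the samples of
#' its target group. Columns are then rescaled to sum to one million
#' (TPM); transcriptome-weighted usage is invariant to this per-sample
#' rescaling, so the injected usage shifts are preserved exactly. A
#' truth record lists which features truly differ between which groups.
#'
#' @param config A [simulation_config()].
#' @param cds_set Output of [generate_cds_set()] (same config).
#' @return List with `tpm` (genes x samples), `meta` (metadata
#'   data.frame) and `truth` (data.frame: feature, family, group, fold,
#'   n_genes_shifted, genes).
#' @export
generate_cohort <- function(config, cds_set) {
  set.seed(config$seed + 1L)
  ids <- vapply(cds_set$cds, `[[`, character(1), "gene_id")
  n_g <- length(ids)
  groups <- config$group_labels
  n_s <- length(groups) * config$samples_per_group
  sample_ids <- sprintf("S%03d", seq_len(n_s))
  sample_group <- rep(groups, each = config$samples_per_group)
  meanlog <- stats::rnorm(n_g, config$abundance_meanlog,
                          config$abundance_sdlog)
  tpm <- exp(meanlog +
             matrix(stats::rnorm(n_g * n_s, 0, config$noise_sdlog),
                    n_g, n_s))
  dimnames(tpm) <- list(ids, sample_ids)
  truth <- NULL
  for (e in config$effects) {
    if (!e$group %in% groups)
      stop("effect references unknown group: ", e$group)
    top_fraction <- if (is.null(e$top_fraction)) 0.1 else e$top_fraction
    score <- gene_feature_score(cds_set, e$feature, e$family)
    n_top <- max(1L, ceiling(top_fraction * n_g))
    top <- names(sort(score, decreasing = TRUE))[seq_len(n_top)]
    cols <- sample_ids[sample_group == e$group]
    tpm[top, cols] <- tpm[top, cols] * e$fold
    truth <- rbind(truth, data.frame(
      feature = e$feature,
      family = if (is.null(e$family)) NA_character_ else e$family,
      group = e$group, fold = e$fold, n_genes_shifted = n_top,
      genes = paste(top, collapse = ";"), stringsAsFactors = FALSE))
  }
  tpm <- sweep(tpm, 2L, colSums(tpm), `/`) * 1e6
  meta <- data.frame(sample_id = sample_ids, strain = sample_group,
                     tissue = config$tissue, theiler_stage = config$stage,
                     embryonic_day = NA_character_,
                     stringsAsFactors = FALSE)
  list(tpm = tpm, meta = meta,
       truth = if (is.null(truth))
         data.frame(feature = character(0), family = character(0),
                    group = character(0), fold = numeric(0),
                    n_genes_shifted = integer(0), genes = character(0),
                    stringsAsFactors = FALSE)
       else truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits the same dialects the real pipeline consumes: `genes.fasta`,
#' `expression.tsv`, `metadata.tsv` and `truth.tsv`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named vector of the paths written.
#' @export
write_synthetic_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(out_dir, "genes.fasta"),
             expression = file.path(out_dir, "expression.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  cds_set <- generate_cds_set(config, fasta_path = paths[["fasta"]])
  cohort <- generate_cohort(config, cds_set)
  write_expression(cohort$tpm, paths[["expression"]])
  utils::write.table(cohort$meta, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
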