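# Transcriptome weighting: dot product of per-gene counts with TPM,
# normalization to the family scale, and weighted positional GC.

#' Reconcile gene sets between a count matrix and an expression table
#'
#' Exact case-insensitive symbol matching. Genes present on only one side
#' are reported and excluded from weighting; silent intersection would
#' hide data loss.
#'
#' @param count_ids Gene ids of the count matrix.
#' @param expr_ids Gene ids of the expression table (or TPM vector names).
#' @param quiet Suppress the log message.
#' @return data.frame with columns `count_id`, `expr_id` (matched pairs).
#' @export
reconcile_genes <- function(count_ids, expr_ids, quiet = FALSE) {
  idx <- match(toupper(count_ids), toupper(expr_ids))
  matched <- !is.na(idx)
  if (!quiet) {
    lost_counts <- sum(!matched)
    lost_expr <- length(expr_ids) - sum(matched)
    if (lost_counts > 0 || lost_expr > 0)
      message("reconcile_genes: ", sum(matched), " matched; ",
              lost_counts, " count-only and ", lost_expr,
              " expression-only gene(s) excluded from weighting")
  }
  data.frame(count_id = count_ids[matched],
             expr_id = expr_ids[idx[matched]],
             stringsAsFactors = FALSE)
}

#' Transcriptome-weighted feature counts
#'
#' For each feature f, the weighted count is `sum_g tpm_g * counts_{g,f}`:
#' each gene's per-sequence counts scaled by its expression and summed
#' over genes, so highly expressed genes dominate. Zero-TPM genes remain
#' in the dot product (contributing nothing), keeping gene sets aligned
#' across samples.
#'
#' @param tpm_vector Named numeric vector, gene -> TPM.
#' @param counts A `count_matrix` from [build_count_matrix()].
#' @param quiet Suppress reconciliation logging.
#' @return Named numeric vector, feature -> weighted count.
#' @export
weighted_counts <- function(tpm_vector, counts, quiet = FALSE) {
  map <- reconcile_genes(rownames(counts), names(tpm_vector), quiet = quiet)
  if (nrow(map) == 0L)
    stop("weighted_counts: no overlapping genes between counts and ",
         "expression")
  w <- tpm_vector[map$expr_id]
  drop(crossprod(unclass(counts)[map$count_id, , drop = FALSE], w))
}

#' Normalize weighted counts to a family scale
#'
#' Scales a weighted feature vector so that it sums to 1,000 (codon,
#' dinucleotide, junction-dinucleotide families) or 1,000,000 (codon
#' pairs); proportions are preserved.
#'
#' @param weighted Named numeric vector of weighted counts.
#' @param scale Target total (use [family_scale()]).
#' @return Named numeric vector summing to `scale`.
#' @export
normalize_usage <- function(weighted, scale) {
  total <- sum(weighted)
  if (!is.finite(total) || total <= 0)
    stop("normalize_usage: total weighted count is ", total,
         "; nothing to normalize")
  weighted / total * scale
}

#' Transcriptome-weighted GC percentages
#'
#' Weighted positional GC: `gck% = 100 * sum_g tpm_g * gck_g / sum_g
#' tpm_g * codons_g` for codon positions k = 1, 2, 3, and overall
#' `gc% = (gc1% + gc2% + gc3%) / 3` (an exact identity, since each codon
#' contributes three positions).
#'
#' @param tpm_vector Named numeric vector, gene -> TPM.
#' @param codon_matrix A codon-family `count_matrix` (its `positional_gc`
#'   attribute is used).
#' @param quiet Suppress reconciliation logging.
#' @return Named numeric vector `(gc, gc1, gc2, gc3)` of percentages.
#' @export
weighted_gc <- function(tpm_vector, codon_matrix, quiet = FALSE) {
  pg <- attr(codon_matrix, "positional_gc")
  if (is.null(pg))
    stop("weighted_gc: count matrix has no positional_gc ",
         "(codon family required)")
  map <- reconcile_genes(rownames(pg), names(tpm_vector), quiet = quiet)
  if (nrow(map) == 0L)
    stop("weighted_gc: no overlapping genes")
  w <- tpm_vector[map$expr_id]
  agg <- drop(crossprod(pg[map$count_id, , drop = FALSE], w))
  if (agg[["codons"]] <= 0)
    stop("weighted_gc: zero weighted codon total")
  pct <- 100 * agg[c("gc1", "gc2", "gc3")] / agg[["codons"]]
  c(gc = mean(pct), gc1 = unname(pct[1L]), gc2 = unname(pct[2L]),
    gc3 = unname(pct[3L]))
}

new_usage_matrix <- function(values, family, gc = NULL) {
  structure(values, family = family, scale = family_scale(family),
            gc = gc, class = c("usage_matrix", class(values)))
}

#' @export
print.usage_matrix <- function(x, ...) {
  cat(sprintf("<usage_matrix> %s family, %d row(s) x %d feature(s), scale %g\n",
              attr(x, "family"), nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

#' Per-sample transcriptome-weighted usage
#'
#' One normalized [weighted_counts()] row per sample of the expression
#' table — the sample-level distributions the comparison statistics
#' operate on. For the codon family, weighted GC percentages per sample
#' are attached as the `gc` attribute.
#'
#' @param tpm Genes-by-samples matrix.
#' @param counts A `count_matrix`.
#' @return A `usage_matrix` (samples x features), attributes `family`,
#'   `scale` and (codon family) `gc`.
#' @export
per_sample_usage <- function(tpm, counts) {
  family <- attr(counts, "family")
  map <- reconcile_genes(rownames(counts), rownames(tpm))
  if (nrow(map) == 0L)
    stop("per_sample_usage: no overlapping genes")
  w <- tpm[map$expr_id, , drop = FALSE]
  raw <- crossprod(unclass(counts)[map$count_id, , drop = FALSE], w)
  totals <- colSums(raw)
  if (any(totals <= 0))
    stop("per_sample_usage: zero weighted total for sample(s): ",
         paste(colnames(tpm)[totals <= 0], collapse = ", "))
  vals <- t(raw) / totals * family_scale(family)
  gc <- NULL
  if (family == "codon") {
    gc <- t(vapply(colnames(tpm), function(s)
      weighted_gc(tpm[, s], counts, quiet = TRUE), numeric(4)))
  }
  new_usage_matrix(vals, family, gc = gc)
}

#' Group-level transcriptome-weighted usage
#'
#' For each group the published quantity is computed median-first: build
#' the group's median sample, weight the counts by it, then normalize.
#' `order = "weight_first"` instead takes the per-feature median of the
#' per-sample usage rows and renormalizes — useful for sensitivity
#' checks, but not the default convention.
#'
#' @param tpm Genes-by-samples matrix.
#' @param counts A `count_matrix`.
#' @param groups Named list, group label -> sample ids (see
#'   [group_samples()]).
#' @param order `"median_first"` (default) or `"weight_first"`.
#' @return A `usage_matrix` (groups x features) with `gc` attribute for
#'   the codon family.
#' @export
group_usage <- function(tpm, counts, groups,
                        order = c("median_first", "weight_first")) {
  order <- match.arg(order)
  family <- attr(counts, "family")
  empty <- names(groups)[lengths(groups) == 0L]
  if (length(empty) > 0)
    stop("group_usage: empty group(s): ", paste(empty, collapse = ", "))
  keys <- feature_keys(family)
  vals <- matrix(NA_real_, length(groups), length(keys),
                 dimnames = list(names(groups), keys))
  gc <- if (family == "codon")
    matrix(NA_real_, length(groups), 4L,
           dimnames = list(names(groups), c("gc", "gc1", "gc2", "gc3")))
  for (g in names(groups)) {
    if (order == "median_first") {
      med <- median_sample(tpm, groups[[g]])
      vals[g, ] <- normalize_usage(
        weighted_counts(med, counts, quiet = TRUE), family_scale(family))
      if (family == "codon") gc[g, ] <- weighted_gc(med, counts, quiet = TRUE)
    } else {
      psu <- per_sample_usage(tpm[, groups[[g]], drop = FALSE], counts)
      med <- apply(unclass(psu), 2L, stats::median)
      vals[g, ] <- normalize_usage(med, family_scale(family))
      if (family == "codon")
        gc[g, ] <- apply(attr(psu, "gc"), 2L, stats::median)
    }
  }
  new_usage_matrix(vals, family, gc = gc)
}

#' Write a usage matrix (and its GC summary) as TSV
#'
#' One row per sample/group, one column per feature; the codon family
#' additionally writes a GC summary table with columns `gc`, `gc1`,
#' `gc2`, `gc3`.
#'
#' @param usage A `usage_matrix`.
#' @param path Output TSV path; the GC summary (if any) is written next to
#'   it with suffix `_gc.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_usage_tsv <- function(usage, path) {
  write_matrix_tsv(usage, path, id_col = "group")
  paths <- path
  gc <- attr(usage, "gc")
  if (!is.null(gc)) {
    gp <- sub("\\.tsv$", "_gc.tsv", path)
    write_matrix_tsv(gc, gp, id_col = "group")
    paths <- c(paths, gp)
  }
  invisible(paths)
}

#' Read a usage matrix written by [write_usage_tsv()]
#'
#' @param path TSV path (rows = groups, columns = features).
#' @param family Usage family of the table.
#' @return A `usage_matrix`.
#' @export
read_usage_tsv <- function(path, family) {
  family <- match.arg(family, USAGE_FAMILIES)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  miss <- setdiff(feature_keys(family), colnames(m))
  if (length(miss) > 0)
    stop("usage table is missing ", length(miss), " ", family,
         " feature column(s), e.g. ", paste(utils::head(miss, 3),
                                            collapse = ", "))
  new_usage_matrix(m[, feature_keys(family), drop = FALSE], family)
}
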