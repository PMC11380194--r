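# Expression-table and metadata IO, gene exclusion, grouping and the
# median-sample construction.

#' Default strain and tissue vocabularies
#'
#' The four embryonic mouse strains and fifteen generalized tissue
#' categories used by the packaged metadata vocabulary. Metadata values
#' outside the vocabulary are flagged, not rejected.
#'
#' @name vocabularies
#' @export
DEFAULT_STRAINS <- c("C57BL/6", "C57BL/6J", "C57BL/6N", "CD-1")

#' @rdname vocabularies
#' @export
DEFAULT_TISSUES <- c(
  "Central Nervous System", "Eye", "Face Head & Neck", "Gonad", "Heart",
  "Kidney", "Limbs", "Liver", "Lung and Bronchus", "Pancreas",
  "Small & Large Intestine", "Spleen", "Stomach", "Thymus", "Whole Embryo"
)

#' Packaged pseudogene exclusion list
#'
#' The default gene-exclusion list: 22 pseudogene symbols identified from
#' C57BL/6NJ strain pseudogene annotation, removed from expression tables
#' before weighting. Matching is case-insensitive.
#'
#' @return Character vector of 22 gene symbols.
#' @export
pseudogene_exclusions <- function() {
  c("ADAM1A", "ADAM1B", "ADAM5", "ATP6AP1L", "FADS2B", "FER1L4", "GGNBP1",
    "GLRA4", "GLYCAM1", "GUCY1B2", "LY6G6E", "MFSD13B", "MPTX1", "NPY6R",
    "OFCC1", "SERHL", "SMPD5", "TDH", "TMCO5B", "TMEM198B", "TRPC2", "UOX")
}

#' Read a gene-exclusion list (one symbol per line)
#'
#' @param path Text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return Character vector of unique symbols.
#' @export
read_exclusion_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Read an expression (TPM) table
#'
#' Reads a genes-by-samples TSV or CSV (optionally gzipped): first column =
#' gene identifier, remaining columns = samples. Values must be finite and
#' nonnegative; duplicated gene rows are an error.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return Numeric matrix (genes x samples) with gene ids as rownames.
#' @export
read_expression <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  if (is.null(sep)) {
    con <- file(path, "r")
    on.exit(close(con))
    header <- readLines(con, n = 1L)
    close(con); on.exit()
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("expression table needs a gene column plus >= 1 ",
                          "sample column: ", path)
  genes <- as.character(df[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0)
    stop("duplicated gene rows in expression table: ",
         paste(dup, collapse = ", "))
  tpm <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(tpm) <- "double"
  rownames(tpm) <- genes
  if (anyNA(tpm) || any(!is.finite(tpm)) || any(tpm < 0)) {
    bad <- which(is.na(tpm) | !is.finite(tpm) | tpm < 0, arr.ind = TRUE)
    lab <- apply(utils::head(bad, 10L), 1L, function(ij)
      paste0(genes[ij[1L]], "/", colnames(tpm)[ij[2L]]))
    stop("negative or non-finite TPM values at: ",
         paste(lab, collapse = ", "),
         if (nrow(bad) > 10L) sprintf(" (and %d more)", nrow(bad) - 10L))
  }
  sdup <- unique(colnames(tpm)[duplicated(colnames(tpm))])
  if (length(sdup) > 0)
    stop("duplicated sample columns: ", paste(sdup, collapse = ", "))
  tpm
}

#' Write an expression table as TSV
#'
#' @param tpm Genes-by-samples matrix with rownames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression <- function(tpm, path) {
  write_matrix_tsv(tpm, path, id_col = "gene_id")
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `strain`, `tissue`, `theiler_stage`,
#' `embryonic_day` (the last may be empty). Strain/tissue values outside
#' the vocabulary are kept but flagged in the logical columns
#' `strain_in_vocab` / `tissue_in_vocab`. `TS00` is a permitted stage
#' token for samples without a true Theiler stage.
#'
#' @param path File path.
#' @param strains,tissues Accepted vocabularies.
#' @return data.frame of metadata.
#' @export
read_sample_metadata <- function(path, strains = DEFAULT_STRAINS,
                                 tissues = DEFAULT_TISSUES) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  need <- c("sample_id", "strain", "tissue", "theiler_stage")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (!"embryonic_day" %in% names(df)) df$embryonic_day <- NA_character_
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0)
    stop("duplicated sample_id in metadata: ", paste(dup, collapse = ", "))
  df$strain_in_vocab <- df$strain %in% strains
  df$tissue_in_vocab <- df$tissue %in% tissues
  if (any(!df$strain_in_vocab))
    message("metadata: ", sum(!df$strain_in_vocab),
            " sample(s) with out-of-vocabulary strain")
  if (any(!df$tissue_in_vocab))
    message("metadata: ", sum(!df$tissue_in_vocab),
            " sample(s) with out-of-vocabulary tissue")
  df
}

#' Remove excluded genes from an expression table
#'
#' Case-insensitive symbol matching; the number of removed rows is
#' reported. Zero matches is valid, and the operation is idempotent.
#'
#' @param tpm Genes-by-samples matrix.
#' @param exclusions Character vector of symbols (default: the packaged
#'   22-pseudogene list).
#' @return The filtered matrix.
#' @export
apply_exclusions <- function(tpm, exclusions = pseudogene_exclusions()) {
  hit <- toupper(rownames(tpm)) %in% toupper(exclusions)
  if (any(hit))
    message("apply_exclusions: removed ", sum(hit), " gene(s)")
  tpm[!hit, , drop = FALSE]
}

#' Group samples by metadata keys
#'
#' Partitions samples into disjoint groups labelled by the `|`-joined
#' values of the grouping keys. Samples with a missing or empty value for
#' any key collect into the `"unassigned"` group — reported, never
#' silently dropped.
#'
#' @param meta Metadata data.frame (see [read_sample_metadata()]).
#' @param keys Subset of `c("strain", "tissue", "theiler_stage",
#'   "embryonic_day")`.
#' @param sample_ids Optional universe of sample ids the metadata must
#'   cover (e.g. expression-table columns); unknown metadata rows error.
#' @return Named list: group label -> character vector of sample ids.
#' @export
group_samples <- function(meta, keys,
                          sample_ids = NULL) {
  keys <- match.arg(keys, c("strain", "tissue", "theiler_stage",
                            "embryonic_day"), several.ok = TRUE)
  if (!is.null(sample_ids)) {
    unknown <- setdiff(meta$sample_id, sample_ids)
    if (length(unknown) > 0)
      stop("metadata references unknown sample_id(s): ",
           paste(unknown, collapse = ", "))
    meta <- meta[meta$sample_id %in% sample_ids, , drop = FALSE]
  }
  vals <- meta[, keys, drop = FALSE]
  missing_any <- Reduce(`|`, lapply(vals, function(v) is.na(v) | !nzchar(v)))
  label <- do.call(paste, c(vals, sep = "|"))
  label[missing_any] <- "unassigned"
  groups <- split(meta$sample_id, label)
  if ("unassigned" %in% names(groups))
    message("group_samples: ", length(groups[["unassigned"]]),
            " sample(s) unassigned (missing grouping key)")
  groups[order(names(groups) == "unassigned", names(groups))]
}

#' Median sample of a group
#'
#' The virtual sample whose per-gene expression is the median TPM across
#' the group's samples; with an even number of samples the mean of the two
#' central order statistics is used (the standard convention).
#'
#' @param tpm Genes-by-samples matrix.
#' @param sample_ids Nonempty vector of sample ids present in `tpm`.
#' @return Named numeric vector, one median TPM per gene.
#' @export
median_sample <- function(tpm, sample_ids) {
  if (length(sample_ids) == 0L) stop("median_sample: empty sample set")
  miss <- setdiff(sample_ids, colnames(tpm))
  if (length(miss) > 0)
    stop("median_sample: sample id(s) not in table: ",
         paste(miss, collapse = ", "))
  sub <- tpm[, sample_ids, drop = FALSE]
  apply(sub, 1L, stats::median)
}
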