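# Counting of codons, codon pairs, dinucleotides and junction
# dinucleotides from validated coding sequences, plus positional GC.
# Word counting is delegated to Biostrings::oligonucleotideFrequency;
# windows containing a non-ACGT base (N) are thereby skipped, so the
# per-gene effective totals of N-containing genes shrink accordingly.

#' Construct a validation policy for coding sequences
#'
#' @param max_n_fraction Maximum tolerated fraction of `N` bases; sequences
#'   above it are rejected. Default 0.05.
#' @param min_length Minimum CDS length in nucleotides (default 6, i.e. two
#'   codons, the shortest sequence with a codon junction).
#' @return A `cds_policy` list.
#' @export
cds_policy <- function(max_n_fraction = 0.05, min_length = 6L) {
  stopifnot(max_n_fraction >= 0, max_n_fraction <= 1, min_length >= 3)
  structure(list(max_n_fraction = max_n_fraction,
                 min_length = as.integer(min_length)),
            class = "cds_policy")
}

#' Validate a raw coding sequence record
#'
#' Uppercases the sequence and checks that it is non-empty, at least
#' `min_length` long, a multiple of 3 in length, contains only
#' `A`/`C`/`G`/`T`/`N`, and has an `N` fraction at or below the policy
#' threshold. Frame 0 is assumed throughout: sequences failing the mod-3
#' check are rejected, never trimmed.
#'
#' @param gene_id Gene symbol or accession.
#' @param seq Nucleotide string.
#' @param policy A [cds_policy()].
#' @return A `coding_sequence` (list with `gene_id`, `seq`) on success, or
#'   a `cds_rejection` (list with `gene_id`, `reason`) on failure.
#' @examples
#' validate_cds("g1", "atggcttaa")  # accepted, uppercased
#' validate_cds("g2", "ATGGC")      # rejected: length not divisible by 3
#' @export
validate_cds <- function(gene_id, seq, policy = cds_policy()) {
  if (is.null(gene_id) || !nzchar(gene_id))
    stop("coding sequence record without an id")
  reject <- function(reason)
    structure(list(gene_id = gene_id, reason = reason),
              class = "cds_rejection")
  if (is.null(seq) || is.na(seq) || !nzchar(seq))
    return(reject("empty sequence"))
  seq <- toupper(seq)
  bad <- regmatches(seq, regexpr("[^ACGTN]", seq))
  if (length(bad) > 0)
    return(reject(sprintf("invalid character %s", bad)))
  n <- nchar(seq)
  if (n < policy$min_length)
    return(reject(sprintf("sequence shorter than %d nt", policy$min_length)))
  if (n %% 3L != 0L)
    return(reject("length not divisible by 3"))
  n_frac <- lengths(regmatches(seq, gregexpr("N", seq, fixed = TRUE))) / n
  if (n_frac > policy$max_n_fraction)
    return(reject(sprintf("N fraction %.3f exceeds %.3f",
                          n_frac, policy$max_n_fraction)))
  structure(list(gene_id = gene_id, seq = seq), class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s (%d nt, %d codons)\n",
              x$gene_id, nchar(x$seq), nchar(x$seq) %/% 3L))
  invisible(x)
}

is_cds <- function(x) inherits(x, "coding_sequence")

as_cds_seq <- function(cds) {
  if (is_cds(cds)) cds$seq
  else if (is.character(cds) && length(cds) == 1L) toupper(cds)
  else stop("expected a coding_sequence or a single sequence string")
}

# One row of family counts for a set of sequences (character vector).
# Junction dinucleotides are the dinucleotides starting at the 3rd, 6th,
# ... base, i.e. dinucleotide windows at step 3 after dropping the first
# two bases.
family_count_matrix <- function(seqs, family) {
  x <- Biostrings::DNAStringSet(seqs)
  counts <- switch(family,
    codon = Biostrings::oligonucleotideFrequency(x, width = 3L, step = 3L),
    codon_pair = Biostrings::oligonucleotideFrequency(x, width = 6L, step = 3L),
    dinucleotide = Biostrings::oligonucleotideFrequency(x, width = 2L, step = 1L),
    junction_dinucleotide = Biostrings::oligonucleotideFrequency(
      Biostrings::subseq(x, start = 3L), width = 2L, step = 3L),
    stop("unknown family: ", family)
  )
  storage.mode(counts) <- "integer"
  counts
}

count_family_single <- function(cds, family) {
  m <- family_count_matrix(as_cds_seq(cds), family)
  stats::setNames(as.integer(m[1L, ]), colnames(m))
}

#' Count features of any family in a coding sequence
#'
#' Family-generic dispatcher over [count_codons()],
#' [count_codon_pairs()], [count_dinucleotides()] and
#' [count_junction_dinucleotides()].
#'
#' @param cds A `coding_sequence` from [validate_cds()] (or a bare string).
#' @param family One of [USAGE_FAMILIES].
#' @return Named integer vector over the family's feature keys.
#' @export
count_family <- function(cds, family) {
  family <- match.arg(family, USAGE_FAMILIES)
  count_family_single(cds, family)
}

#' Count codons in a coding sequence
#'
#' Non-overlapping frame-0 triplets; all 64 keys are present (zeros
#' included) and stop codons are counted like any other codon.
#'
#' @param cds A `coding_sequence` from [validate_cds()] (or a bare string).
#' @return Named integer vector over the 64 codons.
#' @examples
#' count_codons(validate_cds("g", "ATGGCTTAA"))[c("ATG", "GCT", "TAA")]
#' @export
count_codons <- function(cds) count_family_single(cds, "codon")

#' Count codon pairs (in-frame hexamers)
#'
#' Overlapping adjacent codon pairs (codon i, codon i+1); a CDS of L
#' codons yields L - 1 pairs over the 4096 hexamer keys.
#'
#' @inheritParams count_codons
#' @return Named integer vector over the 4096 codon pairs.
#' @export
count_codon_pairs <- function(cds) count_family_single(cds, "codon_pair")

#' Count junction dinucleotides
#'
#' For each adjacent codon pair, the dinucleotide spanning the codon
#' boundary (last base of codon i, first base of codon i+1).
#'
#' @inheritParams count_codons
#' @return Named integer vector over the 16 dinucleotides.
#' @examples
#' count_junction_dinucleotides(validate_cds("g", "ATGGCTTAA"))[c("GG", "TT")]
#' @export
count_junction_dinucleotides <- function(cds)
  count_family_single(cds, "junction_dinucleotide")

#' Count overlapping dinucleotides
#'
#' Every adjacent base pair across the whole CDS (length - 1 windows),
#' codon junctions included; junction-dinucleotide counts are therefore a
#' per-key subset of these counts.
#'
#' @inheritParams count_codons
#' @return Named integer vector over the 16 dinucleotides.
#' @export
count_dinucleotides <- function(cds) count_family_single(cds, "dinucleotide")

#' G/C counts by codon position
#'
#' Counts of G or C bases at codon positions 1, 2 and 3, plus the codon
#' count. Percentages (GC1/GC2/GC3) are computed downstream, after
#' transcriptome weighting. `N` bases count as non-GC.
#'
#' @inheritParams count_codons
#' @return Named integer vector `(gc1, gc2, gc3, codons)`.
#' @examples
#' gc_by_position(validate_cds("g", "ATGGCT"))  # 1, 1, 1, 2
#' @export
gc_by_position <- function(cds) {
  seq <- as_cds_seq(cds)
  positional_gc_matrix(seq)[1L, ]
}

positional_gc_matrix <- function(seqs) {
  out <- matrix(0L, nrow = length(seqs), ncol = 4L,
                dimnames = list(NULL, c("gc1", "gc2", "gc3", "codons")))
  for (i in seq_along(seqs)) {
    b <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    gc <- b == "G" | b == "C"
    pos <- rep_len(1:3, length(b))
    out[i, 1:3] <- vapply(1:3, function(p) sum(gc[pos == p]), integer(1))
    out[i, 4L] <- length(b) %/% 3L
  }
  out
}

#' Build a gene-by-feature count matrix
#'
#' Stacks per-gene counts of one family into a matrix with genes as rows
#' (input order preserved) and feature keys as columns. For the codon
#' family, per-gene positional G/C counts are attached as the
#' `positional_gc` attribute (columns `gc1`, `gc2`, `gc3`, `codons`).
#'
#' @param cds_set List of `coding_sequence` objects (unique gene ids).
#' @param family One of [USAGE_FAMILIES].
#' @return Integer matrix of class `count_matrix` with attributes `family`
#'   and, for codons, `positional_gc`.
#' @export
build_count_matrix <- function(cds_set, family) {
  family <- match.arg(family, USAGE_FAMILIES)
  if (length(cds_set) > 0 && is_cds(cds_set)) cds_set <- list(cds_set)
  ids <- vapply(cds_set, function(x) x$gene_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate gene_id in CDS set: ", paste(dup, collapse = ", "))
  keys <- feature_keys(family)
  if (length(cds_set) == 0L) {
    message("build_count_matrix: empty gene set (0 x ", length(keys),
            " matrix)")
    counts <- matrix(integer(0), nrow = 0L, ncol = length(keys),
                     dimnames = list(character(0), keys))
  } else {
    seqs <- vapply(cds_set, function(x) x$seq, character(1))
    counts <- family_count_matrix(seqs, family)
    rownames(counts) <- ids
  }
  structure(counts, family = family, class = c("count_matrix", class(counts)),
            positional_gc = if (family == "codon" && length(cds_set) > 0) {
              pg <- positional_gc_matrix(vapply(cds_set, `[[`, character(1),
                                                "seq"))
              rownames(pg) <- ids
              pg
            } else if (family == "codon") {
              matrix(integer(0), 0L, 4L,
                     dimnames = list(NULL, c("gc1", "gc2", "gc3", "codons")))
            })
}

#' Read and validate coding sequences from a FASTA file
#'
#' Reads a (possibly gzipped) FASTA of one CDS per gene, validates every
#' record against the policy and partitions records into accepted
#' `coding_sequence`s and rejections.
#'
#' @param path FASTA file path.
#' @param policy A [cds_policy()].
#' @return List with `cds` (list of `coding_sequence`), `rejected` (list of
#'   rejections) and `n_input`.
#' @export
read_cds_fasta <- function(path, policy = cds_policy()) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA input: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  recs <- mapply(validate_cds, ids, seqs,
                 MoreArgs = list(policy = policy), SIMPLIFY = FALSE)
  ok <- vapply(recs, is_cds, logical(1))
  if (any(!ok)) {
    rej <- recs[!ok]
    message(length(rej), " record(s) rejected: ",
            paste(vapply(rej, function(r)
              paste0(r$gene_id, " (", r$reason, ")"), character(1)),
              collapse = "; "))
  }
  list(cds = unname(recs[ok]), rejected = unname(recs[!ok]),
       n_input = length(set))
}

#' Write per-family count matrices as TSV
#'
#' One file per family (`counts_<family>.tsv`), header row = feature keys
#' in lexicographic A<C<G<T order, first column `gene_id`; the codon file
#' is accompanied by `gc_positional.tsv`.
#'
#' @param cds_set List of `coding_sequence` objects.
#' @param out_dir Output directory (created if needed).
#' @param families Families to write (default all four).
#' @return Invisibly, the paths written.
#' @export
write_count_tables <- function(cds_set, out_dir,
                               families = USAGE_FAMILIES) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (fam in families) {
    m <- build_count_matrix(cds_set, fam)
    p <- file.path(out_dir, paste0("counts_", fam, ".tsv"))
    write_matrix_tsv(m, p, id_col = "gene_id")
    paths <- c(paths, p)
    if (fam == "codon") {
      gp <- file.path(out_dir, "gc_positional.tsv")
      write_matrix_tsv(attr(m, "positional_gc"), gp, id_col = "gene_id")
      paths <- c(paths, gp)
    }
  }
  invisible(paths)
}

# TSV writer shared by count/usage outputs: id column first; doubles are
# written with 17 significant digits so a read-back reproduces them exactly.
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- as.data.frame(unclass(m)[, , drop = FALSE], check.names = FALSE,
                      stringsAsFactors = FALSE)
  dbl <- vapply(df, is.double, logical(1))
  df[dbl] <- lapply(df[dbl], function(x) formatC(x, digits = 17, format = "g"))
  id <- stats::setNames(data.frame(rownames(m), stringsAsFactors = FALSE),
                        id_col)
  utils::write.table(cbind(id, df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
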