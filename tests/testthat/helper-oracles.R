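# Independent brute-force oracles used to check the package's counting
# and testing code. Deliberately naive (character loops, exhaustive
# enumeration) and separate from the implementations they check.

oracle_random_cds <- function(len_nt) {
  paste(sample(c("A", "C", "G", "T"), len_nt, replace = TRUE),
        collapse = "")
}

oracle_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# Frame-0 triplet scan.
oracle_count_codons <- function(seq) {
  out <- setNames(integer(64), feature_keys("codon"))
  for (i in seq(1L, nchar(seq) - 2L, by = 3L)) {
    w <- substr(seq, i, i + 2L)
    if (w %in% names(out)) out[w] <- out[w] + 1L
  }
  out
}

# Sliding in-frame hexamer window.
oracle_count_codon_pairs <- function(seq) {
  out <- setNames(integer(4096), feature_keys("codon_pair"))
  if (nchar(seq) < 6L) return(out)
  for (i in seq(1L, nchar(seq) - 5L, by = 3L)) {
    w <- substr(seq, i, i + 5L)
    if (w %in% names(out)) out[w] <- out[w] + 1L
  }
  out
}

# Base pairs at positions (3k, 3k+1).
oracle_count_junctions <- function(seq) {
  out <- setNames(integer(16), feature_keys("junction_dinucleotide"))
  n_codons <- nchar(seq) %/% 3L
  if (n_codons < 2L) return(out)
  for (k in seq_len(n_codons - 1L)) {
    w <- substr(seq, 3L * k, 3L * k + 1L)
    if (w %in% names(out)) out[w] <- out[w] + 1L
  }
  out
}

oracle_count_dinucleotides <- function(seq) {
  out <- setNames(integer(16), feature_keys("dinucleotide"))
  for (i in seq_len(nchar(seq) - 1L)) {
    w <- substr(seq, i, i + 1L)
    if (w %in% names(out)) out[w] <- out[w] + 1L
  }
  out
}

oracle_count <- function(seq, family) {
  switch(family,
         codon = oracle_count_codons(seq),
         codon_pair = oracle_count_codon_pairs(seq),
         dinucleotide = oracle_count_dinucleotides(seq),
         junction_dinucleotide = oracle_count_junctions(seq))
}

oracle_gc_by_position <- function(seq) {
  b <- oracle_chars(seq)
  gc <- b %in% c("G", "C")
  pos <- rep_len(1:3, length(b))
  c(gc1 = sum(gc[pos == 1L]), gc2 = sum(gc[pos == 2L]),
    gc3 = sum(gc[pos == 3L]), codons = length(b) %/% 3L)
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[oracle_chars(seq)]), collapse = "")
}

# Exhaustive two-sided Mann-Whitney p: enumerate every split of the
# pooled values into groups of sizes (n_a, n_b), compute the U
# distribution, and double the smaller tail probability (capped at 1).
oracle_mw_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  obs <- oracle_mw_u(a, b)
  splits <- utils::combn(n, length(a))
  us <- apply(splits, 2L, function(idx)
    oracle_mw_u(pooled[idx], pooled[-idx]))
  lower <- mean(us <= obs)
  upper <- mean(us >= obs)
  min(1, 2 * min(lower, upper))
}

# Per-gene brute-force transcriptome weighting.
oracle_weighted_usage <- function(tpm_vec, seqs, family, scale) {
  acc <- setNames(numeric(length(feature_keys(family))),
                  feature_keys(family))
  for (g in names(seqs)) {
    acc <- acc + tpm_vec[[g]] * oracle_count(seqs[[g]], family)
  }
  acc / sum(acc) * scale
}

# Strip usage_matrix attributes, keeping only dim/dimnames, for value
# comparisons.
strip_usage <- function(m) {
  a <- unclass(m)
  attributes(a) <- attributes(a)[c("dim", "dimnames")]
  a
}
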