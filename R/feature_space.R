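#' Feature families
#'
#' The five usage families handled by the package. Four of them are count
#' families over nucleotide words (codons, codon pairs, overlapping
#' dinucleotides and junction dinucleotides); positional GC content is
#' carried alongside the codon family rather than counted as words.
#'
#' @format Character vector of the four count family names.
#' @export
USAGE_FAMILIES <- c("codon", "codon_pair", "dinucleotide",
                    "junction_dinucleotide")

BASES <- c("A", "C", "G", "T")

#' Feature keys of a usage family
#'
#' Returns the ordered feature keys for a family: 64 codons, 4096 codon
#' pairs (in-frame hexamers), or 16 dinucleotides / junction dinucleotides.
#' Keys are in lexicographic order with A < C < G < T, which is also the
#' column order of every count and usage matrix the package emits.
#'
#' @param family One of `"codon"`, `"codon_pair"`, `"dinucleotide"`,
#'   `"junction_dinucleotide"`.
#' @return Character vector of feature keys.
#' @examples
#' length(feature_keys("codon"))      # 64
#' length(feature_keys("codon_pair")) # 4096
#' @export
feature_keys <- function(family) {
  family <- match.arg(family, USAGE_FAMILIES)
  width <- switch(family,
    codon = 3L,
    codon_pair = 6L,
    dinucleotide = 2L,
    junction_dinucleotide = 2L
  )
  grid <- do.call(expand.grid,
                  c(rep(list(BASES), width), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse columns so the
  # leftmost base is the slowest-varying digit (true lexicographic order)
  do.call(paste0, rev(grid))
}

#' Normalization scale of a usage family
#'
#' Codon, dinucleotide and junction-dinucleotide usage are normalized to
#' one thousand; codon-pair usage to one million.
#'
#' @inheritParams feature_keys
#' @return Numeric scalar, 1e3 or 1e6.
#' @export
family_scale <- function(family) {
  family <- match.arg(family, USAGE_FAMILIES)
  if (family == "codon_pair") 1e6 else 1e3
}
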