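# Small in-code fixture: a handful of genes with known sequences plus a
# TPM table, reused across weighting tests.
weighting_fixture <- function(seed = 42, n_genes = 20, n_samples = 4) {
  set.seed(seed)
  seqs <- setNames(
    replicate(n_genes, oracle_random_cds(sample(8:50, 1L) * 3L)),
    paste0("gene", seq_len(n_genes)))
  cds <- mapply(validate_cds, names(seqs), seqs, SIMPLIFY = FALSE)
  tpm <- matrix(rexp(n_genes * n_samples, rate = 0.02),
                n_genes, n_samples,
                dimnames = list(names(seqs),
                                paste0("s", seq_len(n_samples))))
  list(seqs = seqs, cds = unname(cds), tpm = tpm)
}

test_that("weighted counts are the TPM-weighted sum of gene counts", {
  fx <- weighting_fixture()
  counts <- build_count_matrix(fx$cds, "codon")

  # single gene: linearity in TPM
  one <- weighted_counts(c(gene1 = 5), counts, quiet = TRUE)
  expect_equal(one, 5 * as.numeric(unclass(counts)["gene1", ]),
               ignore_attr = TRUE)

  # two genes with equal TPM: elementwise sum times TPM
  two <- weighted_counts(c(gene1 = 2, gene2 = 2), counts, quiet = TRUE)
  expect_equal(two,
               2 * as.numeric(unclass(counts)["gene1", ] +
                              unclass(counts)["gene2", ]),
               ignore_attr = TRUE)

  # full fixture against the gene-by-gene accumulation oracle
  tv <- fx$tpm[, 1L]
  got <- normalize_usage(weighted_counts(tv, counts, quiet = TRUE), 1e3)
  expect_equal(unname(got),
               unname(oracle_weighted_usage(tv, fx$seqs, "codon", 1e3)),
               tolerance = 1e-12)

  expect_error(weighted_counts(c(zzz = 1), counts, quiet = TRUE),
               "no overlapping genes")
})

test_that("normalization reaches the family scale and is scale-invariant", {
  w <- c(ATG = 5, GCT = 5, TAA = 5)
  expect_equal(unname(normalize_usage(w, 1e3)), rep(1000 / 3, 3))
  expect_equal(sum(normalize_usage(w, 1e6)), 1e6)
  expect_equal(normalize_usage(w * 17.3, 1e3), normalize_usage(w, 1e3))
  expect_error(normalize_usage(c(a = 0, b = 0), 1e3), "nothing to normalize")

  set.seed(7)
  for (i in 1:10) {
    v <- setNames(runif(4096), feature_keys("codon_pair"))
    expect_equal(sum(normalize_usage(v, 1e6)), 1e6, tolerance = 1e-6)
  }
})

test_that("weighted GC reproduces degenerate and oracle cases", {
  gg <- build_count_matrix(list(validate_cds("g", "GGGGGG")), "codon")
  expect_equal(weighted_gc(c(g = 3), gg, quiet = TRUE),
               c(gc = 100, gc1 = 100, gc2 = 100, gc3 = 100))
  at <- build_count_matrix(list(validate_cds("g", "ATATAT")), "codon")
  expect_equal(weighted_gc(c(g = 3), at, quiet = TRUE),
               c(gc = 0, gc1 = 0, gc2 = 0, gc3 = 0))

  # overall GC% equals the weighted G+C base fraction by a counting oracle
  fx <- weighting_fixture(seed = 13)
  counts <- build_count_matrix(fx$cds, "codon")
  tv <- fx$tpm[, 2L]
  got <- weighted_gc(tv, counts, quiet = TRUE)
  base_gc <- vapply(fx$seqs, function(s)
    sum(oracle_chars(s) %in% c("G", "C")), numeric(1))
  base_n <- vapply(fx$seqs, nchar, numeric(1))
  expect_equal(unname(got["gc"]),
               100 * sum(tv * base_gc) / sum(tv * base_n),
               tolerance = 1e-12)
  # positional identity holds by construction
  expect_equal(unname(got["gc"]), mean(got[c("gc1", "gc2", "gc3")]))

  expect_error(weighted_gc(tv, build_count_matrix(fx$cds, "dinucleotide")),
               "positional_gc")
})

test_that("per-sample usage equals column-wise weighting and normalizing", {
  fx <- weighting_fixture(seed = 99)
  for (fam in c("codon", "junction_dinucleotide")) {
    counts <- build_count_matrix(fx$cds, fam)
    psu <- per_sample_usage(fx$tpm, counts)
    expect_equal(rownames(psu), colnames(fx$tpm))
    expect_equal(unname(rowSums(unclass(psu))),
                 rep(family_scale(fam), ncol(fx$tpm)))
    for (s in colnames(fx$tpm))
      expect_equal(unclass(psu)[s, ],
                   normalize_usage(
                     weighted_counts(fx$tpm[, s], counts, quiet = TRUE),
                     family_scale(fam)),
                   tolerance = 1e-12)
  }
  # duplicating a sample column duplicates its usage row
  tpm2 <- cbind(fx$tpm, s1_copy = fx$tpm[, "s1"])
  counts <- build_count_matrix(fx$cds, "codon")
  psu2 <- per_sample_usage(tpm2, counts)
  expect_equal(unclass(psu2)["s1_copy", ], unclass(psu2)["s1", ])
})

test_that("group usage follows the median-first convention", {
  fx <- weighting_fixture(seed = 3, n_samples = 5)
  counts <- build_count_matrix(fx$cds, "codon")
  groups <- list(all = colnames(fx$tpm), single = "s2")
  gu <- group_usage(fx$tpm, counts, groups)

  # group of one sample reproduces that sample's per-sample usage
  psu <- per_sample_usage(fx$tpm, counts)
  expect_equal(unclass(gu)["single", ], unclass(psu)["s2", ],
               tolerance = 1e-12)

  # median-first composition by hand: median sample -> weight -> normalize
  med <- median_sample(fx$tpm, groups$all)
  byhand <- normalize_usage(weighted_counts(med, counts, quiet = TRUE), 1e3)
  expect_equal(unclass(gu)["all", ], byhand, tolerance = 1e-12)

  # identical samples: group equals any member under both orders
  same <- fx$tpm[, c(1, 1, 1)]
  colnames(same) <- paste0("r", 1:3)
  for (ord in c("median_first", "weight_first")) {
    gs <- group_usage(same, counts, list(g = colnames(same)), order = ord)
    expect_equal(unclass(gs)["g", ], unclass(psu)["s1", ],
                 tolerance = 1e-12)
  }
  expect_error(group_usage(fx$tpm, counts, list(bad = character(0))),
               "empty group")
})

test_that("TPM rescaling, uniform and single-gene limits hold", {
  fx <- weighting_fixture(seed = 77)
  for (fam in USAGE_FAMILIES) {
    counts <- build_count_matrix(fx$cds, fam)
    u1 <- per_sample_usage(fx$tpm, counts)
    u2 <- per_sample_usage(fx$tpm * 13.7, counts)
    expect_equal(unclass(u1), unclass(u2), tolerance = 1e-12)

    uniform <- fx$tpm; uniform[] <- 1
    uu <- per_sample_usage(uniform, counts)
    genome <- colSums(unclass(counts)) /
      sum(colSums(unclass(counts))) * family_scale(fam)
    expect_equal(unclass(uu)[1L, ], genome, tolerance = 1e-12)

    solo <- fx$tpm; solo[] <- 0; solo["gene3", ] <- 50
    su <- per_sample_usage(solo, counts)
    own <- unclass(counts)["gene3", ]
    expect_equal(unclass(su)[2L, ], own / sum(own) * family_scale(fam),
                 tolerance = 1e-12)
  }
})

test_that("usage tables write and read back to the same matrix", {
  fx <- weighting_fixture(seed = 21)
  counts <- build_count_matrix(fx$cds, "codon")
  gu <- group_usage(fx$tpm, counts,
                    list(A = c("s1", "s2"), B = c("s3", "s4")))
  dir <- withr::local_tempdir()
  paths <- write_usage_tsv(gu, file.path(dir, "usage_codon.tsv"))
  expect_length(paths, 2L)  # usage + GC summary
  back <- read_usage_tsv(paths[1L], "codon")
  expect_equal(strip_usage(back), strip_usage(gu), tolerance = 0)
  gc_tab <- read.delim(paths[2L])
  expect_equal(gc_tab$group, c("A", "B"))
  expect_equal(names(gc_tab), c("group", "gc", "gc1", "gc2", "gc3"))
})
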