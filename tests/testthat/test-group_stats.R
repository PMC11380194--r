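test_that("Mann-Whitney worked case and symmetry", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$p_raw, 0.1)

  same <- mann_whitney_u(c(1, 5, 9), c(9, 1, 5))
  expect_equal(same$p_raw, 1, tolerance = 1e-9)

  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
  expect_warning(deg <- mann_whitney_u(rep(2, 4), rep(2, 3)), "identical")
  expect_equal(deg$p_raw, 1)
})

test_that("exact p matches exhaustive enumeration for small samples", {
  set.seed(101)
  for (i in 1:60) {
    n_a <- sample(1:5, 1L)
    n_b <- sample(1:5, 1L)
    a <- round(rnorm(n_a), 6)
    b <- round(rnorm(n_b), 6)
    if (anyDuplicated(c(a, b))) next
    got <- mann_whitney_u(a, b)
    expect_equal(got$p_raw, oracle_mw_exact_p(a, b), tolerance = 1e-9,
                 info = sprintf("draw %d (n=%d,%d)", i, n_a, n_b))
    expect_equal(got$u_statistic, oracle_mw_u(a, b))
  }
})

test_that("U complement identity holds on random inputs", {
  set.seed(57)
  for (i in 1:25) {
    a <- rnorm(sample(2:12, 1L))
    b <- rnorm(sample(2:12, 1L))
    u_ab <- mann_whitney_u(a, b)$u_statistic
    u_ba <- mann_whitney_u(b, a)$u_statistic
    expect_equal(u_ab + u_ba, length(a) * length(b))
  }
})

test_that("ties and large samples fall back to the corrected normal", {
  a <- c(1, 2, 2, 3, 7)
  b <- c(2, 5, 6, 6, 8)
  got <- mann_whitney_u(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                      correct = TRUE))
  expect_equal(got$p_raw, ref$p.value)
  big_a <- rnorm(15); big_b <- rnorm(15)
  expect_equal(mann_whitney_u(big_a, big_b)$p_raw,
               wilcox.test(big_a, big_b, exact = FALSE,
                           correct = TRUE)$p.value)
})

test_that("Bonferroni thresholds and monotone flags", {
  expect_equal(bonferroni(runif(10))$alpha_adjusted, 0.005)
  expect_equal(bonferroni(0.03)$alpha_adjusted, 0.05)
  expect_true(bonferroni(0.03)$significant)

  # monotone: shrinking the family never turns significant into not
  set.seed(2)
  p <- runif(40, 0, 0.2)
  full <- bonferroni(p)
  sub <- bonferroni(p[1:10])
  expect_true(all(!full$significant[1:10] | sub$significant))
})

test_that("Cohen's d uses the average-variance denominator", {
  a <- c(0, 1, 2); b <- c(-1, 0, 1)  # unit variances, mean diff 1
  expect_equal(cohens_d(a, b), 1)
  expect_equal(cohens_d(b, a), -1)  # antisymmetry
  expect_equal(cohens_d(c(0, 2), c(4, 6)), -4 / sqrt(2), tolerance = 1e-12)

  # shift invariance and scale equivariance
  set.seed(8)
  x <- rnorm(9); y <- rnorm(7, 1)
  d0 <- cohens_d(x, y)
  expect_equal(cohens_d(x + 5, y + 5), d0, tolerance = 1e-12)
  expect_equal(cohens_d(3 * x, 3 * y), d0, tolerance = 1e-12)

  expect_equal(cohens_d(c(1, 1), c(1, 1)), 0)
  expect_warning(inf <- cohens_d(c(2, 2), c(1, 1)), "infinity")
  expect_equal(inf, Inf)
  expect_error(cohens_d(1, c(1, 2)), ">= 2 values")
})

test_that("effect bins reproduce the printed labels", {
  expect_equal(classify_effect(c(0.05, 0.3, 0.5, 0.8, 1.2)),
               c("very small", "small", "medium", "large", "very large"))
  # gap values resolve by the contiguous lower-anchored bins
  expect_equal(classify_effect(c(0.15, 0.355, 0.95)),
               c("very small", "small", "large"))
  expect_equal(classify_effect(-2), "very large")  # magnitude only
  expect_equal(classify_effect(c(0, 1)), c("very small", "very large"))
})

stats_fixture <- function(seed = 4, strains = c("A", "B"),
                          stages = c("TS19", "TS20"), n = 4) {
  set.seed(seed)
  meta <- expand.grid(strain = strains, theiler_stage = stages,
                      rep = seq_len(n), stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("s%02d", seq_len(nrow(meta)))
  usage <- matrix(rnorm(nrow(meta) * 3, mean = 300, sd = 5),
                  nrow(meta), 3,
                  dimnames = list(meta$sample_id, c("AAA", "AAC", "AAG")))
  psu <- structure(usage, family = "codon", scale = 1e3,
                   class = c("usage_matrix", "matrix", "array"))
  list(meta = meta, psu = psu)
}

test_that("comparison battery bookkeeping matches the design", {
  fx <- stats_fixture()
  # 2 strains x 2 stages, across strains: 2 pairs x 3 features
  cmp <- run_comparisons(fx$psu, fx$meta, "within_stage_across_strains")
  expect_equal(nrow(cmp), 6L)
  expect_equal(unique(cmp$N_tests), 6L)
  expect_equal(unique(cmp$alpha_adjusted), 0.05 / 6)
  expect_setequal(unique(cmp$group_a),
                  c("TS19|A", "TS20|A"))

  # 1 strain x 3 stages: C(3,2) = 3 stage pairs per feature
  fx3 <- stats_fixture(seed = 5, strains = "A",
                       stages = c("TS19", "TS20", "TS21"))
  cmp3 <- run_comparisons(fx3$psu, fx3$meta, "within_strain_across_stages")
  expect_equal(nrow(cmp3), 9L)
  expect_equal(sort(unique(paste(cmp3$group_a, cmp3$group_b))),
               c("A|TS19 A|TS20", "A|TS19 A|TS21", "A|TS20 A|TS21"))

  # significance flags agree with thresholding the raw p-values
  expect_equal(cmp$significant, cmp$p_raw < unique(cmp$alpha_adjusted))
  expect_equal(cmp$effect_label, classify_effect(cmp$cohen_d))
})

test_that("insufficient samples are emitted as NA rows, not dropped", {
  fx <- stats_fixture(n = 1)  # 1 sample per cell: U testable, d is not
  cmp <- run_comparisons(fx$psu, fx$meta, "within_stage_across_strains")
  expect_true(all(is.na(cmp$cohen_d)))
  expect_true(all(is.na(cmp$effect_label)))
  expect_false(any(is.na(cmp$p_raw)))
  expect_error(
    run_comparisons(fx$psu, fx$meta[1:2, ], "within_stage_across_strains"),
    "missing sample")
})

test_that("null cohorts are calibrated and shifted features recovered", {
  # one injected codon shift at the packaged study conditions
  cfg <- simulation_config(
    seed = 314,
    effects = list(list(feature = "GAA", family = "codon",
                        group = "CD-1", fold = 1.2, top_fraction = 0.15)))
  cs <- generate_cds_set(cfg)
  co <- generate_cohort(cfg, cs)
  counts <- build_count_matrix(cs$cds, "codon")
  psu <- suppressMessages(per_sample_usage(co$tpm, counts))
  cmp <- run_comparisons(psu, co$meta, "within_stage_across_strains")
  expect_true(cmp$significant[cmp$feature == "GAA"])
  expect_gte(abs(cmp$cohen_d[cmp$feature == "GAA"]), 2)

  # null cohort at the same conditions: nothing should fire (this seed)
  cfg0 <- simulation_config(seed = 314)
  cs0 <- generate_cds_set(cfg0)
  co0 <- generate_cohort(cfg0, cs0)
  psu0 <- suppressMessages(
    per_sample_usage(co0$tpm, build_count_matrix(cs0$cds, "codon")))
  cmp0 <- run_comparisons(psu0, co0$meta, "within_stage_across_strains")
  expect_equal(sum(cmp0$significant), 0L)
})
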