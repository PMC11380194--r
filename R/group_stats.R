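# Group comparison battery: two-sided Mann-Whitney U per feature,
# Bonferroni family-wise control, unequal-variance Cohen's d and effect
# classification.

#' Two-sided Mann-Whitney U test
#'
#' U statistic and two-sided p-value for two independent samples. The
#' exact null distribution is used when the pooled sample is tie-free and
#' `n_a + n_b <= exact_limit` (embryo stage groups are small, so
#' exactness is usually feasible); otherwise the normal approximation
#' with continuity and tie correction. When all pooled values are
#' identical the test is degenerate: `U = n_a * n_b / 2`, `p = 1`, with a
#' warning.
#'
#' @param a,b Numeric vectors (each nonempty).
#' @param exact_limit Largest `n_a + n_b` for which the exact distribution
#'   is used (tie-free samples only). Default 20.
#' @return List with `u_statistic` (U for sample `a`) and `p_raw`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(a, b, exact_limit = 20L) {
  if (length(a) < 1L || length(b) < 1L)
    stop("mann_whitney_u: both groups must be nonempty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    warning("mann_whitney_u: all pooled values identical; p = 1")
    return(list(u_statistic = length(a) * length(b) / 2, p_raw = 1))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && (length(a) + length(b)) <= exact_limit
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(u_statistic = unname(wt$statistic), p_raw = wt$p.value)
}

#' Bonferroni family-wise threshold and significance flags
#'
#' The family threshold is `alpha / N` for N tests; a test is significant
#' when its raw p-value is strictly below the threshold. Raw p-values are
#' thresholded, never rescaled.
#'
#' @param p_raw Numeric vector of raw p-values (N = its length).
#' @param alpha Family-wise error level (default 0.05).
#' @return List with `alpha_adjusted`, `n_tests` and logical
#'   `significant`.
#' @export
bonferroni <- function(p_raw, alpha = 0.05) {
  n <- length(p_raw)
  if (n < 1L) stop("bonferroni: empty p-value list")
  thr <- alpha / n
  list(alpha_adjusted = thr, n_tests = n,
       significant = !is.na(p_raw) & p_raw < thr)
}

#' Cohen's d with unequal variances
#'
#' Standardized mean difference using the average-variance denominator
#' `d = (mean(a) - mean(b)) / sqrt((s_a^2 + s_b^2) / 2)` with sample
#' (n - 1) variances — the form that does not assume equal group
#' variances. Zero pooled spread gives 0 for equal means and a flagged
#' signed infinity otherwise.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @return Numeric scalar.
#' @examples
#' cohens_d(c(0, 2), c(4, 6))  # -4 / sqrt(2)
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("cohens_d: both groups need >= 2 values")
  denom <- sqrt((stats::var(a) + stats::var(b)) / 2)
  num <- mean(a) - mean(b)
  if (denom == 0) {
    if (num == 0) return(0)
    warning("cohens_d: zero spread with unequal means; returning ",
            "signed infinity")
    return(sign(num) * Inf)
  }
  num / denom
}

EFFECT_BREAKS <- c(0, 0.2, 0.36, 0.66, 1.0, Inf)
EFFECT_LABELS <- c("very small", "small", "medium", "large", "very large")

#' Classify an effect size
#'
#' Magnitude bins for |d|: very small `[0, 0.2)`, small `[0.2, 0.36)`,
#' medium `[0.36, 0.66)`, large `[0.66, 1)`, very large `[1, Inf)`. The
#' conventional printed bins leave gaps (0.1-0.2, 0.35-0.36, 0.9-1.0);
#' these contiguous half-open intervals anchored at the printed lower
#' bounds make the classification total and deterministic.
#'
#' @param d Numeric vector of effect sizes (sign ignored).
#' @return Character vector of labels.
#' @examples
#' classify_effect(c(0.05, 0.3, 0.5, 0.8, 1.2))
#' @export
classify_effect <- function(d) {
  idx <- pmin(findInterval(abs(d), EFFECT_BREAKS), length(EFFECT_LABELS))
  lab <- EFFECT_LABELS[idx]
  lab[is.na(d)] <- NA_character_
  lab
}

#' Run the full comparison battery over a per-sample usage matrix
#'
#' Emits one comparison per (feature, group pair) of the chosen design:
#' `"within_strain_across_stages"` compares every pair of stages inside
#' each strain; `"within_stage_across_strains"` compares every pair of
#' strains at each stage. The Bonferroni family is the complete set of
#' performed tests in the emitted table (one usage type, one design), and
#' its size is recorded in every row. Pairs with insufficient samples are
#' emitted with statistics marked `NA`, never silently skipped (the U
#' test needs >= 1 sample per side, Cohen's d >= 2).
#'
#' @param per_sample A `usage_matrix` from [per_sample_usage()] (rows =
#'   samples).
#' @param meta Metadata data.frame covering the usage rows (columns
#'   `sample_id`, `strain`, `theiler_stage`).
#' @param design `"within_strain_across_stages"` or
#'   `"within_stage_across_strains"`.
#' @param alpha Family-wise error level (default 0.05).
#' @param features Optional subset of feature columns to test.
#' @return data.frame with one row per (feature, group pair): columns
#'   `feature`, `group_a`, `group_b`, `n_a`, `n_b`, `U`, `p_raw`,
#'   `N_tests`, `alpha_adjusted`, `significant`, `cohen_d`,
#'   `effect_label`.
#' @export
run_comparisons <- function(per_sample, meta,
                            design = c("within_strain_across_stages",
                                       "within_stage_across_strains"),
                            alpha = 0.05, features = NULL) {
  design <- match.arg(design)
  samples <- rownames(per_sample)
  miss <- setdiff(samples, meta$sample_id)
  if (length(miss) > 0)
    stop("run_comparisons: metadata missing sample(s): ",
         paste(miss, collapse = ", "))
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  if (is.null(features)) features <- colnames(per_sample)

  block_key <- if (design == "within_strain_across_stages") "strain"
               else "theiler_stage"
  pair_key <- setdiff(c("strain", "theiler_stage"), block_key)
  pairs <- list()
  for (blk in unique(meta[[block_key]])) {
    in_blk <- meta[[block_key]] == blk
    levels <- sort(unique(meta[[pair_key]][in_blk]))
    if (length(levels) < 2L) next
    cmb <- utils::combn(levels, 2L)
    for (j in seq_len(ncol(cmb))) {
      ga <- samples[in_blk & meta[[pair_key]] == cmb[1L, j]]
      gb <- samples[in_blk & meta[[pair_key]] == cmb[2L, j]]
      pairs[[length(pairs) + 1L]] <- list(
        label_a = paste(blk, cmb[1L, j], sep = "|"),
        label_b = paste(blk, cmb[2L, j], sep = "|"),
        a = ga, b = gb)
    }
  }
  if (length(pairs) == 0L)
    stop("run_comparisons: design '", design,
         "' yields no comparable group pairs")

  rows <- vector("list", length(pairs) * length(features))
  k <- 0L
  vals <- unclass(per_sample)
  for (pr in pairs) {
    for (f in features) {
      a <- vals[pr$a, f]
      b <- vals[pr$b, f]
      testable <- length(a) >= 1L && length(b) >= 1L
      if (testable) {
        mw <- suppressWarnings(mann_whitney_u(a, b))
        u <- mw$u_statistic; p <- mw$p_raw
      } else {
        u <- NA_real_; p <- NA_real_
      }
      d <- if (length(a) >= 2L && length(b) >= 2L)
        suppressWarnings(cohens_d(a, b)) else NA_real_
      k <- k + 1L
      rows[[k]] <- data.frame(
        feature = f, group_a = pr$label_a, group_b = pr$label_b,
        n_a = length(a), n_b = length(b), U = u, p_raw = p,
        cohen_d = d, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  performed <- !is.na(out$p_raw)
  bf <- bonferroni(out$p_raw[performed], alpha = alpha)
  out$N_tests <- bf$n_tests
  out$alpha_adjusted <- bf$alpha_adjusted
  out$significant <- NA
  out$significant[performed] <- bf$significant
  out$effect_label <- classify_effect(out$cohen_d)
  out[, c("feature", "group_a", "group_b", "n_a", "n_b", "U", "p_raw",
          "N_tests", "alpha_adjusted", "significant", "cohen_d",
          "effect_label")]
}

#' Write a comparison table as TSV
#'
#' @param comparisons data.frame from [run_comparisons()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_comparisons_tsv <- function(comparisons, path) {
  utils::write.table(comparisons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
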