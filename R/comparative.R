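# Comparative analyses: stage-to-stage usage deltas, cross-species usage
# ratios, and heatmap / bar chart rendering.

#' Stage-to-stage usage delta matrix
#'
#' Consecutive differences of usage along an ordered stage sequence:
#' each output row `S_i->S_{i+1}` holds `usage(S_{i+1}) - usage(S_i)`,
#' so positive values are increases in usage at the transition. `TS00`
#' (the catch-all pseudo-stage) is dropped from the sequence by default.
#' Missing intermediate stages break the chain: transitions are only
#' formed between stages adjacent in `stage_order` that are both present.
#'
#' @param usage A `usage_matrix` whose rownames are stage labels (one
#'   strain at a time; loop over strains for multi-strain inputs).
#' @param stage_order Ordered stage labels. Default: natural sort of the
#'   usage rownames.
#' @param drop_ts00 Drop the `TS00` catch-all from the sequence.
#' @return Numeric matrix of class `delta_matrix` (transitions x
#'   features) with attribute `family`.
#' @export
stage_delta <- function(usage, stage_order = NULL, drop_ts00 = TRUE) {
  if (is.null(stage_order)) stage_order <- sort_stages(rownames(usage))
  if (drop_ts00) stage_order <- setdiff(stage_order, "TS00")
  present <- stage_order[stage_order %in% rownames(usage)]
  if (length(stage_order) != length(present))
    stop("stage_delta: stage(s) absent from usage rows: ",
         paste(setdiff(stage_order, present), collapse = ", "))
  if (length(present) < 2L)
    stop("stage_delta: need at least 2 stages, got ", length(present))
  from <- present[-length(present)]
  to <- present[-1L]
  vals <- unclass(usage)[to, , drop = FALSE] -
    unclass(usage)[from, , drop = FALSE]
  rownames(vals) <- paste(from, to, sep = "->")
  structure(vals, family = attr(usage, "family"),
            class = c("delta_matrix", class(vals)))
}

# Natural Theiler-stage order: numeric suffix where available.
sort_stages <- function(stages) {
  num <- suppressWarnings(as.numeric(sub("^TS", "", stages)))
  stages[order(is.na(num), num, stages)]
}

#' Cross-species usage ratio matrix
#'
#' Elementwise ratio of a usage matrix to a reference usage profile of
#' the same feature space and scale (e.g. mouse embryo over human
#' tissue): values above one mean the row's usage exceeds the reference.
#' Features where the reference is zero are emitted as `NA` (flagged,
#' never infinity).
#'
#' @param usage A `usage_matrix` (rows = strain/stage groups).
#' @param reference Named numeric vector (feature -> usage) or a 1-row
#'   `usage_matrix`, with exactly the same feature set.
#' @return Numeric matrix of class `ratio_matrix` (same shape as
#'   `usage`).
#' @export
species_ratio <- function(usage, reference) {
  if (is.matrix(reference)) {
    if (nrow(reference) != 1L)
      stop("species_ratio: reference must be a single usage profile")
    reference <- reference[1L, ]
  }
  extra <- setdiff(names(reference), colnames(usage))
  miss <- setdiff(colnames(usage), names(reference))
  if (length(extra) > 0 || length(miss) > 0)
    stop("species_ratio: feature sets differ; missing from reference: ",
         paste(utils::head(miss, 5), collapse = ", "),
         "; extra in reference: ",
         paste(utils::head(extra, 5), collapse = ", "))
  ref <- reference[colnames(usage)]
  zero <- !is.na(ref) & ref == 0
  if (any(zero))
    message("species_ratio: ", sum(zero),
            " feature(s) with zero reference usage set to NA")
  ref[zero] <- NA_real_
  vals <- sweep(unclass(usage), 2L, ref, `/`)
  structure(vals, family = attr(usage, "family"),
            class = c("ratio_matrix", class(vals)))
}

#' Render a usage / delta / ratio heatmap
#'
#' Usage heatmaps use a sequential white-to-blue palette (darker = higher
#' usage); delta heatmaps a red-yellow-green diverging palette centered
#' at zero (green = increase, red = decrease); ratio heatmaps a
#' purple-white-blue diverging palette centered at one (blue = row usage
#' above the reference). Rows and columns keep their input order (no
#' clustering); the input matrix is never modified.
#'
#' @param matrix A usage, delta or ratio matrix (rows x features).
#' @param mode `"usage"`, `"delta"` or `"ratio"`; default guessed from
#'   the matrix class.
#' @param out_path Output file ending in `.png` or `.pdf`.
#' @param scale_rows Min-max scale each row to `[0, 1]` for display only
#'   (useful for codon-pair panels); underlying data are untouched.
#' @return Invisibly, `out_path`.
#' @export
render_heatmap <- function(matrix, mode = NULL, out_path,
                           scale_rows = FALSE) {
  if (is.null(mode))
    mode <- if (inherits(matrix, "delta_matrix")) "delta"
            else if (inherits(matrix, "ratio_matrix")) "ratio"
            else "usage"
  mode <- match.arg(mode, c("usage", "delta", "ratio"))
  if (nrow(matrix) == 0L || ncol(matrix) == 0L)
    stop("render_heatmap: empty matrix")
  vals <- unclass(matrix)[, , drop = FALSE]
  if (scale_rows) {
    rng <- apply(vals, 1L, function(x) diff(range(x, na.rm = TRUE)))
    rng[rng == 0] <- 1
    vals <- (vals - apply(vals, 1L, min, na.rm = TRUE)) / rng
  }
  n_col <- 101L
  finite <- vals[is.finite(vals)]
  if (mode == "usage") {
    pal <- grDevices::colorRampPalette(c("white", "#08306B"))(n_col)
    lo <- min(finite, 0)
    breaks <- seq(lo, max(max(finite), lo + 1e-6),
                  length.out = n_col + 1L)
  } else {
    center <- if (mode == "delta") 0 else 1
    # floor keeps breaks distinct when every value sits at the center
    half <- max(abs(finite - center), 1e-6)
    breaks <- seq(center - half, center + half, length.out = n_col + 1L)
    pal <- if (mode == "delta")
      grDevices::colorRampPalette(c("#B2182B", "#FFFFBF", "#1A9850"))(n_col)
    else
      grDevices::colorRampPalette(c("#762A83", "white", "#2166AC"))(n_col)
  }
  ext <- tolower(tools::file_ext(out_path))
  if (!ext %in% c("png", "pdf"))
    stop("render_heatmap: out_path must end in .png or .pdf")
  dir <- dirname(out_path)
  if (!dir.exists(dir)) stop("render_heatmap: unwritable path (no such ",
                             "directory): ", dir)
  ph <- pheatmap::pheatmap(
    vals, cluster_rows = FALSE, cluster_cols = FALSE, color = pal,
    breaks = breaks, fontsize_col = if (ncol(vals) > 80) 2 else 7,
    fontsize_row = 8, silent = TRUE,
    main = switch(mode, usage = "Usage", delta = "Usage change",
                  ratio = "Usage ratio"))
  if (ext == "png") {
    grDevices::png(out_path, width = 1600, height = 300 + 40 * nrow(vals),
                   res = 150)
  } else {
    grDevices::pdf(out_path, width = 11, height = 2 + 0.3 * nrow(vals))
  }
  grid::grid.newpage()
  grid::grid.draw(ph$gtable)
  grDevices::dev.off()
  invisible(out_path)
}

#' Render a grouped usage bar chart
#'
#' Grouped bars per feature, one series per row of the usage matrix (the
#' website-style codon / dinucleotide frequency chart). For the codon
#' family the weighted GC percentages (if attached) are annotated in the
#' subtitle. More than `max_rows` rows is an error — use a heatmap
#' instead.
#'
#' @param usage A `usage_matrix`.
#' @param out_path Output file ending in `.png` or `.pdf`.
#' @param max_rows Legibility cap on the number of series (default 8).
#' @return Invisibly, the ggplot object (also written to `out_path`).
#' @export
render_usage_barchart <- function(usage, out_path, max_rows = 8L) {
  if (nrow(usage) < 1L) stop("render_usage_barchart: empty usage matrix")
  if (nrow(usage) > max_rows)
    stop("render_usage_barchart: ", nrow(usage), " rows exceed the ",
         "legibility cap of ", max_rows, "; use render_heatmap() instead")
  vals <- unclass(usage)
  df <- data.frame(
    group = factor(rep(rownames(vals), ncol(vals)), levels = rownames(vals)),
    feature = factor(rep(colnames(vals), each = nrow(vals)),
                     levels = colnames(vals)),
    value = as.vector(vals))
  gc <- attr(usage, "gc")
  subtitle <- if (!is.null(gc))
    paste(vapply(rownames(gc), function(r)
      sprintf("%s: GC %.1f%% (GC1 %.1f, GC2 %.1f, GC3 %.1f)", r,
              gc[r, "gc"], gc[r, "gc1"], gc[r, "gc2"], gc[r, "gc3"]),
      character(1)), collapse = "\n")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = feature, y = value,
                                        fill = group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL,
                  y = sprintf("usage (per %g)", attr(usage, "scale")),
                  fill = NULL,
                  title = paste(attr(usage, "family"), "usage"),
                  subtitle = subtitle) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
  ggplot2::ggsave(out_path, p, width = 12,
                  height = 4 + if (is.null(subtitle)) 0 else 0.5, dpi = 150)
  invisible(p)
}
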