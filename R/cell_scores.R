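# Single-cell QC, normalization, binned-control activity scores,
# percentage-expressed specificity, differential expression and
# co-expression summaries.

#' Quality-control filter on mitochondrial fraction and library size
#'
#' Removes cells whose mitochondrial transcript fraction exceeds `mito_max`
#' or whose total counts fall below `libsize_min`; both inequalities are
#' strict (fraction exactly 0.5 and library size exactly 1500 are kept, per
#' the thresholds "> 0.5" and "< 1500"). Cells failing both criteria are
#' counted once, under the mitochondrial tally.
#'
#' @param expr A [cell_expression()] object.
#' @param mito_genes Character vector of mitochondrial gene ids; defaults to
#'   genes whose id starts with `MT-`.
#' @param mito_max Maximum allowed mitochondrial fraction (default 0.5).
#' @param libsize_min Minimum allowed library size (default 1500).
#' @return A list with `expr` (the filtered [cell_expression()]) and
#'   `report` (`n_input_cells`, `n_removed_mito`, `n_removed_libsize`,
#'   `kept_cells`, `removed_cells`).
#' @export
qc_filter <- function(expr, mito_genes = NULL, mito_max = 0.5,
                      libsize_min = 1500) {
  genes <- rownames(expr$counts)
  mito_genes <- mito_genes %||% grep("^MT-", genes, value = TRUE)
  if (!all(mito_genes %in% genes)) {
    stop_scgwas("mito_genes contains gene(s) absent from the matrix.")
  }
  libsize <- Matrix::colSums(expr$counts)
  mito <- if (length(mito_genes) > 0) {
    Matrix::colSums(expr$counts[mito_genes, , drop = FALSE])
  } else {
    numeric(ncol(expr$counts))
  }
  mito_frac <- ifelse(libsize > 0, mito / libsize, 0)
  fail_mito <- mito_frac > mito_max
  fail_lib <- libsize < libsize_min
  keep <- !(fail_mito | fail_lib)
  if (!any(keep)) stop_scgwas("Quality control removed every cell.")
  report <- list(
    n_input_cells = ncol(expr$counts),
    n_removed_mito = sum(fail_mito),
    n_removed_libsize = sum(fail_lib & !fail_mito),
    kept_cells = expr$cell_meta$cell_id[keep],
    removed_cells = expr$cell_meta$cell_id[!keep]
  )
  filtered <- cell_expression(expr$counts[, keep, drop = FALSE],
                              expr$cell_meta[keep, ])
  list(expr = filtered, report = report)
}

#' Library-size normalization: log1p counts-per-10,000
#'
#' The relative-expression transform used throughout the scoring stages:
#' each cell's counts are scaled to a library size of 10,000 and
#' log1p-transformed, making the result invariant to the cell's sequencing
#' depth.
#'
#' @param expr A [cell_expression()] object (QC applied; zero-library cells
#'   are an error).
#' @return A sparse genes x cells matrix of normalized expression.
#' @export
normalize_rle <- function(expr) {
  libsize <- Matrix::colSums(expr$counts)
  if (any(libsize == 0)) {
    stop_scgwas("Zero-library-size cell(s) present; run qc_filter first.")
  }
  scaled <- expr$counts %*% Matrix::Diagonal(x = 1e4 / libsize)
  colnames(scaled) <- colnames(expr$counts)
  log1p(scaled)
}

#' Binned-control module score per cell
#'
#' The cell activity score of a gene program: genes are binned into
#' `n_bins` by average normalized expression across cells; each program gene
#' contributes its expression minus the mean of control genes drawn from its
#' own bin (the whole bin when it holds at most `n_ctrl` genes, otherwise
#' `n_ctrl` sampled without replacement). The per-cell score is the mean
#' program expression minus the mean of the per-gene control means, so a
#' random gene set scores ~0.
#'
#' @param normalized Normalized genes x cells matrix (see
#'   [normalize_rle()]).
#' @param geneset Character vector of program gene ids; at least one must be
#'   present in the matrix.
#' @param n_bins Number of average-expression bins (default 25).
#' @param n_ctrl Control genes per program gene (default 100).
#' @param seed Integer seed for the control draws.
#' @return A tibble with `cell_id` and `score`; scoring parameters are
#'   attached as attributes.
#' @export
module_score <- function(normalized, geneset, n_bins = 25, n_ctrl = 100,
                         seed = NULL) {
  genes <- rownames(normalized)
  program <- intersect(unique(geneset), genes)
  if (length(program) == 0) {
    stop_scgwas("No program gene is present in the expression matrix.")
  }
  avg <- Matrix::rowMeans(normalized)
  bin <- dplyr::ntile(rank(avg, ties.method = "first"), n_bins)
  names(bin) <- genes
  bin_members <- split(genes, bin)
  with_seed(seed, {
    ctrl_mean <- numeric(ncol(normalized))
    for (g in program) {
      pool <- bin_members[[as.character(bin[[g]])]]
      ctrl <- if (length(pool) <= n_ctrl) pool else sample(pool, n_ctrl)
      ctrl_mean <- ctrl_mean +
        Matrix::colMeans(normalized[ctrl, , drop = FALSE])
    }
    ctrl_mean <- ctrl_mean / length(program)
    prog_mean <- Matrix::colMeans(normalized[program, , drop = FALSE])
    out <- tibble(cell_id = colnames(normalized),
                  score = as.numeric(prog_mean - ctrl_mean))
    attr(out, "n_bins") <- n_bins
    attr(out, "n_ctrl") <- n_ctrl
    attr(out, "n_program_genes") <- length(program)
    attr(out, "seed") <- seed
    out
  })
}

#' Percentage of cells expressing a gene, per cell type
#'
#' @param expr A [cell_expression()] object.
#' @param gene A gene id present in the matrix.
#' @param labels Optional per-cell labels (default: the `cell_type` column
#'   of the cell metadata).
#' @return A tibble with `cell_type`, `n_positive`, `n_cells` and `pct`
#'   (percent with count > 0, rounded to 2 decimals).
#' @export
pct_expressed <- function(expr, gene, labels = NULL) {
  if (!gene %in% rownames(expr$counts)) {
    stop_scgwas("Gene '%s' is not in the expression matrix.", gene)
  }
  labels <- labels %||% expr$cell_meta$cell_type
  positive <- as.numeric(expr$counts[gene, ]) > 0
  tibble(cell_type = labels, positive = positive) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      n_positive = sum(.data$positive),
      n_cells = dplyr::n(),
      pct = round(100 * .data$n_positive / .data$n_cells, 2),
      .groups = "drop"
    )
}

#' Differential expression between two cell groups
#'
#' Per gene, a two-sided Wilcoxon rank-sum test (default; the single-cell
#' mode) or Student's t-test (the bulk mode) on normalized values, with a
#' pseudo-counted log2 fold-change `log2((mean_a + eps) / (mean_b + eps))`
#' (`eps = 1e-9`) and Benjamini-Hochberg correction across tested genes.
#' Genes constant across both groups get `p = 1`, `log2fc = 0`.
#'
#' @param normalized Normalized genes x cells (or genes x samples) matrix.
#' @param group_a,group_b Column ids (or indices) of the two groups; each
#'   needs at least 3 columns.
#' @param method `"wilcoxon"` (default) or `"ttest"`.
#' @return A tibble with `gene_id`, `log2fc`, `p`, `fdr_q`, `direction`
#'   (`"up"` when the fold-change favors group A, else `"down"`).
#' @export
de_test <- function(normalized, group_a, group_b,
                    method = c("wilcoxon", "ttest")) {
  method <- match.arg(method)
  a <- as.matrix(normalized[, group_a, drop = FALSE])
  b <- as.matrix(normalized[, group_b, drop = FALSE])
  if (ncol(a) < 3 || ncol(b) < 3) {
    stop_scgwas("Both groups need at least 3 cells/samples.")
  }
  eps <- 1e-9
  res <- purrr::map_dfr(seq_len(nrow(a)), function(i) {
    va <- a[i, ]
    vb <- b[i, ]
    if (stats::sd(c(va, vb)) == 0) {
      return(tibble(gene_id = rownames(a)[i], log2fc = 0, p = 1))
    }
    p <- if (method == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(va, vb)$p.value)
    } else {
      # zero within-group variance with different means breaks the Welch
      # test; fall back to the rank test for such degenerate genes
      tryCatch(stats::t.test(va, vb)$p.value,
               error = function(e) {
                 suppressWarnings(stats::wilcox.test(va, vb)$p.value)
               })
    }
    tibble(gene_id = rownames(a)[i],
           log2fc = log2((mean(va) + eps) / (mean(vb) + eps)),
           p = p)
  })
  res$fdr_q <- bh_fdr(res$p)
  res$direction <- ifelse(res$log2fc > 0, "up", "down")
  res
}

#' Compare per-cell scores between two groups
#'
#' Two-sided Wilcoxon rank-sum test on the per-cell scores; invariant to
#' monotone transformations of the score. Identical constant scores give
#' `p = 1`.
#'
#' @param scores A tibble with `cell_id` and `score` (e.g. from
#'   [module_score()]), or a named numeric vector.
#' @param group_a,group_b Cell ids of the two (non-empty) groups.
#' @return The two-sided p-value.
#' @export
score_compare <- function(scores, group_a, group_b) {
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$cell_id)
  }
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop_scgwas("Both groups must be non-empty.")
  }
  va <- scores[group_a]
  vb <- scores[group_b]
  if (stats::sd(c(va, vb)) == 0) return(1)
  suppressWarnings(stats::wilcox.test(va, vb)$p.value)
}

#' Pairwise co-expression matrix for a gene set
#'
#' Pearson correlation across the given cells/samples; genes constant in
#' the group get zero rows/columns (diagonal kept at 1) with a warning.
#'
#' @param normalized Normalized genes x cells matrix.
#' @param geneset Gene ids to correlate (must be present).
#' @param group_cells Column ids of the group (>= 3).
#' @return A gene x gene correlation matrix.
#' @export
coexpression_matrix <- function(normalized, geneset, group_cells) {
  geneset <- unique(geneset)
  if (!all(geneset %in% rownames(normalized))) {
    stop_scgwas("Gene(s) absent from the matrix: %s",
                paste(setdiff(geneset, rownames(normalized)), collapse = ", "))
  }
  if (length(group_cells) < 3) {
    stop_scgwas("Need at least 3 cells/samples in the group.")
  }
  x <- t(as.matrix(normalized[geneset, group_cells, drop = FALSE]))
  const <- apply(x, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(x))
  if (any(const)) {
    warn_scgwas("%d constant gene(s); their correlations set to 0.",
                sum(const))
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  r
}
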