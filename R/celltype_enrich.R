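# Polygenic cell-type enrichment: a method-of-moments regression linking
# per-gene aggregate GWAS effect-size variance to cell-type-specific
# expression annotations, with block-bootstrap inference, plus the
# gene-property specificity regression.
#
# Model: per-SNP true effects of gene j are iid N(0, sigma_j^2) with
#   sigma_j^2 = gamma0 + sum_i gamma_i * alpha_ji,
# and the observed moment identity
#   E(sum_{i in S_j} beta_hat_i^2) = sigma_j^2 Tr(R_Sj^2) + |S_j| sigma_e^2 / n
# is inverted by ordinary least squares of (y_j - |S_j| sigma_e^2 / n) on the
# design [Tr(R^2), Tr(R^2) * alpha_j1, ..., Tr(R^2) * alpha_jK].

#' Build cell-type expression annotations from single-cell counts
#'
#' Per cell type (with at least `min_cells` cells), the annotation is the
#' mean log1p counts-per-10,000 across its cells; each gene's row is then
#' divided by its maximum across cell types so alpha lies in \[0, 1\].
#' All-zero genes are dropped.
#'
#' @param expr A [cell_expression()] object (QC-filtered counts).
#' @param min_cells Minimum cells per type (default 10); smaller types are
#'   excluded with a warning.
#' @return A tibble with `gene_id` plus one column per retained cell type;
#'   the scaling recipe is recorded in the `"provenance"` attribute.
#' @export
build_annotations <- function(expr, min_cells = 10) {
  types <- table(expr$cell_meta$cell_type)
  small <- names(types)[types < min_cells]
  if (length(small) > 0) {
    warn_scgwas("Excluded cell type(s) with fewer than %d cells: %s",
                min_cells, paste(small, collapse = ", "))
  }
  keep_types <- setdiff(names(types), small)
  if (length(keep_types) == 0) stop_scgwas("No cell type has >= min_cells cells.")
  norm <- normalize_rle(expr)
  means <- vapply(keep_types, function(tt) {
    cells <- expr$cell_meta$cell_id[expr$cell_meta$cell_type == tt]
    Matrix::rowMeans(norm[, cells, drop = FALSE])
  }, numeric(nrow(norm)))
  rowmax <- apply(means, 1, max)
  zero <- rowmax == 0
  if (any(zero)) {
    inform(sprintf("Dropped %d gene(s) with zero expression in every cell type.",
                   sum(zero)))
  }
  alpha <- means[!zero, , drop = FALSE] / rowmax[!zero]
  out <- dplyr::bind_cols(tibble(gene_id = rownames(norm)[!zero]),
                          as_tibble(alpha))
  attr(out, "provenance") <-
    "mean log1p(CP10K) per cell type, per-gene max-normalized to [0,1]"
  out
}

#' Per-gene inputs for the polygenic enrichment regression
#'
#' Computes, for every gene with mapped SNPs present in the GWAS and LD:
#' the observed sum of squared marginal effects `y_j`, the LD trace term
#' `Tr(R_Sj^2)`, the noise offset `|S_j| sigma_e^2 / n`, and the LD block
#' carrying the majority of the gene's SNPs (ties to the lower block index)
#' for block-bootstrap resampling.
#'
#' @inheritParams gene_level_stat
#' @param sigma_e2 Residual variance on the standardized scale (default 1).
#' @return A tibble with `gene_id`, `n_snps`, `y`, `trace`, `offset`,
#'   `block`.
#' @export
rolypoly_inputs <- function(gwas, ld, snpmap, sigma_e2 = 1) {
  n <- mean(gwas$n)
  beta <- setNames(gwas$beta, gwas$snp_id)
  idx <- ld_index(ld)
  map <- snpmap[snpmap$snp_id %in% gwas$snp_id, ]
  map <- dplyr::inner_join(map, idx, by = "snp_id")
  by_gene <- split(map[c("snp_id", "block", "idx")], map$gene_id)
  purrr::imap_dfr(by_gene, function(g, gene) {
    y <- sum(beta[g$snp_id]^2)
    tr <- 0
    for (b in unique(g$block)) {
      pos <- g$idx[g$block == b]
      Rsub <- ld$blocks[[b]]$R[pos, pos, drop = FALSE]
      tr <- tr + sum(Rsub^2)
    }
    counts <- table(g$block)
    major <- as.integer(names(counts)[which.max(counts)])
    tibble(gene_id = gene, n_snps = nrow(g), y = y, trace = tr,
           offset = nrow(g) * sigma_e2 / n, block = major)
  })
}

#' Fit the polygenic cell-type enrichment regression
#'
#' Estimates the intercept `gamma0` and per-cell-type coefficients `gamma`
#' by ordinary least squares of the offset-corrected per-gene sum of squared
#' marginal effects on the trace-scaled annotation design (no intercept
#' beyond the trace column). Use [block_bootstrap()] for standard errors,
#' t-statistics and one-sided enrichment p-values.
#'
#' @inheritParams rolypoly_inputs
#' @param annotations Annotation tibble (`gene_id` plus one non-negative
#'   column per cell type), e.g. from [build_annotations()].
#' @param inputs Optional precomputed [rolypoly_inputs()] table (overrides
#'   `gwas`/`ld`/`snpmap`; useful when refitting many annotation sets).
#' @return An object of class `rolypoly_fit` with elements `gamma0_hat`,
#'   `gamma_hat` (named per cell type), `per_gene` (inputs joined with
#'   annotations), `sigma_e2`, and `boot` (NULL until bootstrapped).
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
rolypoly_fit <- function(gwas = NULL, ld = NULL, snpmap = NULL, annotations,
                         sigma_e2 = 1, inputs = NULL) {
  inputs <- inputs %||% rolypoly_inputs(gwas, ld, snpmap, sigma_e2 = sigma_e2)
  ann_cols <- setdiff(names(annotations), "gene_id")
  dat <- dplyr::inner_join(inputs, annotations, by = "gene_id")
  if (nrow(dat) == 0) stop_scgwas("No gene appears in both the SNP map and the annotations.")
  A <- as.matrix(dat[ann_cols])
  X <- cbind(trace = dat$trace, dat$trace * A)
  colnames(X) <- c("(gamma0)", ann_cols)
  y_adj <- dat$y - dat$offset
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop_scgwas("Rank-deficient enrichment design (rank %d of %d; condition number %.3g). Are annotation columns constant or collinear?",
                qrX$rank, ncol(X), kappa(X))
  }
  coefs <- qr.coef(qrX, y_adj)
  structure(list(
    gamma0_hat = unname(coefs[1]),
    gamma_hat = coefs[-1],
    per_gene = dat,
    ann_cols = ann_cols,
    X = X,
    y_adj = y_adj,
    sigma_e2 = sigma_e2,
    boot = NULL
  ), class = "rolypoly_fit")
}

#' @export
print.rolypoly_fit <- function(x, ...) {
  cat(sprintf("<rolypoly_fit: %d genes, %d cell type(s); gamma0 = %.4g%s>\n",
              nrow(x$per_gene), length(x$gamma_hat), x$gamma0_hat,
              if (is.null(x$boot)) ", not bootstrapped"
              else sprintf(", %d bootstrap iterations", x$boot$n_boot)))
  invisible(x)
}

#' Block-bootstrap inference for a polygenic enrichment fit
#'
#' Resamples LD blocks (each gene travels with its majority block) with
#' replacement and refits the regression per resample. The bootstrap
#' variance is the variance over resamples scaled by `B / (B - 1)` (the
#' usual small-cluster bias correction at `B` blocks), `t = gamma_hat / se`,
#' and the one-sided upper-tail p-value uses a Student-t reference with
#' `B - 1` degrees of freedom — with a few dozen genomic blocks the block
#' count, not the gene count, sets the effective degrees of freedom, and a
#' normal reference is anti-conservative. Positive gamma means enrichment.
#' Refits reuse per-block Gram matrices, so a resample costs one small
#' linear solve.
#'
#' @param fit A [rolypoly_fit()] object.
#' @param n_boot Number of bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @return The fit with a `boot` element (`boot_se`, `t`, `p`, `n_boot`);
#'   degenerate resampling (zero bootstrap SE) yields `p = NA` with a
#'   warning.
#' @export
block_bootstrap <- function(fit, n_boot = 1000, seed = NULL) {
  blocks <- fit$per_gene$block
  ublocks <- unique(blocks)
  if (length(ublocks) < 2) {
    stop_scgwas("Block bootstrap needs at least 2 LD blocks (found %d).",
                length(ublocks))
  }
  p <- ncol(fit$X)
  # per-block Gram matrices and cross-products
  grams <- lapply(ublocks, function(b) {
    rows <- blocks == b
    Xb <- fit$X[rows, , drop = FALSE]
    list(G = crossprod(Xb), h = crossprod(Xb, fit$y_adj[rows]))
  })
  nb <- length(ublocks)
  coefs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      counts <- tabulate(sample.int(nb, nb, replace = TRUE), nbins = nb)
      G <- matrix(0, p, p)
      h <- numeric(p)
      for (b in seq_len(nb)) {
        if (counts[b] == 0) next
        G <- G + counts[b] * grams[[b]]$G
        h <- h + counts[b] * grams[[b]]$h
      }
      out <- tryCatch(solve(G, h), error = function(e) rep(NA_real_, p))
      as.numeric(out)
    }, numeric(p))
  })
  ok <- colSums(is.na(coefs)) == 0
  if (!all(ok)) {
    warn_scgwas("%d of %d bootstrap resamples were singular and dropped.",
                sum(!ok), n_boot)
    coefs <- coefs[, ok, drop = FALSE]
  }
  boot_se <- apply(coefs, 1, stats::sd) * sqrt(nb / (nb - 1))
  est <- c(fit$gamma0_hat, fit$gamma_hat)
  tstat <- est / boot_se
  pval <- stats::pt(tstat, df = nb - 1, lower.tail = FALSE)
  if (any(boot_se[-1] == 0)) {
    warn_scgwas("Degenerate block resampling: zero bootstrap SE; p set to NA.")
    tstat[boot_se == 0] <- NA_real_
    pval[boot_se == 0] <- NA_real_
  }
  names(boot_se) <- names(tstat) <- names(pval) <- c("(gamma0)", fit$ann_cols)
  fit$boot <- list(boot_se = boot_se, t = tstat, p = pval,
                   n_boot = sum(ok), n_blocks = nb, seed = seed)
  fit
}

#' Annotation-permutation p-values for a polygenic enrichment fit
#'
#' An alternative to bootstrap inference: permutes the annotation rows
#' across genes `n_perm` times, refits, and reports
#' `(1 + #\{permuted gamma >= observed\}) / (n_perm + 1)` per cell type.
#'
#' @param fit A [rolypoly_fit()] object.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A tibble with `cell_type` and `perm_p`.
#' @export
rolypoly_perm_test <- function(fit, n_perm = 1000, seed = NULL) {
  A <- as.matrix(fit$per_gene[fit$ann_cols])
  trace <- fit$per_gene$trace
  y_adj <- fit$y_adj
  obs <- fit$gamma_hat
  with_seed(seed, {
    exceed <- numeric(length(obs))
    for (i in seq_len(n_perm)) {
      Ap <- A[sample.int(nrow(A)), , drop = FALSE]
      Xp <- cbind(trace, trace * Ap)
      cf <- qr.coef(qr(Xp), y_adj)[-1]
      exceed <- exceed + (cf >= obs)
    }
    tibble(cell_type = fit$ann_cols,
           perm_p = (1 + exceed) / (n_perm + 1))
  })
}

#' Gene-property specificity regression
#'
#' For each cell type, regresses gene-level association z-scores (upper-tail
#' normal quantile of the gene p-value) on the cell type's expression
#' specificity plus log1p mean expression as a covariate, by ordinary least
#' squares; reports a one-sided p-value on the specificity coefficient and
#' its Bonferroni correction across cell types.
#'
#' @param gene_results Tibble with `gene_id` and `p` (e.g. from
#'   [gene_level_stat()]).
#' @param annotations Annotation tibble (`gene_id` + specificity columns).
#' @param mean_expr Tibble with `gene_id` and `mean_expr` (average raw
#'   expression used as the covariate).
#' @return A tibble with `cell_type`, `coefficient`, `p` (one-sided upper
#'   tail), `bonferroni_p`. Constant specificity columns are skipped with a
#'   warning.
#' @export
gene_property_enrichment <- function(gene_results, annotations, mean_expr) {
  dat <- gene_results |>
    dplyr::inner_join(annotations, by = "gene_id") |>
    dplyr::inner_join(mean_expr, by = "gene_id")
  ann_cols <- setdiff(names(annotations), "gene_id")
  z <- gene_z_from_p(dat$p)
  covar <- log1p(dat$mean_expr)
  res <- purrr::map_dfr(ann_cols, function(ct) {
    alpha <- dat[[ct]]
    if (stats::sd(alpha) == 0) {
      warn_scgwas("Cell type '%s' skipped: constant specificity column.", ct)
      return(NULL)
    }
    fit <- stats::lm(z ~ alpha + covar)
    sm <- summary(fit)$coefficients
    tval <- sm["alpha", "t value"]
    df <- fit$df.residual
    tibble(cell_type = ct, coefficient = sm["alpha", "Estimate"],
           p = stats::pt(tval, df, lower.tail = FALSE))
  })
  res$bonferroni_p <- pmin(1, res$p * nrow(res))
  res
}
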