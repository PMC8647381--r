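# Synthetic-data generators. Every generator is a pure function of its
# parameters and seed (the caller's RNG stream is left untouched), and each
# returns the planted ground truth needed by downstream recovery tests.
#
# Effects and genotypes live on the standardized scale throughout, so that
# marginal GWAS standard errors are 1/sqrt(n) and the residual variance
# sigma_e^2 of the polygenic model is 1.

#' Simulate AR(1) LD blocks
#'
#' Each block gets the autoregressive correlation structure
#' `R[i, j] = rho^|i - j|`, a standard stand-in for local LD decay.
#'
#' @param n_blocks Number of blocks.
#' @param block_size SNPs per block (recycled to length `n_blocks`).
#' @param rho AR(1) correlation, strictly inside (-1, 1).
#' @param snp_prefix Prefix for generated SNP ids.
#' @return An [ld_blocks()] object with SNPs named `<prefix><index>`.
#' @export
simulate_ld_blocks <- function(n_blocks, block_size, rho = 0,
                               snp_prefix = "rs") {
  if (abs(rho) >= 1) stop_scgwas("rho must lie strictly inside (-1, 1).")
  block_size <- rep_len(block_size, n_blocks)
  offsets <- c(0, cumsum(block_size))
  blocks <- lapply(seq_len(n_blocks), function(b) {
    k <- block_size[b]
    R <- rho^abs(outer(seq_len(k), seq_len(k), "-"))
    list(snps = paste0(snp_prefix, offsets[b] + seq_len(k)), R = R)
  })
  ld_blocks(blocks)
}

# Lower Cholesky factors for every block, with a small jitter fallback for
# numerically semi-definite R.
ld_chol <- function(ld) {
  lapply(ld$blocks, function(b) {
    L <- tryCatch(t(chol(b$R)), error = function(e) {
      t(chol(b$R + diag(1e-8, nrow(b$R))))
    })
    L
  })
}

# Draw marginal GWAS estimates given per-SNP true effects: per block,
# beta_hat ~ MVN(R beta, R / n); se = 1/sqrt(n); p is the two-sided normal
# tail of beta_hat * sqrt(n).
gwas_marginals <- function(ld, true_beta, n) {
  chols <- ld_chol(ld)
  rows <- purrr::imap_dfr(ld$blocks, function(b, i) {
    beta <- true_beta[b$snps]
    beta[is.na(beta)] <- 0
    eps <- chols[[i]] %*% rnorm(length(b$snps))
    beta_hat <- as.numeric(b$R %*% beta + eps / sqrt(n))
    tibble(snp_id = b$snps, beta = beta_hat)
  })
  z <- rows$beta * sqrt(n)
  tibble(
    snp_id = rows$snp_id,
    chrom = "1",
    pos = seq_len(nrow(rows)) * 1000L,
    effect_allele = "A",
    other_allele = "G",
    beta = rows$beta,
    se = 1 / sqrt(n),
    p = 2 * stats::pnorm(-abs(z)),
    n = as.integer(n)
  )
}

#' Simulate GWAS summary statistics under the annotation-dependent polygenic model
#'
#' True SNP effects for the SNPs of gene j are drawn iid N(0, sigma_j^2) with
#' `sigma_j^2 = gamma0 + sum_i gamma_i * alpha[j, i]`; SNPs mapped to no gene
#' get variance `gamma0`. Marginal estimates are then drawn per LD block as
#' `beta_hat ~ MVN(R beta, R / n)` with `se = 1/sqrt(n)`.
#'
#' When overlapping genes share a SNP, the effect is drawn under the first
#' mapped gene's variance.
#'
#' @param ld An [ld_blocks()] object covering every SNP in `snpmap`.
#' @param snpmap Gene-to-SNP map tibble (`gene_id`, `snp_id`).
#' @param annotations Tibble with `gene_id` plus one non-negative numeric
#'   column per cell type (the alpha matrix). Genes absent from `snpmap` are
#'   skipped with a warning.
#' @param gamma0 Intercept variance component (>= 0 for unmapped SNPs).
#' @param gamma Numeric vector of annotation coefficients, one per annotation
#'   column.
#' @param n GWAS sample size.
#' @param seed Integer seed.
#' @return A list with `gwas` (summary tibble) and `truth` (planted
#'   parameters: `gamma0`, `gamma`, `sigma_e2 = 1`, `per_gene_sigma2`,
#'   `true_beta`, `seed`).
#' @export
simulate_gwas <- function(ld, snpmap, annotations, gamma0, gamma, n, seed) {
  ann_cols <- setdiff(names(annotations), "gene_id")
  if (length(gamma) != length(ann_cols)) {
    stop_scgwas("Length of gamma (%d) must match the number of annotation columns (%d).",
                length(gamma), length(ann_cols))
  }
  A <- as.matrix(annotations[ann_cols])
  sigma2 <- as.numeric(gamma0 + A %*% gamma)
  names(sigma2) <- annotations$gene_id
  if (any(sigma2 < 0) || gamma0 < 0) {
    stop_scgwas("Negative per-gene variance: gamma0 + sum(gamma * alpha) must be >= 0 for every gene.")
  }
  missing_genes <- setdiff(annotations$gene_id, snpmap$gene_id)
  if (length(missing_genes) > 0) {
    warn_scgwas("%d annotated gene(s) missing from the SNP map were skipped.",
                length(missing_genes))
  }
  idx <- ld_index(ld)
  with_seed(seed, {
    true_beta <- setNames(numeric(nrow(idx)), idx$snp_id)
    # assign each SNP to its first mapped gene
    first_map <- snpmap[!duplicated(snpmap$snp_id), ]
    first_map <- first_map[first_map$gene_id %in% names(sigma2), ]
    sd_mapped <- sqrt(sigma2[first_map$gene_id])
    true_beta[first_map$snp_id] <- rnorm(nrow(first_map), 0, sd_mapped)
    unmapped <- setdiff(idx$snp_id, first_map$snp_id)
    if (gamma0 > 0) {
      true_beta[unmapped] <- rnorm(length(unmapped), 0, sqrt(gamma0))
    }
    gwas <- gwas_marginals(ld, true_beta, n)
    list(
      gwas = gwas,
      truth = list(gamma0 = gamma0, gamma = setNames(gamma, ann_cols),
                   sigma_e2 = 1, per_gene_sigma2 = sigma2,
                   true_beta = true_beta, seed = seed)
    )
  })
}

#' Simulate sparse eQTL weight models across tissues
#'
#' Each modeled gene receives `ceiling(sparsity * |S_j|)` SNPs with weights
#' drawn N(0, 1). Tissues beyond the first reuse each chosen (SNP, weight)
#' entry of the first tissue with probability `share_frac`, inducing
#' cross-tissue weight correlation; otherwise they draw their own.
#'
#' @param snpmap Gene-to-SNP map tibble.
#' @param tissues Character vector of tissue names.
#' @param sparsity Fraction of a gene's SNPs given non-zero weight, in (0, 1].
#' @param share_frac Fraction of entries shared with the first tissue, in
#'   \[0, 1\].
#' @param genes Optional subset of genes to model (default: all in `snpmap`).
#' @param seed Integer seed.
#' @return A tibble with columns `tissue`, `gene_id`, `snp_id`, `weight`,
#'   `effect_allele` (no zero-weight rows).
#' @export
simulate_eqtl_weights <- function(snpmap, tissues, sparsity = 0.5,
                                  share_frac = 0.5, genes = NULL, seed = 1) {
  if (sparsity <= 0 || sparsity > 1) stop_scgwas("sparsity must be in (0, 1].")
  genes <- genes %||% unique(snpmap$gene_id)
  snp_sets <- split(snpmap$snp_id, snpmap$gene_id)[genes]
  empty <- lengths(snp_sets) == 0 | vapply(snp_sets, is.null, logical(1))
  if (any(empty)) {
    warn_scgwas("%d gene(s) with no mapped SNPs were not modeled.", sum(empty))
    snp_sets <- snp_sets[!empty]
  }
  with_seed(seed, {
    purrr::imap_dfr(snp_sets, function(snps, gene) {
      k <- ceiling(sparsity * length(snps))
      base_snps <- sample(snps, k)
      base_w <- rnorm(k)
      purrr::map_dfr(seq_along(tissues), function(t) {
        if (t == 1) {
          snp <- base_snps
          w <- base_w
        } else {
          keep <- runif(k) < share_frac
          snp <- base_snps
          w <- base_w
          if (any(!keep)) {
            snp[!keep] <- sample(snps, sum(!keep))
            w[!keep] <- rnorm(sum(!keep))
          }
        }
        ok <- !duplicated(snp) & w != 0
        tibble(tissue = tissues[t], gene_id = gene, snp_id = snp[ok],
               weight = w[ok], effect_allele = "A")
      })
    })
  })
}

#' Simulate GWAS summary statistics with expression-mediated gene effects
#'
#' Inverts the transcriptome-wide association model: each SNP's true effect
#' is the weight-weighted sum `sum_g omega_ig * gamma_g` over the gene models
#' containing it, and marginal estimates are drawn as in [simulate_gwas()].
#'
#' @param weights eQTL weight tibble (a single tissue's rows are typical;
#'   all provided rows contribute).
#' @param ld An [ld_blocks()] object.
#' @param gene_effects Tibble with `gene_id` and `gamma` (effect of predicted
#'   expression on the trait); genes absent from `weights` are an error.
#' @param n GWAS sample size.
#' @param seed Integer seed.
#' @return A list with `gwas` and `truth` (`true_beta`, `gene_effects`,
#'   `seed`).
#' @export
simulate_twas_gwas <- function(weights, ld, gene_effects, n, seed) {
  missing <- setdiff(gene_effects$gene_id, weights$gene_id)
  if (length(missing) > 0) {
    stop_scgwas("gene_effects contains gene(s) not modeled in weights: %s",
                paste(missing, collapse = ", "))
  }
  contrib <- dplyr::inner_join(weights, gene_effects, by = "gene_id")
  per_snp <- dplyr::summarise(
    dplyr::group_by(contrib, .data$snp_id),
    beta = sum(.data$weight * .data$gamma), .groups = "drop"
  )
  idx <- ld_index(ld)
  true_beta <- setNames(numeric(nrow(idx)), idx$snp_id)
  true_beta[per_snp$snp_id] <- per_snp$beta
  with_seed(seed, {
    list(
      gwas = gwas_marginals(ld, true_beta, n),
      truth = list(true_beta = true_beta, gene_effects = gene_effects,
                   seed = seed)
    )
  })
}

#' Simulate cell-type-structured single-cell counts
#'
#' Counts are negative binomial with cell-type-specific means, log-normal
#' cell-specific library-size factors and a fixed dispersion. A configurable
#' number of mitochondrial genes (ids prefixed `MT-`) is included, and
#' configurable fractions of cells are planted as quality-control failures
#' (mitochondrial fraction > 0.5, or library size < 1500).
#'
#' @param celltypes Character vector of cell-type names.
#' @param n_cells_per_type Cells per type (recycled).
#' @param n_genes Total genes, including `n_mito` mitochondrial genes.
#' @param program_spec Optional tibble (`gene_id`, `cell_type`, `log2fc`)
#'   planting per-type log2 fold-changes on named program genes. Unknown
#'   genes or cell types are an error.
#' @param n_mito Number of mitochondrial genes (default 5).
#' @param base_mean Baseline per-gene mean count at library factor 1; a
#'   per-gene lognormal spread is applied (default 0.5).
#' @param dispersion Negative-binomial dispersion (1/size; default 0.5; 0
#'   gives Poisson).
#' @param libsize_sdlog SD of the log-normal library-size factors
#'   (default 0.3).
#' @param qc_fail_mito_frac Fraction of cells planted with mitochondrial
#'   fraction > 0.5 (default 0).
#' @param qc_fail_libsize_frac Fraction of cells planted with library size
#'   < 1500 (default 0).
#' @param seed Integer seed.
#' @return A list with `expr` (a [cell_expression()]) and `truth` (program
#'   table, mito gene ids, planted QC-failure cell ids, seed).
#' @export
simulate_cell_expression <- function(celltypes, n_cells_per_type, n_genes,
                                     program_spec = NULL, n_mito = 5,
                                     base_mean = 0.5, dispersion = 0.5,
                                     libsize_sdlog = 0.3,
                                     qc_fail_mito_frac = 0,
                                     qc_fail_libsize_frac = 0, seed = 1) {
  n_cells_per_type <- rep_len(n_cells_per_type, length(celltypes))
  n_ord <- n_genes - n_mito
  gene_ids <- c(sprintf("gene%04d", seq_len(n_ord)),
                if (n_mito > 0) paste0("MT-", seq_len(n_mito)))
  if (!is.null(program_spec)) {
    bad_genes <- setdiff(program_spec$gene_id, gene_ids)
    if (length(bad_genes) > 0) {
      stop_scgwas("program_spec names unknown gene(s): %s",
                  paste(bad_genes, collapse = ", "))
    }
    bad_types <- setdiff(program_spec$cell_type, celltypes)
    if (length(bad_types) > 0) {
      stop_scgwas("program_spec names unknown cell type(s): %s",
                  paste(bad_types, collapse = ", "))
    }
  }
  with_seed(seed, {
    cell_type <- rep(celltypes, n_cells_per_type)
    n_cells <- length(cell_type)
    cell_id <- sprintf("cell%05d", seq_len(n_cells))
    lib <- rlnorm(n_cells, 0, libsize_sdlog)
    base <- base_mean * rlnorm(n_genes, 0, 0.5)
    names(base) <- gene_ids
    # per-type mean matrix (genes x types)
    mu_type <- matrix(base, n_genes, length(celltypes),
                      dimnames = list(gene_ids, celltypes))
    if (!is.null(program_spec)) {
      for (r in seq_len(nrow(program_spec))) {
        mu_type[program_spec$gene_id[r], program_spec$cell_type[r]] <-
          mu_type[program_spec$gene_id[r], program_spec$cell_type[r]] *
          2^program_spec$log2fc[r]
      }
    }
    mu <- mu_type[, cell_type, drop = FALSE] *
      matrix(lib, n_genes, n_cells, byrow = TRUE)
    counts <- if (dispersion > 0) {
      matrix(rnbinom(n_genes * n_cells, mu = mu, size = 1 / dispersion),
             n_genes, n_cells)
    } else {
      matrix(stats::rpois(n_genes * n_cells, lambda = mu), n_genes, n_cells)
    }
    dimnames(counts) <- list(gene_ids, cell_id)

    mito_ids <- grep("^MT-", gene_ids, value = TRUE)
    qc_mito_cells <- character(0)
    qc_lib_cells <- character(0)
    n_fail_mito <- round(qc_fail_mito_frac * n_cells)
    n_fail_lib <- round(qc_fail_libsize_frac * n_cells)
    if (n_fail_mito + n_fail_lib > n_cells) {
      stop_scgwas("Planted QC-failure fractions exceed the number of cells.")
    }
    if (n_fail_mito > 0 || n_fail_lib > 0) {
      fail <- sample(cell_id, n_fail_mito + n_fail_lib)
      qc_mito_cells <- head(fail, n_fail_mito)
      qc_lib_cells <- utils::tail(fail, n_fail_lib)
      if (length(qc_mito_cells) > 0 && length(mito_ids) > 0) {
        for (cc in qc_mito_cells) {
          other <- sum(counts[setdiff(gene_ids, mito_ids), cc])
          # push mitochondrial content to ~4x the rest (fraction ~0.8)
          counts[mito_ids[1], cc] <- counts[mito_ids[1], cc] + 4 * other + 50
        }
      }
      if (length(qc_lib_cells) > 0) {
        for (cc in qc_lib_cells) {
          tot <- sum(counts[, cc])
          if (tot >= 1500) {
            keep <- 800 / tot
            counts[, cc] <- rbinom(n_genes, counts[, cc], keep)
          }
        }
      }
    }
    expr <- cell_expression(
      counts,
      tibble(cell_id = cell_id, cell_type = cell_type, sample = "sim1")
    )
    list(
      expr = expr,
      truth = list(program_spec = program_spec, mito_genes = mito_ids,
                   qc_fail_mito = qc_mito_cells, qc_fail_libsize = qc_lib_cells,
                   library_factors = setNames(lib, cell_id),
                   dispersion = dispersion, seed = seed)
    )
  })
}
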