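# Summary-based transcriptome-wide association: single-tissue Wald Z-scores
# from sparse eQTL weights and reference LD, the multi-tissue joint
# chi-square test with a condition-number cutoff on the predicted-expression
# correlation, and cross-method consensus/concordance summaries.

# Per-gene quadratic form w1' R w2 over the block-diagonal LD, for named
# weight vectors (names are SNP ids; SNPs absent from the LD contribute 0).
ld_quadform <- function(ld, w1, w2 = w1) {
  idx <- ld_index(ld)
  idx <- idx[idx$snp_id %in% union(names(w1), names(w2)), ]
  total <- 0
  for (b in unique(idx$block)) {
    rows <- idx[idx$block == b, ]
    R <- ld$blocks[[b]]$R[rows$idx, rows$idx, drop = FALSE]
    v1 <- w1[rows$snp_id]
    v2 <- w2[rows$snp_id]
    v1[is.na(v1)] <- 0
    v2[is.na(v2)] <- 0
    total <- total + as.numeric(v1 %*% R %*% v2)
  }
  total
}

#' Single-tissue summary-based TWAS Z-scores
#'
#' Implements the summary-statistic Wald Z for the association between
#' genetically predicted expression and the trait: with standardized
#' genotypes, `Z_g = sum_i w_i z_i / sqrt(w' R w)` where `z_i` are the GWAS
#' SNP z-scores, `w` the (allele-harmonized) eQTL weights and `R` the
#' reference LD. Weight alleles are harmonized against the GWAS: a weight
#' whose effect allele equals the GWAS other allele flips the SNP's z sign.
#'
#' @param gwas GWAS summary tibble.
#' @param weights eQTL weight tibble (`tissue`, `gene_id`, `snp_id`,
#'   `weight`, `effect_allele`); one or more tissues.
#' @param ld An [ld_blocks()] object (the reference panel role).
#' @return A tibble with `gene_id`, `tissue`, `z`, `p` (two-sided normal),
#'   `fdr_q` (Benjamini-Hochberg within tissue), `n_snps_used`, `coverage`
#'   (fraction of modeled SNPs found in the GWAS). Genes whose predicted
#'   expression variance is <= 1e-12 are skipped with a message.
#' @export
spredixcan_z <- function(gwas, weights, ld) {
  n_model <- dplyr::count(weights, .data$tissue, .data$gene_id,
                          name = "n_modeled")
  harmonized <- harmonize_weights(weights, gwas)
  if (nrow(harmonized) < nrow(weights)) {
    warn_scgwas("%d modeled SNP(s) missing from the GWAS were dropped (remaining weights used as-is).",
                nrow(weights) - nrow(harmonized))
  }
  z_snp <- setNames(gwas$beta / gwas$se, gwas$snp_id)
  skipped <- 0L
  res <- harmonized |>
    dplyr::group_by(.data$tissue, .data$gene_id) |>
    dplyr::group_map(function(g, key) {
      w <- setNames(g$weight, g$snp_id)
      var_g <- ld_quadform(ld, w)
      if (var_g <= 1e-12) {
        skipped <<- skipped + 1L
        return(NULL)
      }
      zg <- sum(g$weight * g$sign * z_snp[g$snp_id]) / sqrt(var_g)
      tibble(tissue = key$tissue, gene_id = key$gene_id, z = zg,
             n_snps_used = nrow(g))
    }) |>
    purrr::list_rbind()
  if (skipped > 0) {
    inform(sprintf("Skipped %d gene model(s) with zero predicted-expression variance.",
                   skipped))
  }
  if (nrow(res) == 0) {
    return(tibble(gene_id = character(0), tissue = character(0),
                  z = numeric(0), p = numeric(0), fdr_q = numeric(0),
                  n_snps_used = integer(0), coverage = numeric(0)))
  }
  res$p <- 2 * stats::pnorm(-abs(res$z))
  res <- res |>
    dplyr::group_by(.data$tissue) |>
    dplyr::mutate(fdr_q = bh_fdr(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::left_join(n_model, by = c("tissue", "gene_id")) |>
    dplyr::mutate(coverage = .data$n_snps_used / .data$n_modeled) |>
    dplyr::select("gene_id", "tissue", "z", "p", "fdr_q", "n_snps_used",
                  "coverage")
  res
}

#' Multi-tissue joint TWAS test
#'
#' Combines per-tissue summary Z-scores into one chi-square test per gene.
#' The correlation of standardized predicted expressions across tissues is
#' computed from the weights and reference LD,
#' `Sigma_jk = w_j' R w_k / (sd_j sd_k)`; its eigen-decomposition is
#' truncated at condition number `condition_threshold` (components with
#' `lambda_max / lambda_k > threshold` are discarded) and the statistic is
#' the quadratic form of the z-vector in the retained pseudo-inverse, with
#' degrees of freedom equal to the number of retained components.
#'
#' @param gwas GWAS summary tibble.
#' @param weights eQTL weight tibble covering one or more tissues.
#' @param ld An [ld_blocks()] object.
#' @param condition_threshold Condition-number cutoff (default 30).
#' @return A tibble with `gene_id`, `chi2`, `dof`, `p`, `fdr_q`,
#'   `n_tissues_used`. Genes with every component discarded are skipped with
#'   a message.
#' @export
smultixcan <- function(gwas, weights, ld, condition_threshold = 30) {
  single <- spredixcan_z(gwas, weights, ld)
  if (nrow(single) == 0) {
    return(tibble(gene_id = character(0), chi2 = numeric(0), dof = integer(0),
                  p = numeric(0), fdr_q = numeric(0),
                  n_tissues_used = integer(0)))
  }
  harmonized <- harmonize_weights(weights, gwas)
  skipped <- 0L
  res <- purrr::map_dfr(unique(single$gene_id), function(gene) {
    sub <- single[single$gene_id == gene, ]
    tissues <- sub$tissue
    zvec <- sub$z
    k <- length(tissues)
    if (k == 1) {
      return(tibble(gene_id = gene, chi2 = zvec^2, dof = 1L,
                    p = stats::pchisq(zvec^2, 1, lower.tail = FALSE),
                    n_tissues_used = 1L))
    }
    wlist <- lapply(tissues, function(tt) {
      g <- harmonized[harmonized$gene_id == gene & harmonized$tissue == tt, ]
      setNames(g$weight, g$snp_id)
    })
    sds <- sqrt(vapply(wlist, function(w) ld_quadform(ld, w), numeric(1)))
    Sigma <- diag(1, k)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (j <= i) next
        Sigma[i, j] <- Sigma[j, i] <-
          ld_quadform(ld, wlist[[i]], wlist[[j]]) / (sds[i] * sds[j])
      }
    }
    ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
    keep <- ev$values > 0 & ev$values[1] / ev$values <= condition_threshold
    if (!any(keep)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    comps <- as.numeric(crossprod(ev$vectors[, keep, drop = FALSE], zvec))
    chi2 <- sum(comps^2 / ev$values[keep])
    dof <- sum(keep)
    tibble(gene_id = gene, chi2 = chi2, dof = as.integer(dof),
           p = stats::pchisq(chi2, dof, lower.tail = FALSE),
           n_tissues_used = as.integer(k))
  })
  if (skipped > 0) {
    inform(sprintf("Skipped %d gene(s) with every principal component discarded.",
                   skipped))
  }
  if (nrow(res) > 0) res$fdr_q <- bh_fdr(res$p)
  res
}

#' Cross-method consensus gene report
#'
#' @param sets Named list (>= 2 entries) of significant gene-id vectors, one
#'   per method.
#' @return A list with `per_method` (tibble of method and count),
#'   `intersection` (genes significant in every method) and `n_intersection`.
#' @export
consensus_genes <- function(sets) {
  if (length(sets) < 2) stop_scgwas("Need results from at least 2 methods.")
  inter <- Reduce(intersect, sets)
  list(
    per_method = tibble(method = names(sets),
                        n_significant = unname(lengths(sets))),
    intersection = inter,
    n_intersection = length(inter)
  )
}

#' Concordance between two association result sets
#'
#' Pearson correlation over shared genes of either `-log10(p)` or the signed
#' z-scores.
#'
#' @param res_a,res_b Tibbles with `gene_id` and `p` (and `z` when
#'   `on = "z"`).
#' @param on `"neglog10p"` (default) or `"z"`.
#' @return The Pearson correlation (scalar).
#' @export
method_concordance <- function(res_a, res_b, on = c("neglog10p", "z")) {
  on <- match.arg(on)
  shared <- dplyr::inner_join(res_a, res_b, by = "gene_id",
                              suffix = c("_a", "_b"))
  if (nrow(shared) < 3) {
    stop_scgwas("Concordance needs at least 3 shared genes (found %d).",
                nrow(shared))
  }
  if (on == "neglog10p") {
    stats::cor(-log10(pmax(shared$p_a, 1e-300)),
               -log10(pmax(shared$p_b, 1e-300)))
  } else {
    stats::cor(shared$z_a, shared$z_b)
  }
}
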