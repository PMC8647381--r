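# Gene-level association from SNP summary statistics, competitive pathway
# testing, and Jaccard/MDS pathway clustering.
#
# The gene statistic is the LD-aware sum of squared SNP z-scores. Under the
# null the statistic is distributed as a weighted mixture sum_k lambda_k *
# chisq_1 with lambda the eigenvalues of the gene's LD matrix; the tail is
# evaluated by Monte-Carlo with a fixed internal seed (exact chi-square when
# the LD is the identity). MAGMA-style gene-size/density covariates are not
# modeled.

# Upper-tail probability of sum_k lambda_k chisq_1 >= stat by Monte-Carlo
# with a fixed internal seed (reproducible across calls), chunked to bound
# memory. Uses the +1/(N+1) correction so p stays in (0, 1].
mixture_tail_p <- function(lambda, stat, n_mc = 1e5, mc_seed = 20240611) {
  k <- length(lambda)
  with_seed(mc_seed, {
    chunk <- max(1L, min(n_mc, floor(2e6 / k)))
    count <- 0L
    done <- 0L
    while (done < n_mc) {
      m <- min(chunk, n_mc - done)
      draws <- matrix(rchisq(m * k, df = 1), m, k) %*% lambda
      count <- count + sum(draws >= stat)
      done <- done + m
    }
    (1 + count) / (n_mc + 1)
  })
}

#' Gene-level association statistic from GWAS summary statistics
#'
#' For each gene j with SNP set S_j, the statistic is the sum of squared SNP
#' z-scores. Its null distribution under LD is the eigenvalue-weighted
#' chi-square mixture of the gene's LD matrix `R_Sj`, evaluated by a
#' 100,000-sample Monte-Carlo with a fixed internal seed; when `R_Sj` is the
#' identity the exact chi-square tail with `|S_j|` degrees of freedom is used.
#' Q-values are Benjamini-Hochberg across genes.
#'
#' @param gwas GWAS summary tibble.
#' @param ld An [ld_blocks()] object covering the mapped SNPs.
#' @param snpmap Gene-to-SNP map tibble (`gene_id`, `snp_id`).
#' @param n_mc Monte-Carlo samples for the mixture tail (default 1e5).
#' @return A tibble with `gene_id`, `stat`, `n_snps`, `p`, `fdr_q`; genes
#'   with no mapped SNP present in the GWAS are omitted.
#' @export
gene_level_stat <- function(gwas, ld, snpmap, n_mc = 1e5) {
  z <- setNames(gwas$beta / gwas$se, gwas$snp_id)
  idx <- ld_index(ld)
  idx$z <- z[idx$snp_id]
  snpmap <- snpmap[snpmap$snp_id %in% gwas$snp_id &
                     snpmap$snp_id %in% idx$snp_id, ]
  by_gene <- split(snpmap$snp_id, snpmap$gene_id)
  by_gene <- by_gene[lengths(by_gene) > 0]
  if (length(by_gene) == 0) {
    return(tibble(gene_id = character(0), stat = numeric(0),
                  n_snps = integer(0), p = numeric(0), fdr_q = numeric(0)))
  }
  lookup <- setNames(seq_len(nrow(idx)), idx$snp_id)
  res <- purrr::imap_dfr(by_gene, function(snps, gene) {
    rows <- idx[lookup[snps], ]
    stat <- sum(rows$z^2)
    # eigenvalues of the block-diagonal LD submatrix
    lambda <- numeric(0)
    for (b in unique(rows$block)) {
      pos <- rows$idx[rows$block == b]
      Rsub <- ld$blocks[[b]]$R[pos, pos, drop = FALSE]
      lambda <- c(lambda, eigen(Rsub, symmetric = TRUE,
                                only.values = TRUE)$values)
    }
    lambda <- pmax(lambda, 0)
    identity_ld <- max(abs(lambda - 1)) < 1e-10
    p <- if (identity_ld) {
      stats::pchisq(stat, df = length(snps), lower.tail = FALSE)
    } else {
      mixture_tail_p(lambda, stat, n_mc = n_mc)
    }
    tibble(gene_id = gene, stat = stat, n_snps = length(snps), p = max(p, 1e-300))
  })
  res$fdr_q <- bh_fdr(res$p)
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q(i) = min over j with rank >= rank(i) of p(j) * m / rank(j)`, preserving
#' input order. Delegates to [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

#' Competitive pathway test by gene-label permutation
#'
#' Converts each gene's association p-value to a z-score (upper-tail normal
#' quantile, capped at p = 1e-300) and scores each pathway as the mean z of
#' member genes minus the mean z of all remaining genes. Significance is
#' assessed by permuting gene labels:
#' `perm_p = (1 + #\{permuted score >= observed\}) / (n_perm + 1)`.
#'
#' @param gene_results Tibble with `gene_id` and `p` (e.g. from
#'   [gene_level_stat()]).
#' @param genesets Gene-set tibble (see [read_gene_sets()]).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A tibble with `set_id`, `n_genes_in_set`, `score`, `perm_p`,
#'   `fdr_q`. Pathways with fewer than two member or two non-member genes in
#'   the tested universe are skipped with a warning.
#' @export
competitive_pathway_test <- function(gene_results, genesets, n_perm = 10000,
                                     seed = NULL) {
  z <- gene_z_from_p(gene_results$p)
  names(z) <- gene_results$gene_id
  n <- length(z)
  with_seed(seed, {
    res <- purrr::pmap_dfr(
      list(genesets$set_id, genesets$genes),
      function(set_id, members) {
        inset <- names(z) %in% members
        k <- sum(inset)
        if (k < 2 || n - k < 2) {
          warn_scgwas("Pathway '%s' skipped: needs >= 2 genes inside and outside the set.",
                      set_id)
          return(NULL)
        }
        total <- sum(z)
        obs <- mean(z[inset]) - (total - sum(z[inset])) / (n - k)
        perm_in <- vapply(seq_len(n_perm), function(i) {
          sum(z[sample.int(n, k)])
        }, numeric(1))
        perm_score <- perm_in / k - (total - perm_in) / (n - k)
        tibble(set_id = set_id, n_genes_in_set = k, score = obs,
               perm_p = (1 + sum(perm_score >= obs)) / (n_perm + 1))
      }
    )
    if (nrow(res) > 0) res$fdr_q <- bh_fdr(res$perm_p)
    res
  })
}

#' Jaccard-distance multidimensional scaling of significant pathways
#'
#' Pairwise pathway distance is `1 - |A intersect B| / |A union B|` over
#' member genes. Classical (Torgerson) scaling of the distance matrix gives
#' the first two coordinates; average-linkage hierarchical clustering on the
#' same distances, cut at `n_clusters`, groups the pathways, and each cluster
#' is labeled by its most significant (lowest `perm_p`) member.
#'
#' @param pathway_results Tibble with `set_id` and `perm_p` for the pathways
#'   to embed (typically the significant ones).
#' @param genesets Gene-set tibble providing the member lists.
#' @param n_clusters Number of clusters to cut; must not exceed the number of
#'   pathways.
#' @return A tibble with `set_id`, `mds1`, `mds2`, `cluster`,
#'   `cluster_label`.
#' @export
pathway_mds <- function(pathway_results, genesets, n_clusters = 2) {
  ids <- pathway_results$set_id
  if (length(ids) < 2) stop_scgwas("Need at least 2 pathways for MDS.")
  if (n_clusters > length(ids)) {
    stop_scgwas("n_clusters (%d) exceeds the number of pathways (%d).",
                n_clusters, length(ids))
  }
  members <- setNames(genesets$genes, genesets$set_id)[ids]
  if (any(vapply(members, is.null, logical(1)))) {
    stop_scgwas("Pathway id(s) missing from genesets.")
  }
  d <- jaccard_distance(members)
  coords <- stats::cmdscale(as.dist(d), k = 2)
  cl <- stats::cutree(stats::hclust(as.dist(d), method = "average"),
                      k = n_clusters)
  pvals <- setNames(pathway_results$perm_p, ids)
  labels <- vapply(seq_len(n_clusters), function(k) {
    mem <- ids[cl == k]
    mem[which.min(pvals[mem])]
  }, character(1))
  tibble(
    set_id = ids,
    mds1 = coords[, 1],
    mds2 = coords[, 2],
    cluster = as.integer(cl),
    cluster_label = labels[cl]
  )
}

#' Jaccard distance matrix between gene sets
#'
#' @param members Named list of character vectors.
#' @return A symmetric matrix of `1 - |intersection| / |union|`.
#' @export
jaccard_distance <- function(members) {
  n <- length(members)
  d <- matrix(0, n, n, dimnames = list(names(members), names(members)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- unique(members[[i]])
      b <- unique(members[[j]])
      d[i, j] <- d[j, i] <- 1 - length(intersect(a, b)) / length(union(a, b))
    }
  }
  d
}
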