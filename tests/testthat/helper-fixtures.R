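# Shared fixture builders. Everything is generated in code; no data files.

# A GWAS summary tibble with prescribed SNP z-scores (standardized scale:
# beta = z / sqrt(n), se = 1 / sqrt(n), p the matching two-sided tail).
gwas_from_z <- function(z, n = 10000, snp_ids = NULL, chrom = "1",
                        pos = NULL) {
  snp_ids <- snp_ids %||% paste0("rs", seq_along(z))
  tibble::tibble(
    snp_id = snp_ids,
    chrom = chrom,
    pos = pos %||% (seq_along(z) * 1000L),
    effect_allele = "A",
    other_allele = "G",
    beta = z / sqrt(n),
    se = 1 / sqrt(n),
    p = 2 * stats::pnorm(-abs(z)),
    n = as.integer(n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Identity-LD blocks over the given SNP ids, one block per chunk.
identity_ld <- function(snp_ids, chunk = length(snp_ids)) {
  idx <- split(snp_ids, ceiling(seq_along(snp_ids) / chunk))
  ld_blocks(lapply(idx, function(s) list(snps = s, R = diag(length(s)))))
}

# A tiny annotated GWAS world: `n_genes` genes with `snps_per_gene` SNPs
# each, AR(1) LD blocks of `genes_per_block` genes, used by the enrichment
# tests. Returns ld, snpmap, and a gene table.
make_gwas_world <- function(n_genes = 40, snps_per_gene = 3,
                            genes_per_block = 4, rho = 0.3) {
  block_size <- genes_per_block * snps_per_gene
  n_blocks <- ceiling(n_genes / genes_per_block)
  ld <- simulate_ld_blocks(n_blocks, block_size, rho = rho)
  snp_ids <- ld$index$snp_id
  snpmap <- tibble::tibble(
    gene_id = rep(sprintf("g%03d", seq_len(n_genes)), each = snps_per_gene),
    snp_id = snp_ids[seq_len(n_genes * snps_per_gene)]
  )
  list(ld = ld, snpmap = snpmap,
       genes = sprintf("g%03d", seq_len(n_genes)))
}

# Dense normalized matrix with prescribed per-gene baselines plus iid noise.
normalized_matrix <- function(n_genes, n_cells, baseline = NULL, noise_sd = 0.1,
                              seed = 1) {
  set.seed(seed)
  baseline <- baseline %||% stats::rnorm(n_genes, 2, 1)
  m <- matrix(baseline, n_genes, n_cells) +
    matrix(stats::rnorm(n_genes * n_cells, 0, noise_sd), n_genes, n_cells)
  m <- pmax(m, 0)
  dimnames(m) <- list(sprintf("gene%04d", seq_len(n_genes)),
                      sprintf("cell%05d", seq_len(n_cells)))
  m
}
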