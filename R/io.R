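# Readers, writers and validated containers for every on-disk format the
# pipeline touches. All genomic coordinates are 1-based and inclusive.

GWAS_COLUMNS <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "beta", "se", "p", "n"
)

#' Validate a table of GWAS summary statistics
#'
#' Checks the per-SNP marginal association table against the invariants the
#' pipeline assumes: unique SNP ids, positive standard errors, p-values in
#' (0, 1] consistent with the two-sided normal tail of `beta / se` (within
#' 1e-6 when both are given), and positive sample sizes. Offending rows are
#' dropped with a warning rather than silently kept.
#'
#' @param gwas A data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta` (effect on the standardized
#'   scale), `se` (> 0), `p` in (0, 1] and `n` (sample size).
#' @return A validated tibble; the number of dropped rows is attached as the
#'   `"n_dropped"` attribute.
#' @export
validate_gwas <- function(gwas) {
  missing <- setdiff(GWAS_COLUMNS, names(gwas))
  if (length(missing) > 0) {
    stop_scgwas("GWAS table is missing required column(s): %s",
                paste(missing, collapse = ", "))
  }
  gwas <- as_tibble(gwas)[GWAS_COLUMNS]
  n0 <- nrow(gwas)
  bad <- !is.finite(gwas$se) | gwas$se <= 0
  bad <- bad | !is.finite(gwas$p) | gwas$p <= 0 | gwas$p > 1
  bad <- bad | !is.finite(gwas$n) | gwas$n <= 0
  # p must agree with the two-sided normal tail of beta/se when both given
  ptail <- 2 * stats::pnorm(-abs(gwas$beta / gwas$se))
  bad <- bad | (is.finite(ptail) & abs(gwas$p - ptail) > 1e-6)
  bad[is.na(bad)] <- TRUE
  bad <- bad | duplicated(gwas$snp_id)
  gwas <- gwas[!bad, ]
  n_drop <- n0 - nrow(gwas)
  if (n_drop > 0) {
    warn_scgwas("Dropped %d GWAS row(s) failing validation (se <= 0, p out of (0,1], p inconsistent with beta/se, non-positive n, or duplicate snp_id).",
                n_drop)
  }
  attr(gwas, "n_dropped") <- n_drop
  gwas
}

#' Read GWAS summary statistics from a TSV file
#'
#' @param path Path to a tab-separated file with a header.
#' @param columns Optional named character vector mapping the standard column
#'   names (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `p`, `n`) to the names used in the file, for dialects
#'   whose headers differ.
#' @return A validated tibble of summary statistics (see [validate_gwas()]).
#' @export
read_gwas <- function(path, columns = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(columns)) {
    for (std in names(columns)) {
      file_col <- columns[[std]]
      if (!file_col %in% names(df)) {
        stop_scgwas("Column '%s' (mapped to '%s') not found in %s",
                    file_col, std, path)
      }
      names(df)[names(df) == file_col] <- std
    }
  }
  missing <- setdiff(GWAS_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop_scgwas("GWAS file %s is missing required column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  df$chrom <- as.character(df$chrom)
  validate_gwas(df)
}

#' Write GWAS summary statistics to a TSV file
#'
#' @param gwas A GWAS summary tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(gwas, path) {
  readr::write_tsv(gwas[GWAS_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Construct a set of LD blocks
#'
#' An LD block set is the block-diagonal SNP correlation structure used by
#' every LD-aware stage: an ordered list of blocks, each holding the SNP ids
#' it covers and their correlation matrix R.
#'
#' @param blocks A list; each element a list with `snps` (character vector)
#'   and `R` (square correlation matrix, same order as `snps`).
#' @return An object of class `ld_blocks`.
#' @details Each R must be symmetric with unit diagonal (tolerance 1e-8) and
#'   positive semi-definite (smallest eigenvalue >= -1e-8); a SNP may appear
#'   in exactly one block.
#' @export
ld_blocks <- function(blocks) {
  all_snps <- character(0)
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    if (!all(c("snps", "R") %in% names(blk))) {
      stop_scgwas("Block %d must have components 'snps' and 'R'.", b)
    }
    R <- as.matrix(blk$R)
    k <- length(blk$snps)
    if (!all(dim(R) == c(k, k))) {
      stop_scgwas("Block %d: R is %dx%d but has %d SNP ids.",
                  b, nrow(R), ncol(R), k)
    }
    if (max(abs(R - t(R))) > 1e-8) {
      stop_scgwas("Block %d: R is not symmetric.", b)
    }
    if (max(abs(diag(R) - 1)) > 1e-8) {
      stop_scgwas("Block %d: R does not have a unit diagonal.", b)
    }
    ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop_scgwas("Block %d: R is not positive semi-definite (min eigenvalue %.3g).",
                  b, min(ev))
    }
    blocks[[b]]$R <- R
    all_snps <- c(all_snps, blk$snps)
  }
  if (anyDuplicated(all_snps)) {
    stop_scgwas("SNP id(s) appear in more than one LD block: %s",
                paste(unique(all_snps[duplicated(all_snps)]), collapse = ", "))
  }
  obj <- structure(list(blocks = blocks), class = "ld_blocks")
  obj$index <- purrr::imap_dfr(blocks, function(b, i) {
    tibble(snp_id = b$snps, block = i, idx = seq_along(b$snps))
  })
  obj
}

#' @export
print.ld_blocks <- function(x, ...) {
  sizes <- vapply(x$blocks, function(b) length(b$snps), integer(1))
  cat(sprintf("<ld_blocks: %d block(s), %d SNPs, block sizes %s>\n",
              length(x$blocks), sum(sizes),
              paste(range(sizes), collapse = "-")))
  invisible(x)
}

# Per-SNP lookup: block index and position within block (precomputed at
# construction).
ld_index <- function(ld) {
  ld$index
}

#' Read LD blocks from JSON
#'
#' The format is a JSON array of objects `{"snps": [...], "R": [[...]]}`.
#'
#' @param path Path to the JSON file.
#' @return An [ld_blocks()] object.
#' @export
read_ld_blocks <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  blocks <- lapply(raw, function(b) {
    R <- do.call(rbind, lapply(b$R, function(row) as.numeric(unlist(row))))
    list(snps = as.character(unlist(b$snps)), R = R)
  })
  ld_blocks(blocks)
}

#' Write LD blocks to JSON
#'
#' @param ld An [ld_blocks()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_blocks <- function(ld, path) {
  out <- lapply(ld$blocks, function(b) {
    list(snps = b$snps,
         R = lapply(seq_len(nrow(b$R)), function(i) unname(b$R[i, ])))
  })
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read gene annotations from a BED-like TSV
#'
#' Expects a header with columns `chrom`, `start`, `end`, `strand`,
#' `gene_id`; coordinates are 1-based inclusive.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("chrom", "start", "end", "strand", "gene_id")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop_scgwas("Gene annotation file %s is missing column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  df <- as_tibble(df)[needed]
  df$chrom <- as.character(df$chrom)
  validate_gene_annotation(df)
}

#' Validate a gene annotation table
#'
#' @param genes Data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id` (1-based inclusive coordinates).
#' @return The validated tibble.
#' @export
validate_gene_annotation <- function(genes) {
  genes <- as_tibble(genes)
  if (any(genes$start > genes$end)) {
    stop_scgwas("Gene annotation has start > end for: %s",
                paste(genes$gene_id[genes$start > genes$end], collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop_scgwas("Gene strand must be '+' or '-'.")
  }
  if (anyDuplicated(genes$gene_id)) {
    stop_scgwas("Duplicate gene_id(s): %s",
                paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                      collapse = ", "))
  }
  genes
}

# MHC bounds used when exclude_mhc is requested (GRCh37 convention).
MHC_CHROM <- "6"
MHC_START <- 25e6
MHC_END <- 35e6

#' Map SNPs to genes by genomic window
#'
#' Assigns SNP i to gene j when the SNP lies within the gene body extended by
#' `window_kb` kilobases on both sides, on the same chromosome. Gene SNP sets
#' may overlap. With `exclude_mhc = TRUE`, genes overlapping the major
#' histocompatibility complex region (chr6:25-35 Mb) are removed entirely,
#' reflecting its extreme LD.
#'
#' @param gwas GWAS summary tibble (only `snp_id`, `chrom`, `pos` are used).
#' @param genes Gene annotation tibble (see [read_gene_annotation()]).
#' @param window_kb Window in kb added both up- and downstream (default 20).
#' @param exclude_mhc Drop MHC-overlapping genes (default `FALSE`).
#' @return A tibble with columns `gene_id` and `snp_id`, ordered by gene then
#'   genomic position.
#' @export
map_snps_to_genes <- function(gwas, genes, window_kb = 20, exclude_mhc = FALSE) {
  if (window_kb < 0) stop_scgwas("window_kb must be >= 0.")
  if (nrow(gwas) == 0 || nrow(genes) == 0) {
    warn_scgwas("Empty GWAS or gene annotation; returning an empty map.")
    return(tibble(gene_id = character(0), snp_id = character(0)))
  }
  genes <- as_tibble(genes)
  genes$.chrom <- norm_chrom(genes$chrom)
  if (exclude_mhc) {
    in_mhc <- genes$.chrom == MHC_CHROM &
      genes$start <= MHC_END & genes$end >= MHC_START
    genes <- genes[!in_mhc, ]
  }
  window <- window_kb * 1000
  snp_by_chrom <- split(
    tibble(snp_id = gwas$snp_id, pos = gwas$pos),
    norm_chrom(gwas$chrom)
  )
  snp_by_chrom <- lapply(snp_by_chrom, function(d) d[order(d$pos), ])
  purrr::pmap_dfr(
    list(genes$gene_id, genes$.chrom, genes$start, genes$end),
    function(gene_id, chrom, start, end) {
      snps <- snp_by_chrom[[chrom]]
      if (is.null(snps)) return(NULL)
      lo <- findInterval(start - window - 0.5, snps$pos) + 1L
      hi <- findInterval(end + window + 0.5, snps$pos)
      if (hi < lo) return(NULL)
      tibble(gene_id = gene_id, snp_id = snps$snp_id[lo:hi])
    }
  )
}

#' Construct a single-cell expression container
#'
#' @param counts A non-negative integer matrix (genes x cells), dense or
#'   sparse; coerced to `dgCMatrix`. Row names are gene ids, column names
#'   cell ids.
#' @param cell_meta A data frame with columns `cell_id`, `cell_type`,
#'   `sample`, aligned with the columns of `counts`.
#' @return An object of class `cell_expression`.
#' @export
cell_expression <- function(counts, cell_meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  cell_meta <- as_tibble(cell_meta)
  needed <- c("cell_id", "cell_type", "sample")
  missing <- setdiff(needed, names(cell_meta))
  if (length(missing) > 0) {
    stop_scgwas("cell_meta is missing column(s): %s",
                paste(missing, collapse = ", "))
  }
  if (ncol(counts) != nrow(cell_meta)) {
    stop_scgwas("Count matrix has %d cells but cell_meta has %d rows.",
                ncol(counts), nrow(cell_meta))
  }
  if (is.null(rownames(counts))) {
    stop_scgwas("Count matrix must have gene ids as row names.")
  }
  if (anyDuplicated(rownames(counts))) {
    stop_scgwas("Gene ids in the count matrix must be unique.")
  }
  if (length(counts@x) && min(counts@x) < 0) {
    stop_scgwas("Count matrix contains negative entries.")
  }
  colnames(counts) <- cell_meta$cell_id
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "cell_expression")
}

#' @export
print.cell_expression <- function(x, ...) {
  cat(sprintf("<cell_expression: %d genes x %d cells, %d cell type(s)>\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$cell_type))))
  invisible(x)
}

#' Read a single-cell count matrix with cell metadata
#'
#' @param path_matrix Matrix-Market (`.mtx`) sparse genes x cells counts.
#' @param path_genes TSV with a `gene_id` column, one row per matrix row.
#' @param path_cells TSV with columns `cell_id`, `cell_type`, `sample`, one
#'   row per matrix column.
#' @return A [cell_expression()] object.
#' @export
read_expression <- function(path_matrix, path_genes, path_cells) {
  m <- Matrix::readMM(path_matrix)
  genes <- readr::read_tsv(path_genes, show_col_types = FALSE, progress = FALSE)
  cells <- readr::read_tsv(path_cells, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(genes)) {
    stop_scgwas("Gene file %s must have a 'gene_id' column.", path_genes)
  }
  if (nrow(genes) != nrow(m)) {
    stop_scgwas("Matrix has %d rows but gene file has %d.", nrow(m), nrow(genes))
  }
  if (nrow(cells) != ncol(m)) {
    stop_scgwas("Matrix has %d columns but cell file has %d.", ncol(m), nrow(cells))
  }
  rownames(m) <- genes$gene_id
  cell_expression(m, cells)
}

#' Write a single-cell count matrix with cell metadata
#'
#' @param expr A [cell_expression()] object.
#' @param path_matrix,path_genes,path_cells Output paths mirroring
#'   [read_expression()].
#' @return `path_matrix`, invisibly.
#' @export
write_expression <- function(expr, path_matrix, path_genes, path_cells) {
  Matrix::writeMM(expr$counts, path_matrix)
  readr::write_tsv(tibble(gene_id = rownames(expr$counts)), path_genes,
                   progress = FALSE)
  readr::write_tsv(expr$cell_meta, path_cells, progress = FALSE)
  invisible(path_matrix)
}

#' Read gene sets from a GMT file
#'
#' Each line is `set_id TAB description TAB gene1 TAB gene2 ...`. Duplicate
#' genes within a set are stored once, preserving first-occurrence order;
#' lines with fewer than three fields are skipped with a warning.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `set_id`, `description` and a `genes`
#'   list-column of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn_scgwas("Empty gene-set file: %s", path)
    return(tibble(set_id = character(0), description = character(0),
                  genes = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short)) {
    warn_scgwas("Skipped %d GMT line(s) with fewer than 3 fields.", sum(short))
    fields <- fields[!short]
  }
  tibble(
    set_id = vapply(fields, `[[`, character(1), 1),
    description = vapply(fields, `[[`, character(1), 2),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}

#' Write gene sets to a GMT file
#'
#' @param sets A gene-set tibble as returned by [read_gene_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- purrr::pmap_chr(
    list(sets$set_id, sets$description, sets$genes),
    function(id, desc, genes) paste(c(id, desc, genes), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a ligand-receptor pair table
#'
#' Expects a TSV with columns `pair_id`, `ligand_genes`, `receptor_genes`
#' (comma-joined gene ids; multi-subunit complexes list every subunit) and
#' `pathway`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `ligand_genes`/`receptor_genes` as list-columns.
#' @export
read_lr_pairs <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("pair_id", "ligand_genes", "receptor_genes", "pathway")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop_scgwas("Ligand-receptor file %s is missing column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  out <- tibble(
    pair_id = df$pair_id,
    ligand_genes = strsplit(df$ligand_genes, ",", fixed = TRUE),
    receptor_genes = strsplit(df$receptor_genes, ",", fixed = TRUE),
    pathway = df$pathway
  )
  bad <- lengths(out$ligand_genes) == 0 | lengths(out$receptor_genes) == 0 |
    !nzchar(out$pathway)
  if (any(bad)) {
    stop_scgwas("Ligand-receptor pair(s) with empty gene lists or pathway: %s",
                paste(out$pair_id[bad], collapse = ", "))
  }
  out
}

# Harmonize eQTL weight alleles against the GWAS effect/other alleles.
# Returns the weight rows joined with a `sign` column: +1 when the weight's
# effect allele equals the GWAS effect allele, -1 when it equals the GWAS
# other allele (the GWAS beta sign is flipped for that SNP), rows dropped
# when neither matches. Strand-ambiguous (A/T, C/G) SNPs are kept as-is with
# a warning since their orientation cannot be resolved from alleles alone.
harmonize_weights <- function(weights, gwas) {
  j <- dplyr::inner_join(
    weights,
    dplyr::select(gwas, "snp_id", gwas_ea = "effect_allele",
                  gwas_oa = "other_allele"),
    by = "snp_id"
  )
  amb <- paste(pmin(j$gwas_ea, j$gwas_oa), pmax(j$gwas_ea, j$gwas_oa)) %in%
    c("A T", "C G")
  if (any(amb)) {
    warn_scgwas("%d weight entr(ies) at strand-ambiguous SNPs kept as-is.",
                sum(amb))
  }
  sign <- dplyr::case_when(
    amb ~ 1,
    j$effect_allele == j$gwas_ea ~ 1,
    j$effect_allele == j$gwas_oa ~ -1,
    TRUE ~ NA_real_
  )
  drop <- is.na(sign)
  if (any(drop)) {
    warn_scgwas("Dropped %d weight entr(ies) whose alleles cannot be resolved against the GWAS.",
                sum(drop))
  }
  j <- j[!drop, , drop = FALSE]
  j$sign <- sign[!drop]
  j
}
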