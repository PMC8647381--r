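# scgwas

Linking GWAS summary statistics to the cell types and cell subsets that
carry a trait's genetic signal.

Genome-wide association studies report per-SNP marginal effects, most of
them non-coding and small; single-cell RNA-seq reports which genes each
cell type expresses. `scgwas` is for analysts who want to connect the two:
it turns SNP-level summary statistics, reference LD, per-tissue eQTL weight
models and labeled single-cell count matrices into gene-, pathway-,
cell-type- and cell-subset-level results — the kind of integrative analysis
used to ask, e.g., which liver cell population is enriched for primary
biliary cholangitis risk and how the implicated cell subset communicates
with its immune microenvironment.

## What it computes

**Polygenic cell-type enrichment.** Per-SNP effects of gene *j* are modeled
as β ~ N(0, σ²ⱼ) with

    σ²ⱼ = γ₀ + Σᵢ γᵢ αⱼᵢ,

where αⱼᵢ ≥ 0 is the cell-type-specific expression annotation. The moment
identity E(Σ_{i∈Sⱼ} β̂ᵢ²) = σ²ⱼ·Tr(R²_{Sⱼ}) + |Sⱼ|σ²ₑ/n (R = LD matrix,
n = GWAS sample size) is inverted by least squares; inference is by block
bootstrap over LD blocks with a small-cluster-corrected t reference.

**Summary-based TWAS.** Single-tissue Wald scores
Z_g = Σᵢ ωᵢ zᵢ / √(ωᵀRω) from sparse eQTL weights ω, and a multi-tissue
joint χ² test on the pseudo-inverse of the predicted-expression correlation
(condition-number cutoff 30), plus cross-method consensus and concordance
reports.

**Gene and pathway association.** LD-aware sum-of-squared-z gene statistic
with an eigenvalue-mixture null; competitive pathway permutation test;
Jaccard-distance MDS maps of significant pathways.

**Overlap permutation.** Empirical P for the overlap of two gene sets
against 100,000 random draws from an explicit background (the Monte-Carlo
analogue of the hypergeometric tail).

**Cell-subset characterization.** QC (mitochondrial fraction > 0.5 or
library size < 1500, strict), log1p-CP10K normalization, binned-control
module scores (genetic-risk, metabolism or pathway activity scores),
percentage-expressed summaries, Wilcoxon/t differential expression with BH
FDR, co-expression matrices, and a simplified Hill-form ligand-receptor
communication model with permutation significance, NMF communication
patterns and network centrality.

**Synthetic data.** `simulate_ld_blocks()`, `simulate_gwas()`,
`simulate_eqtl_weights()`, `simulate_twas_gwas()` and
`simulate_cell_expression()` generate every input with planted ground
truth, so the full pipeline runs offline.

## Worked example

Simulate a GWAS whose effect-size variance is enriched in cholangiocyte
-specific genes, then recover the enrichment:

```r
library(scgwas)
library(dplyr)

ld <- simulate_ld_blocks(n_blocks = 10, block_size = 30, rho = 0.5)
genes <- sprintf("g%03d", 1:100)
snpmap <- tibble(gene_id = rep(genes, each = 3), snp_id = ld$index$snp_id)

set.seed(1)
ann <- tibble(gene_id = genes,
              cholangiocyte = runif(100), hepatocyte = runif(100),
              macrophage = runif(100))

sim <- simulate_gwas(ld, snpmap, ann, gamma0 = 0.05,
                     gamma = c(0.4, 0, 0), n = 10000, seed = 42)

fit <- rolypoly_fit(sim$gwas, ld, snpmap, ann) |>
  block_bootstrap(n_boot = 1000, seed = 7)
tidy(fit)
#> # A tibble: 3 × 5
#>   cell_type      gamma boot_se     t      p
#>   <chr>          <dbl>   <dbl> <dbl>  <dbl>
#> 1 cholangiocyte  0.568  0.243   2.34 0.0220
#> 2 hepatocyte    -0.196  0.104  -1.88 0.954
#> 3 macrophage     0.131  0.0922  1.42 0.0953
```

The planted cell type (true γ = 0.4) is the only one with a one-sided
enrichment p below 0.05; `gamma` is its estimated contribution to per-SNP
effect-size variance per unit of expression specificity, and `boot_se`/`t`
come from 1000 block-bootstrap refits. `glance(fit)` reports the intercept
γ₀ (here 0.0355 against a planted 0.05) and fit metadata, and
`autoplot(fit)` draws the per-cell-type estimates with bootstrap intervals.

Downstream, `gene_level_stat(sim$gwas, ld, snpmap)` scores each gene
(Monte-Carlo mixture p-values are floored at 1/(N+1) = 1e-5 at the default
100,000 samples), `competitive_pathway_test()` scores gene sets, and the
single-cell side (`qc_filter()` → `normalize_rle()` → `module_score()`,
`de_test()`, `comm_perm_test()` → `nmf_patterns()`) characterizes the
implicated cell subsets.

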