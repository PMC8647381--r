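---
title: "Methods: linking GWAS summary statistics to cell types and cell subsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking GWAS summary statistics to cell types and cell subsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgwas)
library(dplyr)
```

# Overview

`scgwas` connects three layers of evidence about a complex trait — per-SNP
GWAS summary statistics, per-tissue eQTL weight models, and single-cell
expression — into gene-, pathway-, cell-type- and cell-subset-level
statements. The pipeline has four statistical cores:

1. **Gene and pathway association** from SNP z-scores under block-wise LD
   (`gene_level_stat()`, `competitive_pathway_test()`, `pathway_mds()`).
2. **Summary-based TWAS**, single-tissue and multi-tissue
   (`spredixcan_z()`, `smultixcan()`).
3. **Polygenic cell-type enrichment**: a method-of-moments regression of
   per-gene aggregate effect-size variance on cell-type expression
   annotations, with block-bootstrap inference (`rolypoly_fit()`,
   `block_bootstrap()`).
4. **Cell-subset characterization**: QC, binned-control activity scores,
   differential expression, and simplified ligand-receptor communication
   with NMF pattern discovery (`module_score()`, `de_test()`,
   `comm_perm_test()`, `nmf_patterns()`).

A synthetic-data module (`simulate_*()`) generates every input with known
ground truth, so each stage is testable end to end without any download.

# The polygenic enrichment model

Let $S_j$ be the SNPs mapped to gene $j$ (gene body ± 20 kb; the MHC region
chr6:25–35 Mb can be excluded because of its extreme LD). The model assumes
per-SNP true effects $\beta_{S_j} \sim \mathrm{MVN}(0, \sigma_j^2 I)$ with

$$\sigma_j^2 = \gamma_0 + \sum_i \gamma_i \,\alpha_{ji},$$

where $\alpha_{ji} \ge 0$ is the cell-type-$i$ expression annotation of gene
$j$ and $\gamma_i$ its enrichment coefficient. Marginal GWAS estimates obey

$$E\Big(\sum_{i \in S_j} \hat\beta_i^2\Big)
  = \sigma_j^2\,\mathrm{Tr}(R_{S_j}^2) + |S_j|\,\sigma_e^2\,n^{-1},$$

with $R_{S_j}$ the LD matrix of $S_j$, $n$ the GWAS sample size and
$\sigma_e^2$ the residual variance (fixed at 1 on the standardized scale,
where $\mathrm{se}(\hat\beta) = 1/\sqrt{n}$; configurable). The package
estimates $(\gamma_0, \gamma)$ by ordinary least squares of the
offset-corrected response $y_j - |S_j|\sigma_e^2/n$ on the design
$[\mathrm{Tr}(R^2_{S_j}),\ \mathrm{Tr}(R^2_{S_j})\,\alpha_{j1}, \dots]$.

**Annotations.** `build_annotations()` uses mean log1p counts-per-10,000 per
cell type, then scales each gene's row by its maximum so $\alpha \in [0,1]$.
This recipe is a package choice (recorded in the matrix's provenance
attribute); any non-negative gene × cell-type matrix can be supplied
instead. The estimator is equivariant: rescaling $\alpha$ by $c$ rescales
$\hat\gamma$ by $1/c$.

**Inference.** Genes are resampled by LD block (a gene travels with the
block holding most of its SNPs; ties go to the lower block index).
`block_bootstrap()` refits per resample using precomputed per-block Gram
matrices, so 1000 resamples cost 1000 small linear solves. Two deliberate
small-sample choices: the bootstrap variance is scaled by $B/(B-1)$ at $B$
blocks, and the one-sided p-value for enrichment uses a Student-t reference
with $B-1$ degrees of freedom. With the few dozen blocks typical of a
block-level resampling scheme, the block count — not the gene count — sets
the effective degrees of freedom; in null simulations (400 genes, 20 blocks)
the plain normal reference rejects at ~0.08–0.09 instead of 0.05, while the
corrected t-reference sits inside [0.03, 0.07]. A label-permutation
alternative (`rolypoly_perm_test()`) is also exposed, since permutation and
bootstrap answers are both used in this literature and neither dominates.

# Gene-level and pathway association

The gene statistic is $\sum_{i \in S_j} z_i^2$. Under the null it follows
the eigenvalue mixture $\sum_k \lambda_k \chi^2_1$ with $\lambda$ the
eigenvalues of $R_{S_j}$. The tail is computed by a 100,000-sample
Monte-Carlo with a fixed internal seed (reproducible; chunked to bound
memory), except under identity LD where the exact $\chi^2_{|S_j|}$ tail is
used. This LD-aware sum-of-squares test is a self-contained stand-in for
multi-marker gene analysis tools; gene-size and SNP-density covariates are
not modeled. Monte-Carlo p-values use the $(1+\#)/(N+1)$ correction so they
never report zero.

The competitive pathway test converts gene p-values to z-scores
($z = \Phi^{-1}(1-p)$, p capped at $10^{-300}$), scores a pathway as
mean(z inside) − mean(z outside), and permutes gene labels (default 10,000
permutations, `+1` correction). Significant pathways are embedded by
classical (Torgerson) MDS of their pairwise Jaccard distances and grouped by
average-linkage clustering, each cluster labeled by its most significant
member.

# Summary-based TWAS

With standardized genotypes, the single-tissue association between
genetically predicted expression and the trait is

$$Z_g = \frac{\sum_i \omega_{ig} z_i}{\sqrt{\omega^\top R\, \omega}},$$

where $\omega$ are the sparse eQTL weights and $R$ the reference LD. Weight
alleles are harmonized against the GWAS: a weight whose effect allele equals
the GWAS other allele flips that SNP's z sign; strand-ambiguous (A/T, C/G)
SNPs are kept as-is with a warning, and unresolvable alleles are dropped.
Modeled SNPs absent from the GWAS are dropped without renormalizing the
remaining weights; the coverage fraction is reported per gene.

The multi-tissue test assembles the per-tissue z-vector and the correlation
of standardized predicted expressions,
$\Sigma_{jk} = \omega^{(j)\top} R\, \omega^{(k)} / (\hat\sigma_j
\hat\sigma_k)$, eigen-decomposes $\Sigma$, discards components with
condition number above 30 (configurable), and reports
$\chi^2 = z^\top \Sigma^+ z$ with degrees of freedom equal to the retained
components. The cutoff stabilizes the pseudo-inverse when tissue models are
nearly collinear; with a single tissue the statistic reduces exactly to
$Z^2$. FDR is computed within tissue for single-tissue results and across
the union of tested genes for the multi-tissue test.

# Overlap permutation

`empirical_p()` draws $|B|$ genes uniformly without replacement from an
explicit background $N_{total}$ times (default 100,000) and reports the
fraction of draws whose overlap with $A$ reaches the observed overlap. The
estimand is the hypergeometric survival probability, and the Monte-Carlo
agrees with `phyper()` within sampling error; the Monte-Carlo route is kept
because it is the procedure being emulated, with the closed form used only
as a test oracle. A reported 0 means "below 1/n_draws" and carries that
annotation. The background is always passed explicitly — each method has its
own gene universe and inferring it silently would change the null.

# Cell scores, QC, and differential expression

QC removes cells with mitochondrial fraction **strictly above 0.5** or
library size **strictly below 1500** (boundary cells are kept; cells failing
both are tallied once, under the mitochondrial count). Normalization is
log1p counts-per-10,000, which is invariant to sequencing depth.

`module_score()` is a binned-control activity score: genes are ranked into
25 average-expression bins, and each program gene is compared against
control genes from its own bin (the whole bin when it holds at most
`n_ctrl = 100` genes, otherwise `n_ctrl` sampled without replacement —
exhaustive small bins make the self-control identity exact: scoring the
entire transcriptome yields 0 for every cell). A random gene set scores ~0;
the defaults mirror the widely used binned-control scoring workflow. One
subtlety the tests respect: a shift applied to program genes in *all* cells
migrates those genes into higher bins, where the matched controls absorb the
shift — the score is a *relative* quantity. Recovery of a planted +δ program
is therefore measured as the score contrast between cells where the program
is active and cells where it is not, which the design recovers to within
10%.

Differential expression uses the two-sided Wilcoxon rank-sum test per gene
for single-cell contrasts and Student's t for bulk profiles, with a
pseudo-counted log2 fold-change and BH correction (one shared BH
implementation across the whole package). Genes constant across both groups
report p = 1; genes with zero within-group variance but different means fall
back to the rank test, whose statistic is defined there.

# Ligand-receptor communication

The communication probability between a sender and receiver type is the
saturating Hill form $P = LR/(k_h + LR)$ with $k_h = 0.5$, where $L$ and $R$
are the types' average normalized ligand and receptor expression (geometric
mean over subunits, so one absent subunit silences a complex). This is a
deliberate simplification of full mass-action communication models — no
cofactors, agonists or antagonists — with the same input/output shape, and
it is what every downstream number in this module means. Significance is by
label permutation (default 100 shuffles, `+1` correction); pathway
aggregation sums significant pair probabilities; interaction strengths and
link counts summarize each group's sender/receiver roles.

Communication patterns come from multiplicative-update Frobenius NMF
(hand-implemented; best of 20 random restarts; rows of W normalized to sum
1). The pattern count k is user-chosen; no automatic selection is provided.
Network centrality of a pathway graph reports four max-normalized roles:
sender (out-strength), receiver (in-strength), mediator (betweenness with
edge weight treated as capacity, i.e. distance 1/weight), and influencer
(total strength). The VEGF-style pathway activity score
(`module_score()` on the pathway's genes) and the pathway-aggregated
communication probability are different quantities and are never conflated.

# The synthetic-data generators

Every generator is a pure function of its parameters and seed and returns
its planted truth:

* `simulate_ld_blocks()` — AR(1) blocks, $R_{ij} = \rho^{|i-j|}$.
* `simulate_gwas()` — true effects under the annotation-dependent variance
  model; marginals $\hat\beta \sim \mathrm{MVN}(R\beta, R/n)$ per block with
  $\mathrm{se} = 1/\sqrt{n}$. A negative implied $\sigma_j^2$ is a fatal
  error, not clipped, so the truth stays well-defined.
* `simulate_eqtl_weights()` — $\lceil \text{sparsity}\cdot|S_j|\rceil$ SNPs
  per gene with N(0,1) weights; a configurable fraction shared across
  tissues.
* `simulate_twas_gwas()` — per-SNP effects $\sum_g \omega_{ig}\gamma_g$,
  inverting the expression-mediated model.
* `simulate_cell_expression()` — negative-binomial counts (dispersion 0.5)
  with log-normal library factors (sdlog 0.3), cell-type-specific means,
  mitochondrial genes (`MT-` prefix), planted per-type log2 fold-changes,
  and optional planted QC violators.

What the generators emulate: block LD, polygenic annotation-dependent
effect-size variance, sparse partially shared eQTL weights, overdispersed
counts with depth variation. What they do not: realistic human LD maps and
allele frequencies, imputation artifacts, doublets and ambient RNA, batch
effects, zero-inflation beyond the NB, or cell-type proportions of real
tissue. Passing recovery tests therefore demonstrates the estimators invert
their own generative assumptions correctly — not that those assumptions
capture every property of real data.

Problem sizes used by the test-suite studies were chosen to make Monte-Carlo
error small relative to the tested tolerances while keeping each study a
desk-scale computation: the null calibration of the enrichment regression
uses 1,000 replicates of 400 genes across 20 blocks at 200 bootstrap
iterations; recovery uses 50 replicates with 5 annotations; the TWAS oracle
uses 20 genes at n = 50,000; permutation oracles use 100,000 draws.

# Numerical choices and degenerate inputs

* Monte-Carlo tails are chunked and internally seeded; permutation and
  Monte-Carlo p-values use the `+1` correction except the overlap
  permutation, which follows its defining formula verbatim (and annotates
  zeros).
* Rank-deficient enrichment designs abort with the condition number rather
  than silently dropping columns (perfectly complementary annotation
  columns are collinear with the intercept by construction).
* Degenerate block resampling (zero bootstrap SE) reports NA p-values with
  a warning.
* Genes whose predicted-expression variance is ≤ 1e-12 are skipped and
  logged; multi-tissue genes whose components are all discarded likewise.
* Readers drop invalid GWAS rows (non-positive SE, p outside (0,1], p
  inconsistent with |beta/se| beyond 1e-6, duplicate ids) with counts, and
  reject dimension mismatches outright. Coordinates are 1-based inclusive
  everywhere.
* Strand-ambiguous SNPs cannot be oriented from alleles alone; they are
  kept with a warning rather than guessed.

# Known limitations

The gene statistic is a stand-in, not a reimplementation, for multi-marker
association tools (no gene-size/density covariates, no conditional
analysis). The communication model omits cofactor terms by design. MASHR
weight training, colocalization, clustering/embedding and cell-type
annotation are out of scope: labels and weights are inputs. Real-data
idiosyncrasies (platform effects, ancestry structure, imputation quality)
are not modeled by the generators, so absolute effect sizes from synthetic
studies should not be read as biological estimates.
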