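# Polygenic cell-type enrichment: annotation building, method-of-moments
# regression, block bootstrap, gene-property regression.

test_that("annotation building applies CP10K-log means and row-max scaling", {
  counts <- rbind(
    onlyA = c(5, 6, 0, 0),
    uniform = c(3, 3, 3, 3),
    zero = c(0, 0, 0, 0),
    mixed = c(8, 8, 2, 2)
  )
  colnames(counts) <- paste0("c", 1:4)
  expr <- cell_expression(counts, tibble::tibble(
    cell_id = paste0("c", 1:4), cell_type = c("A", "A", "B", "B"),
    sample = "s"))
  ann <- suppressMessages(build_annotations(expr, min_cells = 2))
  expect_setequal(ann$gene_id, c("onlyA", "uniform", "mixed"))
  row <- ann[ann$gene_id == "onlyA", ]
  expect_equal(row$A, 1)
  expect_equal(row$B, 0)
  expect_true(all(abs(ann$A) <= 1 & abs(ann$B) <= 1))
  # max normalization puts the dominant type at exactly 1
  expect_equal(max(ann[ann$gene_id == "mixed", c("A", "B")]), 1)

  # small cell types are excluded with a warning
  meta3 <- tibble::tibble(cell_id = paste0("c", 1:4),
                          cell_type = c("A", "A", "A", "rare"), sample = "s")
  expr3 <- cell_expression(counts, meta3)
  expect_warning(ann3 <- suppressMessages(build_annotations(expr3, min_cells = 2)),
                 "rare")
  expect_false("rare" %in% names(ann3))
})

test_that("the trace term matches the AR(1) closed form", {
  rho <- 0.7
  k <- 6
  ld <- simulate_ld_blocks(1, k, rho = rho)
  snpmap <- tibble::tibble(gene_id = "g1", snp_id = ld$blocks[[1]]$snps)
  gwas <- gwas_from_z(rnorm(k), snp_ids = snpmap$snp_id)
  inputs <- rolypoly_inputs(gwas, ld, snpmap)
  analytic <- sum(rho^(2 * abs(outer(1:k, 1:k, "-"))))
  expect_equal(inputs$trace, analytic, tolerance = 1e-10)
  expect_equal(inputs$offset, k / 10000)
})

test_that("the enrichment regression solves the hand-built linear system", {
  # two genes, identity LD, sigma_e2 = 0:
  # gene1: 5 SNPs, y = 10, alpha = 1; gene2: 5 SNPs, y = 5, alpha = 0
  # y_j = |S_j| (gamma0 + gamma1 alpha_j)  =>  gamma0 = 1, gamma1 = 1
  z <- c(rep(sqrt(2), 5), rep(1, 5)) # sum z^2 = 10 and 5 at n = 1
  gwas <- gwas_from_z(z, n = 1)
  ld <- identity_ld(gwas$snp_id)
  snpmap <- tibble::tibble(gene_id = rep(c("g1", "g2"), each = 5),
                           snp_id = gwas$snp_id)
  ann <- tibble::tibble(gene_id = c("g1", "g2"), ct = c(1, 0))
  fit <- rolypoly_fit(gwas, ld, snpmap, ann, sigma_e2 = 0)
  expect_equal(fit$gamma0_hat, 1, tolerance = 1e-10)
  expect_equal(unname(fit$gamma_hat["ct"]), 1, tolerance = 1e-10)

  # zero response with zero offset gives exactly zero coefficients
  gwas0 <- gwas_from_z(rep(0, 10), n = 1)
  gwas0$p <- 1
  fit0 <- rolypoly_fit(gwas0, ld, snpmap, ann, sigma_e2 = 0)
  expect_equal(fit0$gamma0_hat, 0)
  expect_equal(unname(fit0$gamma_hat), 0)
})

test_that("identity-LD fits agree with a brute-force normal-equations oracle", {
  set.seed(31)
  world <- make_gwas_world(n_genes = 30, snps_per_gene = 4, rho = 0)
  gwas <- gwas_from_z(rnorm(nrow(world$ld$index), 0, 1.3),
                      snp_ids = world$ld$index$snp_id)
  ann <- tibble::tibble(gene_id = world$genes,
                        a1 = runif(30), a2 = runif(30))
  fit <- rolypoly_fit(gwas, world$ld, world$snpmap, ann, sigma_e2 = 1)
  # oracle: explicit normal equations on y_j = |S_j|(g0 + g.a) + |S_j|/n
  y <- vapply(world$genes, function(g) {
    snps <- world$snpmap$snp_id[world$snpmap$gene_id == g]
    sum((gwas$beta[match(snps, gwas$snp_id)] / gwas$se[match(snps, gwas$snp_id)])^2) / 10000
  }, numeric(1))
  X <- cbind(4, 4 * ann$a1, 4 * ann$a2)
  y_adj <- y - 4 / 10000
  oracle <- solve(t(X) %*% X, t(X) %*% y_adj)
  expect_equal(unname(c(fit$gamma0_hat, fit$gamma_hat)),
               as.numeric(oracle), tolerance = 1e-8)
})

test_that("the estimator is equivariant to rescaling the annotations", {
  set.seed(37)
  world <- make_gwas_world(n_genes = 30, snps_per_gene = 3, rho = 0.4)
  ann <- tibble::tibble(gene_id = world$genes, ct = runif(30))
  sim <- simulate_gwas(world$ld, world$snpmap, ann, gamma0 = 2e-4,
                       gamma = 4e-4, n = 5000, seed = 8)
  fit1 <- rolypoly_fit(sim$gwas, world$ld, world$snpmap, ann)
  ann_scaled <- dplyr::mutate(ann, ct = ct * 5)
  fit2 <- rolypoly_fit(sim$gwas, world$ld, world$snpmap, ann_scaled)
  expect_equal(fit2$gamma0_hat, fit1$gamma0_hat, tolerance = 1e-8)
  expect_equal(unname(fit2$gamma_hat), unname(fit1$gamma_hat) / 5,
               tolerance = 1e-8)
})

test_that("block bootstrap flags degenerate resampling and is stable in n_boot", {
  # identical blocks: every resample reproduces the same fit, se = 0 -> NA
  z <- rep(c(1, 2, 0.5), 2)
  gwas <- gwas_from_z(z, n = 1000)
  ld <- identity_ld(gwas$snp_id, chunk = 3)
  snpmap <- tibble::tibble(gene_id = rep(c("g1", "g2"), each = 3),
                           snp_id = gwas$snp_id)
  ann <- tibble::tibble(gene_id = c("g1", "g2"), ct = c(1, 0))
  fit <- rolypoly_fit(gwas, ld, snpmap, ann)
  # one-gene blocks also make lone-block resamples singular; both warnings
  # are expected here
  w <- testthat::capture_warnings(
    fit <- block_bootstrap(fit, n_boot = 50, seed = 1)
  )
  expect_true(any(grepl("Degenerate", w)))
  expect_true(all(is.na(fit$boot$p)))
  expect_error(block_bootstrap(
    rolypoly_fit(gwas, identity_ld(gwas$snp_id), snpmap, ann),
    n_boot = 10, seed = 1), "at least 2")

  # doubling n_boot moves the bootstrap SE by < 10%
  set.seed(43)
  world <- make_gwas_world(n_genes = 100, snps_per_gene = 3,
                           genes_per_block = 5, rho = 0.3)
  ann <- tibble::tibble(gene_id = world$genes, ct = runif(100))
  sim <- simulate_gwas(world$ld, world$snpmap, ann, gamma0 = 2e-4,
                       gamma = 2e-4, n = 10000, seed = 19)
  base <- rolypoly_fit(sim$gwas, world$ld, world$snpmap, ann)
  se1 <- block_bootstrap(base, n_boot = 1000, seed = 5)$boot$boot_se["ct"]
  se2 <- block_bootstrap(base, n_boot = 2000, seed = 6)$boot$boot_se["ct"]
  expect_lt(abs(se2 - se1) / se1, 0.1)
})

test_that("planted enrichment is recovered within bootstrap uncertainty", {
  world <- make_gwas_world(n_genes = 200, snps_per_gene = 3,
                           genes_per_block = 10, rho = 0.3)
  set.seed(51)
  ann <- tibble::tibble(gene_id = world$genes, target = runif(200),
                        decoy = runif(200))
  gamma_true <- c(target = 5e-4, decoy = 0)
  hits <- vapply(1:10, function(i) {
    sim <- simulate_gwas(world$ld, world$snpmap, ann, gamma0 = 1e-4,
                         gamma = unname(gamma_true), n = 10000,
                         seed = 700 + i)
    fit <- block_bootstrap(
      rolypoly_fit(sim$gwas, world$ld, world$snpmap, ann),
      n_boot = 200, seed = i)
    abs(fit$gamma_hat["target"] - gamma_true["target"]) <=
      3 * fit$boot$boot_se["target"]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("gene-property regression recovers planted specificity signal", {
  set.seed(61)
  n_genes <- 300
  genes <- sprintf("g%03d", 1:n_genes)
  ann <- tibble::tibble(gene_id = genes, hot = runif(n_genes),
                        cold = runif(n_genes))
  me <- tibble::tibble(gene_id = genes, mean_expr = runif(n_genes, 0, 5))
  # z tracks the 'hot' specificity strongly
  z <- 2 * ann$hot + rnorm(n_genes, 0, 0.1)
  gr <- tibble::tibble(gene_id = genes, p = pnorm(z, lower.tail = FALSE))
  res <- gene_property_enrichment(gr, ann, me)
  expect_lt(res$p[res$cell_type == "hot"], 0.01)
  expect_gt(res$coefficient[res$cell_type == "hot"], 0)
  expect_equal(res$bonferroni_p, pmin(1, res$p * 2))

  # null: no association in most replicates
  null_ok <- vapply(1:50, function(i) {
    z0 <- rnorm(n_genes)
    gr0 <- tibble::tibble(gene_id = genes, p = pnorm(z0, lower.tail = FALSE))
    res0 <- gene_property_enrichment(gr0, ann[, c("gene_id", "hot")], me)
    res0$p >= 0.05
  }, logical(1))
  expect_gte(mean(null_ok), 0.85)

  # constant specificity columns are skipped with a warning
  ann_const <- dplyr::mutate(ann, cold = 0.5)
  expect_warning(res2 <- gene_property_enrichment(gr, ann_const, me),
                 "constant")
  expect_false("cold" %in% res2$cell_type)
})

test_that("tidy, glance and autoplot expose the fit", {
  world <- make_gwas_world(n_genes = 40, snps_per_gene = 3, rho = 0.2)
  set.seed(71)
  ann <- tibble::tibble(gene_id = world$genes, ct = runif(40))
  sim <- simulate_gwas(world$ld, world$snpmap, ann, 2e-4, 2e-4, 5000, seed = 2)
  fit <- block_bootstrap(rolypoly_fit(sim$gwas, world$ld, world$snpmap, ann),
                         n_boot = 100, seed = 3)
  td <- tidy(fit)
  expect_named(td, c("cell_type", "gamma", "boot_se", "t", "p"))
  gl <- glance(fit)
  expect_equal(gl$n_genes, 40)
  expect_s3_class(autoplot(fit), "ggplot")
})
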