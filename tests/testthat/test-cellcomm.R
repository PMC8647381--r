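# Ligand-receptor communication: Hill probabilities, permutation
# significance, aggregation, strengths, NMF patterns, centrality.

# A normalized matrix with constant expression per cell type for exact
# Hill-function checks.
const_expr <- function(values, n_per_type = 4) {
  # values: genes x types matrix of constant normalized expression
  types <- colnames(values)
  m <- values[, rep(types, each = n_per_type), drop = FALSE]
  colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  labels <- rep(types, each = n_per_type)
  list(m = m, labels = labels)
}

lrdb_tbl <- function(pair_id, ligand, receptor, pathway) {
  tibble::tibble(pair_id = pair_id, ligand_genes = ligand,
                 receptor_genes = receptor, pathway = pathway)
}

test_that("the Hill communication probability hits its fixed points", {
  vals <- rbind(L1 = c(A = 1, B = 0), R1 = c(A = 0.5, B = 1),
                Rsub1 = c(A = 1, B = 2), Rsub2 = c(A = 0, B = 2))
  ce <- const_expr(vals)
  db <- lrdb_tbl(c("p1", "p2"), list("L1", "L1"),
                 list("R1", c("Rsub1", "Rsub2")), c("path1", "path2"))
  probs <- lr_probability(ce$m, ce$labels, db, kh = 0.5)

  # L * R = 0 gives P = 0 (ligand absent in B)
  expect_equal(probs$prob[probs$sender == "B" & probs$pair_id == "p1"],
               c(0, 0))
  # L * R = kh gives exactly 0.5 (A -> A: 1 * 0.5 = kh)
  expect_equal(probs$prob[probs$sender == "A" & probs$receiver == "A" &
                            probs$pair_id == "p1"], 0.5)
  # multi-subunit receptor with one absent subunit: geometric mean 0
  expect_true(all(probs$prob[probs$receiver == "A" &
                               probs$pair_id == "p2"] == 0))
  # receptor fully present in B: positive probability
  expect_gt(probs$prob[probs$sender == "A" & probs$receiver == "B" &
                         probs$pair_id == "p2"], 0)
  expect_error(lr_probability(ce$m, ce$labels, db, kh = 0), "positive")
})

test_that("probabilities are monotone in ligand and receptor expression", {
  db <- lrdb_tbl("p1", list("L1"), list("R1"), "path")
  lvls <- c(0.2, 0.5, 1, 2)
  ps <- vapply(lvls, function(lv) {
    vals <- rbind(L1 = c(A = lv, B = 0), R1 = c(A = 0, B = 1))
    ce <- const_expr(vals)
    probs <- lr_probability(ce$m, ce$labels, db)
    probs$prob[probs$sender == "A" & probs$receiver == "B"]
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("adding cells of a new type leaves existing probabilities unchanged", {
  set.seed(19)
  m <- normalized_matrix(30, 30, seed = 19)
  rownames(m)[1:2] <- c("L1", "R1")
  labels <- rep(c("A", "B", "C"), each = 10)
  db <- lrdb_tbl("p1", list("L1"), list("R1"), "path")
  base <- lr_probability(m, labels, db)
  extra <- cbind(m, normalized_matrix(30, 5, seed = 20))
  colnames(extra) <- sprintf("c%03d", seq_len(ncol(extra)))
  rownames(extra) <- rownames(m)
  probs2 <- lr_probability(extra, c(labels, rep("D", 5)), db)
  joined <- dplyr::inner_join(base, probs2,
                              by = c("sender", "receiver", "pair_id"))
  expect_equal(joined$prob.x, joined$prob.y, tolerance = 1e-12)
})

test_that("label permutation flags planted directional signaling", {
  set.seed(21)
  n_per <- 40
  m <- normalized_matrix(60, 3 * n_per, noise_sd = 0.2, seed = 21)
  labels <- rep(c("A", "B", "C"), each = n_per)
  rownames(m)[1:2] <- c("LIG", "REC")
  # ligand high only in A, receptor high only in B
  m["LIG", ] <- 0.05
  m["REC", ] <- 0.05
  m["LIG", labels == "A"] <- 3
  m["REC", labels == "B"] <- 3
  db <- lrdb_tbl("planted", list("LIG"), list("REC"), "path")
  res <- comm_perm_test(m, labels, db, n_perm = 100, seed = 5)
  planted <- res[res$sender == "A" & res$receiver == "B", ]
  expect_lte(planted$perm_p, 0.02)
  expect_true(all(res$perm_p >= 1 / 101))
})

test_that("permutation p-values are uniform for exchangeable expression", {
  set.seed(23)
  n_genes <- 80
  m <- normalized_matrix(n_genes, 90, noise_sd = 0.5, seed = 23)
  labels <- rep(c("A", "B", "C"), each = 30)
  db <- lrdb_tbl(sprintf("p%02d", 1:40),
                 as.list(rownames(m)[1:40]),
                 as.list(rownames(m)[41:80]),
                 "path")
  res <- comm_perm_test(m, labels, db, n_perm = 199, seed = 7)
  # discrete perm_p values tie; the KS statistic is still the right summary
  expect_gt(suppressWarnings(stats::ks.test(res$perm_p, "punif"))$p.value,
            0.01)
})

test_that("pathway aggregation and strengths equal brute-force sums", {
  comm <- tibble::tibble(
    sender = c("A", "A", "A", "B"),
    receiver = c("B", "B", "C", "A"),
    pair_id = c("p1", "p2", "p1", "p1"),
    pathway = c("VEGF", "VEGF", "VEGF", "MIF"),
    prob = c(0.2, 0.3, 0.4, 0.6),
    perm_p = c(0.01, 0.02, 0.5, 0.01)
  )
  agg <- pathway_aggregate(comm)
  expect_equal(agg$prob[agg$sender == "A" & agg$receiver == "B" &
                          agg$pathway == "VEGF"], 0.5)
  # non-significant entry contributes zero
  expect_equal(agg$prob[agg$sender == "A" & agg$receiver == "C" &
                          agg$pathway == "VEGF"], 0)
  # brute-force oracle over all rows
  brute <- aggregate(prob ~ sender + receiver + pathway,
                     data = transform(as.data.frame(comm),
                                      prob = prob * (perm_p < 0.05)),
                     FUN = sum)
  merged <- merge(as.data.frame(agg), brute,
                  by = c("sender", "receiver", "pathway"))
  expect_equal(merged$prob.x, merged$prob.y)

  st <- interaction_strengths(comm)
  expect_equal(st$outgoing[st$cell_group == "A"], 0.5)
  expect_equal(st$incoming[st$cell_group == "A"], 0.6)
  expect_equal(st$n_links[st$cell_group == "A"], 3L)
  expect_equal(st$incoming[st$cell_group == "B"], 0.5)
  expect_equal(st$outgoing[st$cell_group == "C"], 0)

  # a symmetric tensor gives equal outgoing and incoming strengths
  sym <- tibble::tibble(
    sender = c("A", "B"), receiver = c("B", "A"),
    pair_id = "p1", pathway = "X", prob = 0.4, perm_p = 0.01
  )
  st2 <- interaction_strengths(sym)
  expect_equal(st2$outgoing, st2$incoming)
})

test_that("NMF recovers exact low rank and improves with k", {
  set.seed(29)
  w0 <- matrix(runif(6, 0.5, 2), 6, 1)
  h0 <- matrix(runif(8, 0.5, 2), 1, 8)
  rank1 <- w0 %*% h0
  dec <- nmf_patterns(rank1, k = 1, seed = 1, n_restart = 5)
  expect_lt(dec$relative_error, 1e-6)
  expect_true(all(dec$W >= 0) && all(dec$H >= 0))
  expect_equal(rowSums(dec$W), rep(1, 6))

  mat <- matrix(runif(60, 0, 3), 6, 10)
  errs <- vapply(1:3, function(k) {
    nmf_patterns(mat, k, seed = 2, n_restart = 10)$reconstruction_error
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  expect_error(nmf_patterns(mat, k = 6, seed = 1), "smaller")
  expect_error(nmf_patterns(-mat, k = 2, seed = 1), "non-negative")

  td <- tidy(dec)
  expect_setequal(unique(td$matrix), c("W", "H"))
  expect_equal(glance(dec)$k, 1)
  expect_s3_class(autoplot(dec), "ggplot")
})

test_that("pathway centrality matches hand-computed graph measures", {
  # star: A sends to B, C, D
  star <- tibble::tibble(
    sender = "A", receiver = c("B", "C", "D"),
    pair_id = paste0("p", 1:3), pathway = "star",
    prob = c(0.2, 0.3, 0.4), perm_p = 0.01
  )
  cs <- pathway_centrality(star, "star")
  expect_equal(cs$sender[cs$cell_group == "A"], 1)
  expect_true(all(cs$sender[cs$cell_group != "A"] == 0))
  expect_equal(cs$receiver[cs$cell_group == "D"], 1) # largest in-strength
  expect_true(all(cs$mediator == 0))

  # two nodes, one edge
  two <- tibble::tibble(sender = "A", receiver = "B", pair_id = "p1",
                        pathway = "x", prob = 0.5, perm_p = 0.01)
  ct <- pathway_centrality(two, "x")
  expect_equal(ct$sender, c(1, 0))
  expect_equal(ct$receiver, c(0, 1))
  expect_true(all(ct$mediator == 0))

  # 3-node chain A -> B -> C: B is the only mediator
  chain <- tibble::tibble(
    sender = c("A", "B"), receiver = c("B", "C"),
    pair_id = c("p1", "p2"), pathway = "chain",
    prob = c(0.5, 0.5), perm_p = 0.01
  )
  cc <- pathway_centrality(chain, "chain")
  expect_equal(cc$mediator, c(0, 1, 0))
  expect_equal(cc$influencer[cc$cell_group == "B"], 1)
  expect_warning(z <- pathway_centrality(chain, "absent"), "no significant")
  expect_true(all(z$sender == 0))
})

test_that("the signaling matrix pivot matches manual sums", {
  comm <- tibble::tibble(
    sender = c("A", "A", "B"), receiver = c("B", "C", "C"),
    pair_id = "p", pathway = c("X", "X", "Y"),
    prob = c(0.2, 0.3, 0.4), perm_p = 0.01
  )
  m <- signaling_matrix(pathway_aggregate(comm), role = "sender")
  expect_equal(m["A", "X"], 0.5)
  expect_equal(m["B", "Y"], 0.4)
  expect_equal(m["B", "X"], 0)
  mi <- signaling_matrix(pathway_aggregate(comm), role = "receiver")
  expect_equal(mi["C", "X"], 0.3)
})
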