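# Simplified ligand-receptor communication inference: Hill-type per-pair
# probabilities from cell-type mean expression, label-permutation
# significance, pathway aggregation, interaction strengths, NMF
# communication patterns, and network centrality.
#
# The per-pair model is a deliberate simplification of mass-action kinetic
# communication models: P = (L * R) / (kh + L * R), with L and R the
# (geometric-mean, for multi-subunit complexes) average normalized ligand
# and receptor expression in the sender and receiver type. No cofactor,
# agonist or antagonist terms are modeled; every output of this module is
# produced under that stated form.

# Mean normalized expression per gene per cell type.
type_means <- function(normalized, labels) {
  types <- sort(unique(labels))
  m <- vapply(types, function(tt) {
    Matrix::rowMeans(normalized[, labels == tt, drop = FALSE])
  }, numeric(nrow(normalized)))
  colnames(m) <- types
  m
}

# Probability table for one genes-x-types mean matrix.
lr_prob_from_means <- function(means, lrdb, kh) {
  types <- colnames(means)
  grid <- tidyr::expand_grid(sender = types, receiver = types)
  purrr::pmap_dfr(
    list(lrdb$pair_id, lrdb$ligand_genes, lrdb$receptor_genes, lrdb$pathway),
    function(pair_id, lg, rg, pathway) {
      L <- vapply(types, function(tt) geom_mean(means[lg, tt]), numeric(1))
      R <- vapply(types, function(tt) geom_mean(means[rg, tt]), numeric(1))
      lr <- L[grid$sender] * R[grid$receiver]
      tibble(sender = grid$sender, receiver = grid$receiver,
             pair_id = pair_id, pathway = pathway,
             prob = unname(lr / (kh + lr)))
    }
  )
}

#' Ligand-receptor communication probabilities between cell types
#'
#' For each (sender type, receiver type, pair), the communication
#' probability is the saturating Hill form `P = L R / (kh + L R)` of the
#' sender's average normalized ligand expression times the receiver's
#' average normalized receptor expression; multi-subunit ligands/receptors
#' use the geometric mean over subunits, so one absent subunit zeroes the
#' signal.
#'
#' @param normalized Normalized genes x cells matrix (see
#'   [normalize_rle()]).
#' @param labels Per-cell type labels, aligned with the matrix columns.
#' @param lrdb Ligand-receptor pair tibble (see [read_lr_pairs()]); pairs
#'   with genes absent from the matrix are skipped with a message.
#' @param kh Half-saturation constant (> 0; default 0.5).
#' @return A tibble with `sender`, `receiver`, `pair_id`, `pathway`, `prob`.
#' @export
lr_probability <- function(normalized, labels, lrdb, kh = 0.5) {
  if (kh <= 0) stop_scgwas("kh must be positive.")
  genes <- rownames(normalized)
  present <- vapply(seq_len(nrow(lrdb)), function(i) {
    all(c(lrdb$ligand_genes[[i]], lrdb$receptor_genes[[i]]) %in% genes)
  }, logical(1))
  if (!all(present)) {
    inform(sprintf("Skipped %d ligand-receptor pair(s) with genes absent from the matrix.",
                   sum(!present)))
    lrdb <- lrdb[present, ]
  }
  if (nrow(lrdb) == 0) stop_scgwas("No ligand-receptor pair has all genes present.")
  lr_prob_from_means(type_means(normalized, labels), lrdb, kh)
}

#' Label-permutation significance of communication probabilities
#'
#' Shuffles the cell-type labels `n_perm` times, recomputes every
#' communication probability, and reports per entry
#' `perm_p = (1 + #\{P_perm >= P_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams lr_probability
#' @param n_perm Number of label permutations (default 100; fewer than 10
#'   draws a warning).
#' @param seed Integer seed.
#' @return The [lr_probability()] tibble with an added `perm_p` column.
#' @export
comm_perm_test <- function(normalized, labels, lrdb, n_perm = 100,
                           seed = NULL, kh = 0.5) {
  if (length(unique(labels)) < 2) {
    stop_scgwas("Need at least 2 cell types.")
  }
  if (n_perm < 10) warn_scgwas("n_perm < 10 gives very coarse p-values.")
  obs <- lr_probability(normalized, labels, lrdb, kh = kh)
  lrdb_used <- lrdb[lrdb$pair_id %in% unique(obs$pair_id), ]
  exceed <- numeric(nrow(obs))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      perm <- lr_prob_from_means(
        type_means(normalized, sample(labels)), lrdb_used, kh
      )
      exceed <- exceed + (perm$prob >= obs$prob)
    }
  })
  obs$perm_p <- (1 + exceed) / (n_perm + 1)
  obs
}

#' Aggregate significant pair probabilities per pathway
#'
#' Sums the probabilities of significant (default `perm_p < 0.05`)
#' ligand-receptor pairs within each pathway for every sender/receiver
#' combination; pathways with no significant pair contribute 0.
#'
#' @param comm Communication tibble with `perm_p` (see [comm_perm_test()]).
#' @param alpha Significance gate on `perm_p` (default 0.05).
#' @return A tibble with `sender`, `receiver`, `pathway`, `prob`.
#' @export
pathway_aggregate <- function(comm, alpha = 0.05) {
  comm |>
    dplyr::mutate(sig = .data$perm_p < alpha) |>
    dplyr::group_by(.data$sender, .data$receiver, .data$pathway) |>
    dplyr::summarise(prob = sum(.data$prob[.data$sig]), .groups = "drop")
}

#' Per-cell-group interaction strengths
#'
#' Outgoing strength is the sum of significant probabilities with the group
#' as sender, incoming likewise as receiver, and `n_links` the number of
#' significant entries involving the group in either role.
#'
#' @inheritParams pathway_aggregate
#' @return A tibble with `cell_group`, `outgoing`, `incoming`, `n_links`.
#' @export
interaction_strengths <- function(comm, alpha = 0.05) {
  sig <- comm[comm$perm_p < alpha, ]
  groups <- sort(unique(c(comm$sender, comm$receiver)))
  purrr::map_dfr(groups, function(g) {
    tibble(
      cell_group = g,
      outgoing = sum(sig$prob[sig$sender == g]),
      incoming = sum(sig$prob[sig$receiver == g]),
      n_links = sum(sig$sender == g | sig$receiver == g)
    )
  })
}

#' Non-negative matrix factorization of communication patterns
#'
#' Factorizes a non-negative cell-group x pathway signaling matrix into `k`
#' latent communication patterns by multiplicative-update NMF minimizing the
#' Frobenius reconstruction error, keeping the best of `n_restart` random
#' restarts. The returned `W` has rows normalized to sum 1 (a cell group's
#' loading distribution over patterns).
#'
#' @param mat Non-negative matrix (cell groups x pathways), e.g. the
#'   sender-side pathway aggregation pivoted wide.
#' @param k Number of patterns; must be smaller than both dimensions.
#' @param seed Integer seed.
#' @param n_restart Random restarts (default 20).
#' @param max_iter,tol Update iterations per restart and relative
#'   convergence tolerance.
#' @return An object of class `comm_patterns` with `W` (groups x k,
#'   row-normalized), `H` (k x pathways), `k`, `reconstruction_error`
#'   (Frobenius) and `relative_error`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
nmf_patterns <- function(mat, k, seed = NULL, n_restart = 20,
                         max_iter = 500, tol = 1e-9) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop_scgwas("NMF input must be non-negative.")
  if (k >= min(dim(mat))) {
    stop_scgwas("k (%d) must be smaller than both matrix dimensions (%d x %d).",
                k, nrow(mat), ncol(mat))
  }
  nr <- nrow(mat)
  nc <- ncol(mat)
  eps <- 1e-12
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restart)) {
      W <- matrix(runif(nr * k, 0.1, 1), nr, k)
      H <- matrix(runif(k * nc, 0.1, 1), k, nc)
      err_prev <- Inf
      for (it in seq_len(max_iter)) {
        H <- H * (crossprod(W, mat) + eps) / (crossprod(W) %*% H + eps)
        W <- W * (mat %*% t(H) + eps) / (W %*% tcrossprod(H) + eps)
        if (it %% 10 == 0) {
          err <- sqrt(sum((mat - W %*% H)^2))
          if (is.finite(err_prev) && err_prev - err < tol * max(err, 1)) break
          err_prev <- err
        }
      }
      err <- sqrt(sum((mat - W %*% H)^2))
      if (is.null(best) || err < best$err) {
        best <- list(W = W, H = H, err = err)
      }
    }
  })
  rowsum_W <- rowSums(best$W)
  W_norm <- best$W / ifelse(rowsum_W > 0, rowsum_W, 1)
  dimnames(W_norm) <- list(rownames(mat), paste0("pattern", seq_len(k)))
  dimnames(best$H) <- list(paste0("pattern", seq_len(k)), colnames(mat))
  structure(list(
    W = W_norm, H = best$H, k = k,
    reconstruction_error = best$err,
    relative_error = best$err / max(sqrt(sum(mat^2)), 1e-300)
  ), class = "comm_patterns")
}

#' @export
print.comm_patterns <- function(x, ...) {
  cat(sprintf("<comm_patterns: %d pattern(s), %d group(s) x %d pathway(s), relative error %.3g>\n",
              x$k, nrow(x$W), ncol(x$H), x$relative_error))
  invisible(x)
}

#' Network centrality of a pathway's communication graph
#'
#' Builds the weighted directed graph of pathway-aggregated significant
#' probabilities and reports four centrality roles per cell group, each
#' max-normalized to \[0, 1\]: sender (weighted out-strength), receiver
#' (in-strength), mediator (betweenness, treating edge weight as capacity,
#' i.e. distance 1/weight), and influencer (total strength).
#'
#' @param comm Communication tibble with `perm_p` (see [comm_perm_test()]).
#' @param pathway Pathway name to analyze.
#' @param alpha Significance gate (default 0.05).
#' @return A tibble with `cell_group`, `sender`, `receiver`, `mediator`,
#'   `influencer`.
#' @export
pathway_centrality <- function(comm, pathway, alpha = 0.05) {
  groups <- sort(unique(c(comm$sender, comm$receiver)))
  agg <- pathway_aggregate(comm, alpha = alpha)
  edges <- agg[agg$pathway == pathway & agg$prob > 0, ]
  zero <- tibble(cell_group = groups, sender = 0, receiver = 0,
                 mediator = 0, influencer = 0)
  if (nrow(edges) == 0) {
    warn_scgwas("Pathway '%s' has no significant entries; returning zeros.",
                pathway)
    return(zero)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$sender, to = edges$receiver, weight = edges$prob),
    directed = TRUE, vertices = groups
  )
  out_s <- igraph::strength(g, mode = "out")
  in_s <- igraph::strength(g, mode = "in")
  btw <- igraph::betweenness(g, directed = TRUE,
                             weights = 1 / igraph::E(g)$weight)
  total <- out_s + in_s
  norm1 <- function(x) if (max(x) > 0) x / max(x) else x
  tibble(
    cell_group = groups,
    sender = unname(norm1(out_s[groups])),
    receiver = unname(norm1(in_s[groups])),
    mediator = unname(norm1(btw[groups])),
    influencer = unname(norm1(total[groups]))
  )
}

#' Pivot a pathway aggregation to a signaling matrix
#'
#' Convenience for [nmf_patterns()]: sums a pathway aggregation over the
#' opposite role to give a cell-group x pathway matrix of outgoing
#' (`role = "sender"`) or incoming (`role = "receiver"`) signaling.
#'
#' @param agg A [pathway_aggregate()] tibble.
#' @param role `"sender"` (outgoing, default) or `"receiver"` (incoming).
#' @return A numeric matrix, cell groups x pathways.
#' @export
signaling_matrix <- function(agg, role = c("sender", "receiver")) {
  role <- match.arg(role)
  long <- agg |>
    dplyr::group_by(.data[[role]], .data$pathway) |>
    dplyr::summarise(prob = sum(.data$prob), .groups = "drop")
  wide <- tidyr::pivot_wider(long, names_from = "pathway",
                             values_from = "prob", values_fill = 0)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide[[role]]
  m
}
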