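# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a polygenic enrichment fit
#'
#' @param x A [rolypoly_fit()] object.
#' @param ... Unused.
#' @return A tibble with one row per cell type: `cell_type`, `gamma`, and,
#'   after [block_bootstrap()], `boot_se`, `t`, `p`.
#' @method tidy rolypoly_fit
#' @export
tidy.rolypoly_fit <- function(x, ...) {
  out <- tibble(cell_type = x$ann_cols, gamma = unname(x$gamma_hat))
  if (!is.null(x$boot)) {
    out$boot_se <- unname(x$boot$boot_se[x$ann_cols])
    out$t <- unname(x$boot$t[x$ann_cols])
    out$p <- unname(x$boot$p[x$ann_cols])
  }
  out
}

#' Glance at a polygenic enrichment fit
#'
#' @param x A [rolypoly_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble: `gamma0`, `n_genes`, `n_cell_types`,
#'   `sigma_e2`, `n_boot`.
#' @method glance rolypoly_fit
#' @export
glance.rolypoly_fit <- function(x, ...) {
  tibble(
    gamma0 = x$gamma0_hat,
    n_genes = nrow(x$per_gene),
    n_cell_types = length(x$ann_cols),
    sigma_e2 = x$sigma_e2,
    n_boot = if (is.null(x$boot)) NA_integer_ else x$boot$n_boot
  )
}

#' Plot cell-type enrichment estimates
#'
#' Bar plot of the per-cell-type enrichment coefficients, with bootstrap
#' intervals (+/- 1.96 SE) when available.
#'
#' @param object A [rolypoly_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rolypoly_fit
#' @export
autoplot.rolypoly_fit <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$cell_type, .data$gamma), y = .data$gamma
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "enrichment coefficient (gamma)") +
    ggplot2::theme_minimal()
  if (!is.null(object$boot)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$gamma - 1.96 * .data$boot_se,
                   ymax = .data$gamma + 1.96 * .data$boot_se),
      width = 0.2
    )
  }
  p
}

#' Tidy a communication-pattern decomposition
#'
#' @param x A [nmf_patterns()] object.
#' @param ... Unused.
#' @return A long tibble with `matrix` (`"W"` or `"H"`), `row`, `column`,
#'   `value`.
#' @method tidy comm_patterns
#' @export
tidy.comm_patterns <- function(x, ...) {
  w <- as_tibble(as.data.frame.table(x$W, stringsAsFactors = FALSE))
  h <- as_tibble(as.data.frame.table(x$H, stringsAsFactors = FALSE))
  names(w) <- names(h) <- c("row", "column", "value")
  dplyr::bind_rows(
    dplyr::mutate(w, matrix = "W", .before = 1),
    dplyr::mutate(h, matrix = "H", .before = 1)
  )
}

#' Glance at a communication-pattern decomposition
#'
#' @param x A [nmf_patterns()] object.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n_groups`, `n_pathways`,
#'   `reconstruction_error`, `relative_error`.
#' @method glance comm_patterns
#' @export
glance.comm_patterns <- function(x, ...) {
  tibble(
    k = x$k,
    n_groups = nrow(x$W),
    n_pathways = ncol(x$H),
    reconstruction_error = x$reconstruction_error,
    relative_error = x$relative_error
  )
}

#' Plot communication-pattern loadings
#'
#' Heatmap of the row-normalized cell-group loadings over patterns.
#'
#' @param object A [nmf_patterns()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot comm_patterns
#' @export
autoplot.comm_patterns <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$matrix == "W", ]
  ggplot2::ggplot(d, ggplot2::aes(.data$column, .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "pattern", y = NULL, fill = "loading") +
    ggplot2::theme_minimal()
}

#' Plot a pathway MDS map
#'
#' Scatter of the first two classical-scaling coordinates of the pathway
#' Jaccard distances, colored by cluster and labeled by each cluster's most
#' significant pathway.
#'
#' @param coords A [pathway_mds()] tibble.
#' @return A ggplot object.
#' @export
plot_pathway_map <- function(coords) {
  ggplot2::ggplot(coords, ggplot2::aes(.data$mds1, .data$mds2,
                                       color = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "MDS1", y = "MDS2", color = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot incoming vs outgoing interaction strengths
#'
#' @param strengths An [interaction_strengths()] tibble.
#' @return A ggplot object with point size mapped to the link count.
#' @export
plot_interaction_strengths <- function(strengths) {
  ggplot2::ggplot(strengths, ggplot2::aes(.data$outgoing, .data$incoming,
                                          size = .data$n_links)) +
    ggplot2::geom_point(alpha = 0.7, color = "firebrick") +
    ggplot2::labs(x = "outgoing interaction strength",
                  y = "incoming interaction strength", size = "links") +
    ggplot2::theme_minimal()
}
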