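# broom-style accessors and ggplot2 autoplot methods for result objects.

#' @method tidy zf_classification
#' @export
tidy.zf_classification <- function(x, ...) {
  as_tibble(x)
}

#' @method glance zf_classification
#' @export
glance.zf_classification <- function(x, ...) {
  tibble(
    n_proteins = nrow(x),
    n_classified = sum(x$label != "unclassified"),
    n_unclassified = sum(x$label == "unclassified"),
    n_tandem = sum(x$arrangement == "tandem"),
    n_dispersed = sum(x$arrangement == "dispersed"),
    n_single = sum(x$arrangement == "single"),
    n_mixed = sum(x$arrangement == "mixed")
  )
}

#' @method tidy zf_subset_summary
#' @export
tidy.zf_subset_summary <- function(x, ...) {
  x$by_subset
}

#' @method glance zf_subset_summary
#' @export
glance.zf_subset_summary <- function(x, ...) {
  tibble(n_proteins = x$n_proteins, n_subsets_seen = sum(x$by_subset$n > 0))
}

#' Bar chart of subset counts
#'
#' @param object A [summarize_subsets()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot zf_subset_summary
#' @export
autoplot.zf_subset_summary <- function(object, ...) {
  d <- filter(object$by_subset, .data$n > 0 | .data$label != "unclassified")
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$label, levels = unique(.data$label)), y = .data$n
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Proteins",
                  title = "C2H2 zinc-finger proteins per subset") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method tidy zf_enrichment
#' @export
tidy.zf_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' @method glance zf_enrichment
#' @export
glance.zf_enrichment <- function(x, ...) {
  tibble(
    n_terms = nrow(x),
    n_over = sum(x$direction == "over"),
    n_under = sum(x$direction == "under"),
    correction = attr(x, "correction") %||% NA_character_
  )
}

#' Volcano-style plot of term enrichment
#'
#' @param object An [enrich()] result.
#' @param alpha Significance line drawn at this adjusted p-value.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot zf_enrichment
#' @export
autoplot.zf_enrichment <- function(object, alpha = 0.05, ...) {
  d <- mutate(as_tibble(object),
              log_fold = log2((.data$k / .data$n) / (.data$K / .data$N)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_fold, y = -log10(.data$p_adj),
                                  colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "log2 (study fraction / population fraction)",
                  y = "-log10 adjusted p",
                  title = "Term over/under-representation") +
    ggplot2::theme_minimal()
}

#' @method tidy zf_boot_tree
#' @export
tidy.zf_boot_tree <- function(x, ...) {
  tr <- x$tree
  n_tip <- length(tr$tip.label)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  tibble(
    node = n_tip + seq_along(tr$node.label),
    support = sup
  )
}

#' @method glance zf_boot_tree
#' @export
glance.zf_boot_tree <- function(x, ...) {
  sup <- suppressWarnings(as.numeric(x$tree$node.label))
  tibble(
    n_tips = length(x$tree$tip.label),
    n_reps = x$n_reps,
    n_skipped = x$n_skipped,
    median_support = stats::median(sup, na.rm = TRUE)
  )
}

#' @method tidy zf_compressed
#' @export
tidy.zf_compressed <- function(x, ...) {
  x$nodes
}

#' @method glance zf_compressed
#' @export
glance.zf_compressed <- function(x, ...) {
  tibble(
    n_leaves = x$n_leaves,
    n_collapsed_nodes = nrow(x$nodes),
    n_mixed_branches = nrow(x$mixed_branches)
  )
}

#' Expression heatmap in clustered order
#'
#' Draws the log2(x + 1) matrix as tiles with rows and columns in the
#' hierarchical-clustering order of [hclust_order()].
#'
#' @param m Expression matrix (wide tibble with `gene`).
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(m) {
  ord <- hclust_order(m)
  v <- expr_values(m)
  long <- as_tibble(v, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "condition", values_to = "value") |>
    mutate(
      gene = factor(.data$gene, levels = rownames(v)[ord$row_order]),
      condition = factor(.data$condition, levels = colnames(v)[ord$col_order])
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$gene,
                                     fill = log2(.data$value + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2(x+1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
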