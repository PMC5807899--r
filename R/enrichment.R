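# Hypergeometric over/under-representation of annotation terms in a study
# set against a population, with per-direction multiple-testing correction.

#' Term over/under-representation by the hypergeometric test
#'
#' For each term annotated in the population, counts study genes carrying it
#' (`k` of `n`) against population carriers (`K` of `N`). The direction is
#' chosen by the sign of `k - n*K/N` (ties count as over-representation) and
#' the one-sided hypergeometric tail is reported: `P(X >= k)` for over,
#' `P(X <= k)` for under. P-values are corrected across terms within each
#' direction.
#'
#' @param study Character vector of study gene ids (subset of `population`).
#' @param population Character vector of population gene ids.
#' @param annot Tibble with `gene_id`, `term_id` and optionally `description`.
#' @param alpha If given, keep only terms with `p_adj < alpha`.
#' @param method Correction method, `"BH"` (default) or `"bonferroni"`.
#' @return A `zf_enrichment` tibble: `term_id`, `description`, `k`, `n`,
#'   `K`, `N`, `direction`, `p`, `p_adj`, sorted by `p_adj`.
#' @export
#' @examples
#' annot <- tibble::tibble(gene_id = paste0("g", 1:10),
#'                         term_id = rep(c("T1", "T2"), each = 5))
#' enrich(paste0("g", 1:3), paste0("g", 1:10), annot)
enrich <- function(study, population, annot, alpha = NULL,
                   method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (length(population) == 0) abort("`population` must be non-empty.")
  population <- unique(population)
  study <- unique(study)
  extra <- setdiff(study, population)
  if (length(extra) > 0) {
    abort(sprintf("Study gene(s) not in population: %s", paste(extra, collapse = ", ")))
  }
  if (!all(c("gene_id", "term_id") %in% names(annot))) {
    abort("`annot` needs columns gene_id and term_id.")
  }
  if (!"description" %in% names(annot)) annot$description <- NA_character_
  orphan_terms <- annot |>
    filter(!.data$gene_id %in% population) |>
    distinct(.data$term_id) |>
    anti_join(
      annot |> filter(.data$gene_id %in% population) |> distinct(.data$term_id),
      by = "term_id"
    )
  if (nrow(orphan_terms) > 0) {
    warn(sprintf("Skipped %d term(s) absent from the population.", nrow(orphan_terms)))
  }
  pop_annot <- filter(annot, .data$gene_id %in% population)
  N <- length(population)
  n <- length(study)
  res <- pop_annot |>
    group_by(.data$term_id) |>
    summarise(
      description = first(stats::na.omit(c(.data$description, NA_character_))),
      K = n_distinct(.data$gene_id),
      k = n_distinct(intersect(.data$gene_id, study)),
      .groups = "drop"
    ) |>
    mutate(
      n = n, N = N,
      direction = ifelse(.data$k >= n * .data$K / N, "over", "under"),
      p = ifelse(
        .data$direction == "over",
        phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE),
        phyper(.data$k, .data$K, N - .data$K, n, lower.tail = TRUE)
      )
    ) |>
    group_by(.data$direction) |>
    mutate(p_adj = p.adjust(.data$p, method = method)) |>
    ungroup() |>
    select("term_id", "description", "k", "n", "K", "N", "direction", "p", "p_adj") |>
    arrange(.data$p_adj, .data$term_id)
  if (!is.null(alpha)) res <- filter(res, .data$p_adj < alpha)
  attr(res, "correction") <- method
  class(res) <- c("zf_enrichment", class(res))
  res
}
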