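# Regulatory-network construction: thresholded co-expression edges,
# intersection with a regulatory map, and nodule-expression filtering.
#
# Edge sets are tibbles with columns regulator, target, sign
# ("up"/"down"/"none"), weight (Pearson r or NA) and provenance
# ("map", "coexpression", "intersected", "final").

edge_set <- function(regulator = character(), target = character(),
                     sign = character(), weight = numeric(),
                     provenance = character(), self_regulation = logical()) {
  tibble(regulator = regulator, target = target, sign = sign,
         weight = weight, provenance = provenance,
         self_regulation = self_regulation)
}

validate_edges <- function(edges, arg = "edges") {
  if (!all(c("regulator", "target") %in% names(edges))) {
    abort(sprintf("`%s` needs columns regulator and target.", arg))
  }
  edges
}

#' Co-expression edges above a Pearson correlation threshold
#'
#' Computes Pearson's r across conditions for each candidate (regulator,
#' target) pair and keeps pairs with `|r| > r_threshold`; positive r gives
#' sign "up", negative "down". Pairs involving a zero-variance gene have an
#' undefined correlation and yield no edge (warned).
#'
#' @param m Expression matrix (wide tibble with `gene`, >= 3 conditions).
#' @param candidate_pairs Tibble with `regulator`, `target` over genes of `m`.
#' @param r_threshold Absolute-correlation threshold (default 0.9, strict).
#' @return Edge tibble with `provenance = "coexpression"`.
#' @export
coexpression_edges <- function(m, candidate_pairs, r_threshold = 0.9) {
  v <- expr_values(m)
  if (ncol(v) < 3) abort("Need at least 3 conditions to correlate.")
  validate_edges(candidate_pairs, "candidate_pairs")
  missing <- setdiff(unique(c(candidate_pairs$regulator, candidate_pairs$target)),
                     rownames(v))
  if (length(missing) > 0) {
    abort(sprintf("Gene(s) absent from the expression matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  n_const <- 0L
  rows <- pmap(list(candidate_pairs$regulator, candidate_pairs$target),
               function(reg, tgt) {
    x <- v[reg, ]; y <- v[tgt, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      n_const <<- n_const + 1L
      return(NULL)
    }
    r <- cor(x, y)
    if (abs(r) <= r_threshold) return(NULL)
    tibble(regulator = reg, target = tgt,
           sign = if (r > 0) "up" else "down",
           weight = r, provenance = "coexpression",
           self_regulation = reg == tgt)
  })
  if (n_const > 0) warn(sprintf("%d pair(s) skipped: zero-variance gene.", n_const))
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- edge_set()
  out
}

#' Intersect a regulatory map with co-expression edges
#'
#' Keeps a map edge (regulator -> target) iff the co-expression set contains
#' the same gene pair; the map edge keeps its direction while the
#' co-expression edge matches orientation-free. The co-expression sign and
#' weight are attached; provenance becomes "intersected".
#'
#' @param map_edges Directed regulator -> target edges.
#' @param coexp_edges Output of [coexpression_edges()].
#' @return Edge tibble, `|result| <= min(|map|, |coexp|)`.
#' @export
intersect_networks <- function(map_edges, coexp_edges) {
  validate_edges(map_edges, "map_edges")
  validate_edges(coexp_edges, "coexp_edges")
  if (nrow(map_edges) == 0 || nrow(coexp_edges) == 0) return(edge_set())
  pair_key <- function(a, b) map2_chr_sorted(a, b)
  co <- coexp_edges |>
    mutate(.key = pair_key(.data$regulator, .data$target)) |>
    distinct(.data$.key, .keep_all = TRUE) |>
    select(".key", co_sign = "sign", co_weight = "weight")
  out <- map_edges |>
    mutate(.key = pair_key(.data$regulator, .data$target)) |>
    inner_join(co, by = ".key") |>
    transmute(
      regulator = .data$regulator, target = .data$target,
      sign = .data$co_sign, weight = .data$co_weight,
      provenance = "intersected",
      self_regulation = .data$regulator == .data$target
    )
  if (nrow(out) == 0) edge_set() else out
}

#' Filter the intersected network by nodule expression and de-duplicate
#'
#' Drops edges whose regulator or target is expressed (value >=
#' `expressed_threshold`) in none of the nodule-stage conditions — genes
#' unrelated to nodule development or function. Genes absent from the
#' expression matrix are treated as not expressed (warned). Duplicate
#' parallel edges collapse to one; self-loops are retained and flagged
#' `self_regulation`.
#'
#' @param net Edge tibble (typically from [intersect_networks()]).
#' @param nodule_expr Expression matrix over nodule-stage conditions.
#' @param expressed_threshold Expression call threshold (default 1).
#' @return Edge tibble with `provenance = "final"`.
#' @export
filter_final_network <- function(net, nodule_expr, expressed_threshold = 1) {
  validate_edges(net)
  if (nrow(net) == 0) return(edge_set())
  v <- expr_values(nodule_expr)
  genes <- unique(c(net$regulator, net$target))
  missing <- setdiff(genes, rownames(v))
  if (length(missing) > 0) {
    warn(sprintf("%d network gene(s) missing from nodule expression; treated as not expressed.",
                 length(missing)))
  }
  expressed <- setNames(rep(FALSE, length(genes)), genes)
  present <- intersect(genes, rownames(v))
  expressed[present] <- rowSums(v[present, , drop = FALSE] >= expressed_threshold) > 0
  net |>
    filter(expressed[.data$regulator] & expressed[.data$target]) |>
    distinct(.data$regulator, .data$target, .keep_all = TRUE) |>
    mutate(provenance = "final",
           self_regulation = .data$regulator == .data$target)
}

#' Write an edge set as a SIF file
#'
#' @param edges Edge tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path) {
  validate_edges(edges)
  rel <- if ("sign" %in% names(edges)) edges$sign else rep("regulates", nrow(edges))
  writeLines(paste(edges$regulator, rel, edges$target, sep = "\t"), path)
  invisible(path)
}

#' Write an edge set as GraphML
#'
#' @param edges Edge tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(edges, path) {
  validate_edges(edges)
  g <- igraph::graph_from_data_frame(
    edges[, intersect(c("regulator", "target", "sign", "weight"), names(edges))],
    directed = TRUE
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
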