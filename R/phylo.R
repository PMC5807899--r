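# Distance-based phylogeny of classified proteins: p-distances under
# pairwise gap deletion, neighbor-joining trees, column-bootstrap supports,
# and compression of label-uniform clades for subset-level display.

alignment_matrix <- function(alignment) {
  if (is.data.frame(alignment)) {
    validate_proteins(alignment |> mutate(sequence = gsub("-", "X", .data$sequence)))
    seqs <- setNames(alignment$sequence, alignment$id)
  } else if (is.character(alignment)) {
    seqs <- alignment
    if (is.null(names(seqs))) abort("Alignment sequences must be named.")
  } else {
    abort("`alignment` must be a tibble with id/sequence or a named character vector.")
  }
  if (length(seqs) < 2) abort("An alignment needs at least two sequences.")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) abort("Aligned sequences must have equal length.")
  do.call(rbind, strsplit(toupper(seqs), ""))
}

#' p-distance matrix from an alignment
#'
#' The p-distance between two sequences is the proportion of differing sites
#' among the columns where neither sequence has a gap (`-`): pairwise
#' deletion.
#'
#' @param alignment Tibble with `id` and `sequence` (equal lengths, `-` for
#'   gaps) or a named character vector.
#' @return A symmetric numeric matrix with zero diagonal and entries in
#'   \[0, 1\], taxa as dimnames.
#' @export
p_distance <- function(alignment) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  taxa <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        abort(sprintf("No comparable sites between '%s' and '%s'.", taxa[i], taxa[j]))
      }
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}); negative branch
#' lengths are clamped to zero with a warning. The returned tree is unrooted.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An [ape::phylo] object.
#' @export
nj_tree <- function(dm) {
  if (is.data.frame(dm)) dm <- as.matrix(dm)
  if (nrow(dm) < 3) abort("Neighbor joining needs at least 3 taxa.")
  tr <- ape::nj(as.dist(dm))
  if (any(tr$edge.length < 0)) {
    warn(sprintf("Clamped %d negative branch length(s) to zero.",
                 sum(tr$edge.length < 0)))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

resample_columns <- function(n_sites, seed, rep) {
  # per-replicate derived stream: order-independent across replicates
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((seed + 1000003L * rep) %% .Machine$integer.max)
  sample.int(n_sites, n_sites, replace = TRUE)
}

#' Neighbor-joining tree with column-bootstrap supports
#'
#' Builds the point-estimate NJ tree on p-distances, then resamples
#' alignment columns with replacement `n_reps` times; the support of each
#' internal edge is the percentage of replicate trees containing the same
#' bipartition. Replicates in which some pair has no comparable sites are
#' skipped and counted. Each replicate draws from a stream derived from
#' `(seed, replicate)`, so results do not depend on evaluation order.
#'
#' @param alignment As for [p_distance()].
#' @param n_reps Number of bootstrap replicates (>= 1; family surveys
#'   conventionally use 1000).
#' @param seed Master seed (integer).
#' @return A `zf_boot_tree` list: `tree` (phylo, supports as `node.label`
#'   percentages, root unlabelled), `n_reps`, `n_skipped`, `seed`.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L) {
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  m <- alignment_matrix(alignment)
  point <- nj_tree(p_distance_from_matrix(m))
  reps <- vector("list", n_reps)
  n_skipped <- 0L
  for (r in seq_len(n_reps)) {
    idx <- resample_columns(ncol(m), seed, r)
    dm <- tryCatch(p_distance_from_matrix(m[, idx, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(dm)) {
      n_skipped <- n_skipped + 1L
      next
    }
    reps[[r]] <- suppressWarnings(nj_tree(dm))
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  if (length(reps) == 0) abort("Every bootstrap replicate was degenerate.")
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / length(reps), 1)
  point$node.label <- as.character(support)
  point$node.label[1] <- ""  # root of the unrooted representation
  structure(
    list(tree = point, n_reps = as.integer(n_reps), n_skipped = n_skipped,
         seed = as.integer(seed)),
    class = "zf_boot_tree"
  )
}

p_distance_from_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) abort("pair with no comparable sites")
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

node_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

node_support <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip || is.null(tree$node.label)) return(NA_real_)
  suppressWarnings(as.numeric(tree$node.label[node - n_tip]))
}

#' Compress label-uniform clades of a phylogeny
#'
#' Collapses every maximal clade whose leaves all carry one subset label into
#' a single node annotated with the label, leaf count and minimum internal
#' bootstrap support inside the clade, then orders children deterministically
#' by (label, size) — the presentational "flip" that aggregates equal
#' subsets. Also reports internal branches joining two or more distinct
#' subset labels with support above `support_cutoff`.
#'
#' @param tree A phylo object (or `zf_boot_tree`), node labels read as
#'   bootstrap percentages when present.
#' @param labels Tibble with `id` and `label` covering every leaf.
#' @param support_cutoff Mixed branches are reported when their support
#'   exceeds this percentage (default 50).
#' @return A `zf_compressed` list: `newick` (compressed tree, collapsed
#'   nodes named `label|n=k`), `nodes` (tibble label/size/min_support), and
#'   `mixed_branches` (tibble branch support + labels joined).
#' @export
compress_by_subset <- function(tree, labels, support_cutoff = 50) {
  if (inherits(tree, "zf_boot_tree")) tree <- tree$tree
  if (!all(c("id", "label") %in% names(labels))) {
    abort("`labels` needs columns id and label.")
  }
  miss <- setdiff(tree$tip.label, labels$id)
  if (length(miss) > 0) {
    abort(sprintf("Unlabeled leaf/leaves: %s", paste(miss, collapse = ", ")))
  }
  lab <- setNames(labels$label, labels$id)
  # NJ trees are unrooted; midpoint-root so well-separated subsets appear as
  # clades of the rooted representation before collapsing
  if (!ape::is.rooted(tree) && !is.null(tree$edge.length)) {
    tree <- phangorn::midpoint(tree, node.labels = "support")
  }
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L

  nodes <- list()       # collapsed-node registry
  mixed <- list()

  # Returns for a node: list(labels = distinct labels below,
  #   render = newick fragment, size, min_support, is_collapsed)
  walk <- function(node, edge_len) {
    if (node <= n_tip) {
      l <- unname(lab[tree$tip.label[node]])
      return(list(labels = l, size = 1L, min_support = NA_real_, uniform = TRUE,
                  node = node))
    }
    kids <- node_children(tree, node)
    kid_edges <- map_dbl(kids, function(k) {
      e <- which(tree$edge[, 1] == node & tree$edge[, 2] == k)
      if (is.null(tree$edge.length)) 0 else tree$edge.length[e]
    })
    sub <- map2(kids, kid_edges, walk)
    labs <- unique(unlist(map(sub, "labels")))
    sup <- node_support(tree, node)
    kid_sup <- map_dbl(sub, function(s) s$min_support %||% NA_real_)
    min_sup <- suppressWarnings(min(c(sup, kid_sup), na.rm = TRUE))
    if (!is.finite(min_sup)) min_sup <- NA_real_
    list(labels = labs, size = sum(map_int(sub, function(s) as.integer(s$size))),
         min_support = min_sup, uniform = length(labs) == 1L,
         node = node, children = sub, kid_edges = kid_edges, support = sup)
  }

  render <- function(info, edge_len) {
    if (info$uniform) {
      id <- length(nodes) + 1L
      nodes[[id]] <<- tibble(label = info$labels, size = as.integer(info$size),
                             min_support = info$min_support)
      return(sprintf("%s|n=%d:%s", info$labels, info$size,
                     format(edge_len, trim = TRUE)))
    }
    # children of a non-uniform node: collect labels of descendant collapsed
    # nodes for the mixed-branch report
    sup <- info$support
    if (!is.na(sup) && sup > support_cutoff && length(info$labels) >= 2) {
      mixed[[length(mixed) + 1L]] <<- tibble(
        node = info$node, support = sup,
        labels = paste(sort(info$labels), collapse = ",")
      )
    }
    parts <- map2_chr2(info$children, info$kid_edges, render)
    keys <- map(info$children, function(s) {
      list(label = sort(s$labels)[1], size = s$size)
    })
    o <- order(map_chr(keys, "label"), map_int(keys, function(k) as.integer(k$size)))
    sprintf("(%s):%s", paste(parts[o], collapse = ","), format(edge_len, trim = TRUE))
  }

  info <- walk(root, 0)
  if (info$uniform) {
    # whole tree one label: a single collapsed node
    info_for_render <- info
    newick <- sprintf("%s;", sub(":0$", "", render(info_for_render, 0)))
  } else {
    newick <- sprintf("%s;", sub(":0$", "", render(info, 0)))
  }
  nodes_tbl <- bind_rows(nodes)
  mixed_tbl <- if (length(mixed) > 0) bind_rows(mixed) else
    tibble(node = integer(), support = numeric(), labels = character())
  structure(
    list(newick = newick, nodes = nodes_tbl, mixed_branches = mixed_tbl,
         n_leaves = n_tip, support_cutoff = support_cutoff),
    class = "zf_compressed"
  )
}

map2_chr2 <- function(x, y, f) unlist(map2(x, y, f))

#' Write a tree (or compressed tree) to Newick
#'
#' @param tree A phylo, `zf_boot_tree`, or `zf_compressed` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "zf_compressed")) {
    writeLines(tree$newick, path)
  } else {
    if (inherits(tree, "zf_boot_tree")) tree <- tree$tree
    ape::write.tree(tree, file = path)
  }
  invisible(path)
}
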