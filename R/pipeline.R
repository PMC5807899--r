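# Stage orchestration: each stage reads its inputs (TSV/FASTA), writes its
# outputs atomically into the run directory, and records a JSON manifest
# with the parameters, input checksums and row counts needed to re-derive
# every file. A thin command-line wrapper lives in inst/scripts/.

PIPELINE_STAGES <- c("simulate", "scan", "type", "classify", "phylo",
                     "enrich", "express", "qpcr", "network", "report")

#' Default run configuration
#'
#' @param out_dir Output directory of the run.
#' @param seed Master seed for the synthetic stages.
#' @return Nested list of stage parameters; override entries freely before
#'   passing to [run_stage()].
#' @export
default_config <- function(out_dir = "zf_run", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulate = list(n_per_subset = 10L, n_genes = 200L, noise_sigma = 0.2,
                    n_tfs = 12L, n_targets = 200L, overlap_fraction = 0.3,
                    n_taxa_per_subset = 4L, alignment_length = 120L,
                    n_pairs = 135L, n_singletons = 22L, n_not_dup = 25L),
    scan = list(c_gap_range = c(1L, 4L), spacer_range = c(6L, 25L),
                h_gap_range = c(1L, 8L), source = "auto"),
    classify = list(t2_policy = "t2"),
    phylo = list(n_reps = 100L),
    enrich = list(study_label = "Gm-1i-Q-SF", alpha = NULL, correction = "BH"),
    thresholds = list(expressed_threshold = 1, r_threshold = 0.9)
  )
}

#' Read a run configuration from YAML
#'
#' Keys present in the file override [default_config()] entries.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config not found: %s", path))
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_tsv(df, tmp)
  file.rename(tmp, path)
  path
}

stage_path <- function(config, file) file.path(config$out_dir, file)

read_stage_tsv <- function(config, file) {
  p <- stage_path(config, file)
  if (!file.exists(p)) {
    abort(sprintf("Missing input: %s", p), class = "zf_missing_input")
  }
  readr::read_tsv(p, show_col_types = FALSE)
}

manifest_entry <- function(path) {
  # paths recorded relative to the run directory so manifests are portable
  list(path = basename(path), md5 = unname(tools::md5sum(path)))
}

write_manifest <- function(config, stage, params, inputs, outputs) {
  man <- list(
    stage = stage,
    package = "zfsubsets",
    version = as.character(utils::packageVersion("zfsubsets")),
    parameters = params,
    inputs = map(inputs, manifest_entry),
    outputs = map(outputs, function(o) {
      c(manifest_entry(o$path), list(rows = o$rows))
    })
  )
  p <- stage_path(config, sprintf("manifest_%s.json", stage))
  tmp <- paste0(p, ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.rename(tmp, p)
  man
}

out_tsv <- function(config, df, file) {
  p <- write_tsv_atomic(df, stage_path(config, file))
  list(path = p, rows = nrow(df))
}

stage_simulate <- function(config) {
  p <- config$simulate
  recipe <- setNames(rep(p$n_per_subset, length(SUBSET_LABELS)), SUBSET_LABELS)
  prot <- gen_proteins(recipe, seed = config$seed)
  expr <- gen_expression(p$n_genes, noise_sigma = p$noise_sigma,
                         seed = config$seed + 1L)
  net <- gen_networks(p$n_tfs, p$n_targets, p$overlap_fraction,
                      seed = config$seed + 2L)
  aln <- gen_alignment(
    setNames(rep(p$n_taxa_per_subset, length(SUBSET_LABELS)), SUBSET_LABELS),
    length = p$alignment_length, seed = config$seed + 3L
  )
  dup <- gen_duplication_table(p$n_pairs, p$n_singletons, p$n_not_dup,
                               seed = config$seed + 4L)
  qp <- gen_qpcr_concordance(seed = config$seed + 5L)
  go <- gen_go_annotations(prot$truth$proteins, seed = config$seed + 6L)
  fasta <- stage_path(config, "proteins.fasta")
  write_fasta(prot$proteins, fasta)
  aln_fa <- stage_path(config, "alignment.fasta")
  write_fasta(mutate(aln$alignment, sequence = .data$sequence), aln_fa)
  outs <- list(
    out_tsv(config, prot$annotations, "annotations.tsv"),
    out_tsv(config, prot$truth$proteins, "truth_proteins.tsv"),
    out_tsv(config, prot$truth$domains, "truth_domains.tsv"),
    out_tsv(config, expr$expr, "expression.tsv"),
    out_tsv(config, expr$truth, "truth_expression.tsv"),
    out_tsv(config, net$map_edges, "map_edges.tsv"),
    out_tsv(config, net$expr, "net_expression.tsv"),
    out_tsv(config, net$truth_intersection, "truth_intersection.tsv"),
    out_tsv(config, aln$labels, "alignment_labels.tsv"),
    out_tsv(config, dup, "duplication.tsv"),
    out_tsv(config, qp$qpcr, "qpcr_folds.tsv"),
    out_tsv(config, qp$rnaseq, "rnaseq_folds.tsv"),
    out_tsv(config, go, "go_annotations.tsv"),
    list(path = fasta, rows = nrow(prot$proteins)),
    list(path = aln_fa, rows = nrow(aln$alignment))
  )
  write_manifest(config, "simulate", p, character(), outs)
}

# Synthetic gene -> term annotations: a handful of terms, one of them
# concentrated in a single subset so the enrichment stage has signal.
gen_go_annotations <- function(truth_proteins, seed = 1L) {
  restore <- local_seed(seed)
  on.exit(restore())
  terms <- sprintf("T%04d", 1:8)
  rows <- map(seq_len(nrow(truth_proteins)), function(i) {
    g <- truth_proteins$protein_id[i]
    lab <- truth_proteins$label[i]
    picked <- terms[runif(8) < 0.25]
    if (lab == "Gm-1i-Q-SF") picked <- union(picked, "T0001")
    if (length(picked) == 0) return(NULL)
    tibble(gene_id = g, term_id = picked,
           description = paste("synthetic term", picked))
  })
  bind_rows(rows)
}

stage_scan <- function(config) {
  proteins <- read_fasta(stage_path(config, "proteins.fasta"))
  params <- scan_params(config$scan$c_gap_range, config$scan$spacer_range,
                        config$scan$h_gap_range)
  annot_path <- stage_path(config, "annotations.tsv")
  use_annot <- config$scan$source %in% c("auto", "annotations") &&
    file.exists(annot_path)
  domains <- if (use_annot) {
    load_domain_annotations(readr::read_tsv(annot_path, show_col_types = FALSE),
                            proteins)
  } else {
    scan_domains(proteins, params)
  }
  outs <- list(out_tsv(config, domains, "domains.tsv"))
  write_manifest(config, "scan",
                 c(unclass(params), list(source = if (use_annot) "annotations" else "scan")),
                 stage_path(config, "proteins.fasta"), outs)
}

stage_type <- function(config) {
  domains <- read_stage_tsv(config, "domains.tsv")
  typed <- type_domains(domains)
  outs <- list(
    out_tsv(config, typed, "typed_domains.tsv"),
    out_tsv(config, type_counts(typed), "type_counts.tsv")
  )
  write_manifest(config, "type", list(), stage_path(config, "domains.tsv"), outs)
}

stage_classify <- function(config) {
  typed <- read_stage_tsv(config, "typed_domains.tsv")
  cls <- suppressWarnings(classify_proteins(typed, t2_policy = config$classify$t2_policy))
  summ <- summarize_subsets(cls, typed)
  outs <- list(
    out_tsv(config, as_tibble(cls), "classification.tsv"),
    out_tsv(config, summ$by_subset, "subset_counts.tsv"),
    out_tsv(config, summ$by_domain_number, "domain_number_counts.tsv"),
    out_tsv(config, summ$by_q_count, "q_domain_counts.tsv")
  )
  dup_path <- stage_path(config, "duplication.tsv")
  if (file.exists(dup_path)) {
    dup <- classify_duplication_status(
      readr::read_tsv(dup_path, show_col_types = FALSE))
    outs <- c(outs, list(
      out_tsv(config, dup, "duplication_status.tsv"),
      out_tsv(config, duplication_counts(dup), "duplication_counts.tsv")
    ))
  }
  write_manifest(config, "classify", config$classify,
                 stage_path(config, "typed_domains.tsv"), outs)
}

stage_phylo <- function(config) {
  aln <- read_fasta(stage_path(config, "alignment.fasta"))
  labels <- read_stage_tsv(config, "alignment_labels.tsv")
  boot <- bootstrap_support(aln, n_reps = config$phylo$n_reps,
                            seed = config$seed)
  comp <- compress_by_subset(boot, labels)
  tree_path <- stage_path(config, "tree.nwk")
  write_newick(boot, tree_path)
  comp_path <- stage_path(config, "compressed_tree.nwk")
  write_newick(comp, comp_path)
  outs <- list(
    list(path = tree_path, rows = length(boot$tree$tip.label)),
    list(path = comp_path, rows = nrow(comp$nodes)),
    out_tsv(config, comp$nodes, "collapsed_nodes.tsv"),
    out_tsv(config, comp$mixed_branches, "mixed_branches.tsv")
  )
  write_manifest(config, "phylo",
                 list(n_reps = config$phylo$n_reps, seed = config$seed),
                 stage_path(config, "alignment.fasta"), outs)
}

stage_enrich <- function(config) {
  truth <- read_stage_tsv(config, "truth_proteins.tsv")
  annot <- read_stage_tsv(config, "go_annotations.tsv")
  study <- truth$protein_id[truth$label == config$enrich$study_label]
  res <- enrich(study, truth$protein_id, annot,
                alpha = config$enrich$alpha,
                method = config$enrich$correction)
  outs <- list(out_tsv(config, as_tibble(res), "enrichment.tsv"))
  write_manifest(config, "enrich", config$enrich,
                 stage_path(config, "go_annotations.tsv"), outs)
}

stage_express <- function(config) {
  expr <- read_stage_tsv(config, "expression.tsv")
  pat <- classify_tissue_pattern(expr, config$thresholds$expressed_threshold)
  ord <- hclust_order(expr)
  outs <- list(
    out_tsv(config, pat, "expression_patterns.tsv"),
    out_tsv(config, tibble(position = seq_along(ord$row_order),
                           gene = expr$gene[ord$row_order]), "heatmap_row_order.tsv"),
    out_tsv(config, tibble(position = seq_along(ord$col_order),
                           condition = setdiff(names(expr), "gene")[ord$col_order]),
            "heatmap_col_order.tsv")
  )
  write_manifest(config, "express", config$thresholds,
                 stage_path(config, "expression.tsv"), outs)
}

stage_qpcr <- function(config) {
  qp <- read_stage_tsv(config, "qpcr_folds.tsv")
  rs <- read_stage_tsv(config, "rnaseq_folds.tsv")
  conc <- concordance(qp, rs)
  outs <- list(out_tsv(config, conc, "concordance.tsv"))
  write_manifest(config, "qpcr", list(),
                 c(stage_path(config, "qpcr_folds.tsv"),
                   stage_path(config, "rnaseq_folds.tsv")), outs)
}

stage_network <- function(config) {
  map_edges <- read_stage_tsv(config, "map_edges.tsv")
  expr <- read_stage_tsv(config, "net_expression.tsv")
  co <- coexpression_edges(expr, map_edges[, c("regulator", "target")],
                           r_threshold = config$thresholds$r_threshold)
  inter <- intersect_networks(map_edges, co)
  final <- filter_final_network(inter, expr,
                                config$thresholds$expressed_threshold)
  sif <- stage_path(config, "network.sif")
  gml <- stage_path(config, "network.graphml")
  write_sif(final, sif)
  write_graphml(final, gml)
  outs <- list(
    out_tsv(config, co, "coexpression_edges.tsv"),
    out_tsv(config, inter, "intersected_edges.tsv"),
    out_tsv(config, final, "final_network.tsv"),
    list(path = sif, rows = nrow(final)),
    list(path = gml, rows = nrow(final))
  )
  write_manifest(config, "network", config$thresholds,
                 c(stage_path(config, "map_edges.tsv"),
                   stage_path(config, "net_expression.tsv")), outs)
}

stage_report <- function(config) {
  manifests <- list.files(config$out_dir, pattern = "^manifest_.*\\.json$",
                          full.names = TRUE)
  manifests <- setdiff(manifests, stage_path(config, "manifest_report.json"))
  rep <- map(sort(manifests), jsonlite::read_json)
  p <- stage_path(config, "report.json")
  tmp <- paste0(p, ".tmp")
  jsonlite::write_json(rep, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.rename(tmp, p)
  write_manifest(config, "report", list(), character(),
                 list(list(path = p, rows = length(rep))))
}

#' Run one pipeline stage
#'
#' Stages: simulate, scan, type, classify, phylo, enrich, express, qpcr,
#' network, report. Outputs are written atomically under `config$out_dir`
#' together with a per-stage JSON manifest (parameters, input checksums, row
#' counts). Reruns with the same configuration and seed produce byte-identical
#' outputs.
#'
#' @param stage Stage name.
#' @param config Configuration list, see [default_config()] /
#'   [read_run_config()].
#' @return Invisibly, a list with `status` (0 ok, 2 missing input,
#'   3 validation failure) and `manifest`.
#' @export
run_stage <- function(stage, config = default_config()) {
  if (!stage %in% PIPELINE_STAGES) {
    abort(sprintf("Unknown stage '%s'. Stages: %s", stage,
                  paste(PIPELINE_STAGES, collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fn <- get(paste0("stage_", stage), mode = "function")
  res <- tryCatch(
    list(status = 0L, manifest = fn(config)),
    zf_missing_input = function(e) {
      warn(conditionMessage(e))
      list(status = 2L, manifest = NULL)
    },
    error = function(e) {
      warn(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)))
      list(status = 3L, manifest = NULL)
    }
  )
  invisible(res)
}

#' Run several pipeline stages in order
#'
#' @param config Configuration list.
#' @param stages Stages to run, in order (default: all).
#' @return Invisibly, named integer statuses; stops early on the first
#'   nonzero status.
#' @export
run_pipeline <- function(config = default_config(), stages = PIPELINE_STAGES) {
  statuses <- integer()
  for (s in stages) {
    inform(sprintf("[zfsubsets] stage %s", s))
    r <- run_stage(s, config)
    statuses[s] <- r$status
    if (r$status != 0L) break
  }
  invisible(statuses)
}
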