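# Synthetic-data generators with planted ground truth.
#
# Every generator is a pure function of (parameters, seed) and emits the same
# tables the pipeline consumes plus a truth record sufficient to score the
# corresponding stage exactly. Protein backgrounds exclude C and H by default
# so planted fingers are the only possible matches; `hostile = TRUE`
# reintroduces them at uniform frequency for robustness exercises (no
# exactness guarantee there).

BACKGROUND_ALPHABET <- setdiff(setdiff(VALID_RESIDUES, "X"), c("C", "H"))

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

bg <- function(n, alphabet) {
  if (n == 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# One finger as a list: seq, offsets of coordinating residues (1-based within
# the finger), family/subclass, and whether the second His is present.
make_finger <- function(type, alphabet) {
  switch(type,
    Q = {
      seq <- paste0("C", bg(2, alphabet), "C", bg(7, alphabet), "QALGG", "H",
                    bg(3, alphabet), "H")
      list(seq = seq, family = "Q", subclass = "none", len = nchar(seq))
    },
    M = {
      m <- sample(1:5, 1)
      hex <- strsplit("QALGG", "")[[1]]
      pos <- sample(5, m)
      for (p in pos) hex[p] <- sample(setdiff(alphabet, hex[p]), 1)
      seq <- paste0("C", bg(2, alphabet), "C", bg(7, alphabet),
                    paste(hex, collapse = ""), "H", bg(3, alphabet), "H")
      list(seq = seq, family = "M", subclass = paste0("M", m), len = nchar(seq))
    },
    Z1 = {
      s <- sample(13:20, 1); g <- sample(1:4, 1); h <- sample(1:8, 1)
      seq <- paste0("C", bg(g, alphabet), "C", bg(s, alphabet), "H",
                    bg(h, alphabet), "H")
      list(seq = seq, family = "Z", subclass = "Z1", len = nchar(seq))
    },
    Z2 = {
      s <- sample(6:11, 1); g <- sample(1:4, 1); h <- sample(1:8, 1)
      seq <- paste0("C", bg(g, alphabet), "C", bg(s, alphabet), "H",
                    bg(h, alphabet), "H")
      list(seq = seq, family = "Z", subclass = "Z2", len = nchar(seq))
    },
    Z = make_finger(sample(c("Z1", "Z2"), 1), alphabet),
    D = {
      seq <- paste0("C", bg(2, alphabet), "C", bg(7, alphabet), "QALGG", "H",
                    bg(3, alphabet))
      list(seq = seq, family = "D", subclass = "none", len = nchar(seq))
    },
    abort(sprintf("Unknown finger type '%s'.", type))
  )
}

subset_recipe <- function(label, alphabet) {
  pick <- function(...) sample(c(...), 1)
  switch(label,
    "Gm-1i-Q-SF" = list(types = "Q", tandem = FALSE),
    "Gm-1i-M-SF" = list(types = "M", tandem = FALSE),
    "Gm-1i-Z-SF" = list(types = "Z", tandem = FALSE),
    "Gm-1i-D-SF" = list(types = "D", tandem = FALSE),
    "Gm-t1-SF" = list(types = sample(c("M", "Z1", "Z2"), pick(2:5), replace = TRUE),
                      tandem = TRUE),
    "Gm-t2-SF" = list(types = sample(c("M", "Z1", "Z2"), 9, replace = TRUE),
                      tandem = TRUE),
    "Gm-2i-Q-SF" = list(types = c("Q", "Q"), tandem = FALSE),
    "Gm-2i-M-SF" = list(types = c("M", "M"), tandem = FALSE),
    "Gm-2i-Mix-SF" = list(types = sample(c("Q", "M", "Z", "D"), 2), tandem = FALSE),
    "Gm-3i-SF" = list(types = sample(c("Q", "M", "Z", "D"), 3, replace = TRUE),
                      tandem = FALSE),
    "Gm-4i-SF" = list(types = sample(c("Q", "M", "Z", "D"), 4, replace = TRUE),
                      tandem = FALSE),
    abort(sprintf("Unknown subset label '%s'.", label))
  )
}

#' Generate synthetic proteins with planted fingers per subset
#'
#' Builds proteins whose fingers follow the planted subset recipe exactly:
#' Q fingers are canonical, M fingers carry 1-5 sampled degradations of
#' QALGG, Z1/Z2 fingers sample long/short spacers, D fingers lack the second
#' histidine, tandem linkers are at most 11 residues and dispersed linkers at
#' least 12. Background residues exclude C and H so the planted fingers are
#' the only matches the scanner can find.
#'
#' @param recipe Named integer vector: proteins to generate per subset label.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param tandem_linker,dispersed_linker Inclusive linker-length ranges.
#' @param flank Inclusive range for the N/C-terminal background flanks.
#' @param hostile If `TRUE`, background residues include C and H.
#' @return A list: `proteins` (tibble id/sequence), `annotations`
#'   (protein_id/start/end finger windows, the SMART-like table), and `truth`
#'   with `proteins` (planted label per protein) and `domains` (planted
#'   positions, family and subclass per finger).
#' @export
gen_proteins <- function(recipe, seed = 1L,
                         tandem_linker = c(1L, 11L),
                         dispersed_linker = c(12L, 40L),
                         flank = c(2L, 10L),
                         hostile = FALSE) {
  if (is.null(names(recipe)) || any(!names(recipe) %in% SUBSET_LABELS)) {
    abort("`recipe` must be a named vector over the 11 subset labels.")
  }
  if (any(recipe < 0)) abort("Recipe counts must be >= 0.")
  restore <- local_seed(seed)
  on.exit(restore())
  alphabet <- if (hostile) setdiff(VALID_RESIDUES, "X") else BACKGROUND_ALPHABET
  prot <- list(); annot <- list(); truth_p <- list(); truth_d <- list()
  idx <- 0L
  for (label in names(recipe)) {
    for (i in seq_len(recipe[[label]])) {
      idx <- idx + 1L
      id <- sprintf("SYN%05d", idx)
      r <- subset_recipe(label, alphabet)
      linker_range <- if (r$tandem) tandem_linker else dispersed_linker
      fingers <- map(r$types, make_finger, alphabet = alphabet)
      pieces <- character(); starts <- integer(); ends <- integer()
      pos <- 1L
      lead <- sample(flank[1]:flank[2], 1)
      pieces <- c(pieces, bg(lead, alphabet)); pos <- pos + lead
      for (f in seq_along(fingers)) {
        if (f > 1) {
          lk <- sample(linker_range[1]:linker_range[2], 1)
          pieces <- c(pieces, bg(lk, alphabet)); pos <- pos + lk
        }
        starts <- c(starts, pos); ends <- c(ends, pos + fingers[[f]]$len - 1L)
        pieces <- c(pieces, fingers[[f]]$seq); pos <- pos + fingers[[f]]$len
      }
      pieces <- c(pieces, bg(sample(flank[1]:flank[2], 1), alphabet))
      prot[[idx]] <- tibble(id = id, sequence = paste(pieces, collapse = ""))
      annot[[idx]] <- tibble(protein_id = id, start = starts, end = ends)
      truth_p[[idx]] <- tibble(protein_id = id, label = label)
      truth_d[[idx]] <- tibble(
        protein_id = id, start = starts, end = ends,
        family = map_chr(fingers, "family"),
        subclass = map_chr(fingers, "subclass")
      )
    }
  }
  if (idx == 0L) abort("Empty recipe.")
  list(
    proteins = bind_rows(prot),
    annotations = bind_rows(annot),
    truth = list(proteins = bind_rows(truth_p), domains = bind_rows(truth_d))
  )
}

DEFAULT_TISSUES <- c("flower", "leaf", "nodule", "pod", "root", "root_hair",
                     "seed", "stem")

#' Generate an expression matrix with planted tissue patterns
#'
#' Each gene draws a pattern class from `pattern_mix`; expressed cells get a
#' base signal under multiplicative log-normal noise, silent cells are zero.
#' Symbiosis-specific genes are expressed only in symbiotic tissues,
#' tissue-specific genes in exactly one non-symbiotic tissue, broad genes in
#' a proper subset touching both compartments.
#'
#' @param n_genes Number of genes.
#' @param conditions Condition names (default: the eight standard tissues).
#' @param pattern_mix Named proportions over
#'   silent/constitutive/symbiosis_specific/tissue_specific/broad (sum 1).
#' @param noise_sigma Log-normal sigma (>= 0).
#' @param base Base expression level for expressed cells.
#' @param symbiotic_tissues Symbiosis-relative condition names.
#' @param seed Integer seed.
#' @return A list: `expr` (wide tibble gene x conditions) and `truth`
#'   (tibble gene/pattern).
#' @export
gen_expression <- function(n_genes, conditions = DEFAULT_TISSUES,
                           pattern_mix = c(silent = 0.2, constitutive = 0.2,
                                           symbiosis_specific = 0.2,
                                           tissue_specific = 0.2, broad = 0.2),
                           noise_sigma = 0.2, base = 100,
                           symbiotic_tissues = c("nodule", "root", "root_hair"),
                           seed = 1L) {
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (abs(sum(pattern_mix) - 1) > 1e-8) abort("`pattern_mix` must sum to 1.")
  restore <- local_seed(seed)
  on.exit(restore())
  symb <- intersect(symbiotic_tissues, conditions)
  nonsymb <- setdiff(conditions, symb)
  counts <- floor(pattern_mix * n_genes)
  rem <- n_genes - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  patterns <- rep(names(counts), counts)
  nc <- length(conditions)
  v <- matrix(0, n_genes, nc, dimnames = list(sprintf("G%05d", seq_len(n_genes)),
                                              conditions))
  for (i in seq_len(n_genes)) {
    on_set <- switch(patterns[i],
      silent = character(),
      constitutive = conditions,
      symbiosis_specific = sample(symb, sample(length(symb), 1)),
      tissue_specific = sample(nonsymb, 1),
      broad = {
        s <- sample(2:(nc - 1), 1)
        ns <- sample(nonsymb, 1)
        sb <- sample(symb, 1)
        extra <- if (s > 2) sample(setdiff(conditions, c(ns, sb)), s - 2)
                 else character()
        c(ns, sb, extra)
      }
    )
    if (length(on_set) > 0) {
      v[i, on_set] <- base * exp(rnorm(length(on_set), 0, noise_sigma))
    }
  }
  list(
    expr = bind_cols(tibble(gene = rownames(v)), as_tibble(v)),
    truth = tibble(gene = rownames(v), pattern = patterns)
  )
}

#' Generate a subset-structured protein alignment
#'
#' Each subset gets an independent random ancestor; taxa within a subset are
#' i.i.d. mutants of that ancestor (per-site substitution probability
#' `rate`), so within-subset p-distances are small against between-subset
#' distances in expectation.
#'
#' @param n_per_subset Named integer vector: taxa per subset label.
#' @param length Alignment length (>= 1).
#' @param rate Per-site substitution probability within a subset.
#' @param seed Integer seed.
#' @return A list: `alignment` (tibble id/sequence) and `labels`
#'   (tibble id/label).
#' @export
gen_alignment <- function(n_per_subset, length = 200L, rate = 0.05, seed = 1L) {
  if (length < 1) abort("`length` must be >= 1.")
  restore <- local_seed(seed)
  on.exit(restore())
  aa <- setdiff(VALID_RESIDUES, "X")
  rows <- list(); labs <- list()
  for (label in names(n_per_subset)) {
    anc <- sample(aa, length, replace = TRUE)
    for (i in seq_len(n_per_subset[[label]])) {
      s <- anc
      mut <- runif(length) < rate
      s[mut] <- map_chr(s[mut], function(a) sample(setdiff(aa, a), 1))
      id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", label), i)
      rows[[id]] <- tibble(id = id, sequence = paste(s, collapse = ""))
      labs[[id]] <- tibble(id = id, label = label)
    }
  }
  list(alignment = bind_rows(rows), labels = bind_rows(labs))
}

#' Generate a regulatory map plus expression with a planted intersection
#'
#' Builds a directed regulator -> target map (each target regulated by one
#' transcription factor), then plants co-expression for a fraction of the
#' map edges: planted targets are near-linear functions of their regulator
#' profile (|r| > 0.95 by construction) while non-planted targets are
#' rejection-sampled to |r| <= 0.8, so thresholding at |r| > 0.9 recovers
#' exactly the planted intersection.
#'
#' @param n_tfs,n_targets Numbers of regulators and targets
#'   (`n_targets` map edges, one per target).
#' @param overlap_fraction Fraction of map edges planted as co-expressed
#'   (0..1).
#' @param n_conditions Number of expression conditions (>= 3).
#' @param seed Integer seed.
#' @return A list: `map_edges`, `expr` (wide tibble over TFs and targets),
#'   `truth_intersection` (tibble regulator/target of planted edges).
#' @export
gen_networks <- function(n_tfs = 12L, n_targets = 200L, overlap_fraction = 0.3,
                         n_conditions = 12L, seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    abort("`overlap_fraction` must be in [0, 1].")
  }
  restore <- local_seed(seed)
  on.exit(restore())
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  targets <- sprintf("TG%04d", seq_len(n_targets))
  map_edges <- tibble(
    regulator = sample(tfs, n_targets, replace = TRUE),
    target = targets,
    sign = "none", weight = NA_real_, provenance = "map",
    self_regulation = FALSE
  )
  n_planted <- round(overlap_fraction * n_targets)
  planted <- sort(sample(n_targets, n_planted))
  prof <- matrix(NA_real_, n_tfs + n_targets, n_conditions,
                 dimnames = list(c(tfs, targets), NULL))
  for (tf in tfs) prof[tf, ] <- exp(rnorm(n_conditions, log(50), 1))
  for (i in seq_len(n_targets)) {
    reg <- map_edges$regulator[i]
    tg <- map_edges$target[i]
    if (i %in% planted) {
      prof[tg, ] <- runif(1, 0.5, 2) * prof[reg, ] +
        abs(rnorm(n_conditions, 0, 1e-3))
    } else {
      repeat {
        cand <- exp(rnorm(n_conditions, log(50), 1))
        if (abs(cor(cand, prof[reg, ])) <= 0.8) break
      }
      prof[tg, ] <- cand
    }
  }
  colnames(prof) <- sprintf("cond%02d", seq_len(n_conditions))
  list(
    map_edges = map_edges,
    expr = bind_cols(tibble(gene = rownames(prof)), as_tibble(prof)),
    truth_intersection = map_edges[planted, c("regulator", "target")]
  )
}

#' Generate a duplication-status gene table
#'
#' Emits a gene table with symmetric whole-genome-duplication partners,
#' retained singletons inside duplication blocks, and non-duplicated genes,
#' with synonymous-substitution (Ks) values for paired genes.
#'
#' @param n_pairs,n_singletons,n_not_dup Gene counts per category.
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `partner_id`, `ks`, `block_id`, `chromosome`,
#'   `start`, `end` (`2*n_pairs + n_singletons + n_not_dup` rows).
#' @export
gen_duplication_table <- function(n_pairs = 135L, n_singletons = 22L,
                                  n_not_dup = 25L, seed = 1L) {
  restore <- local_seed(seed)
  on.exit(restore())
  n_genes <- 2L * n_pairs + n_singletons + n_not_dup
  ids <- sprintf("Gene%04d", seq_len(n_genes))
  partner <- rep(NA_character_, n_genes)
  ks <- rep(NA_real_, n_genes)
  block <- rep(NA_character_, n_genes)
  for (p in seq_len(n_pairs)) {
    a <- 2L * p - 1L; b <- 2L * p
    partner[a] <- ids[b]; partner[b] <- ids[a]
    ks[c(a, b)] <- round(runif(1, 0.05, 0.3), 4)
    block[c(a, b)] <- sprintf("B%03d", p)
  }
  if (n_singletons > 0) {
    s <- 2L * n_pairs + seq_len(n_singletons)
    block[s] <- sprintf("B%03d", n_pairs + seq_len(n_singletons))
  }
  tibble(
    gene_id = ids, partner_id = partner, ks = ks, block_id = block,
    chromosome = sample(sprintf("Chr%02d", 1:20), n_genes, replace = TRUE),
    start = sample.int(5e7, n_genes),
    end = NA_integer_
  ) |>
    mutate(end = .data$start + sample.int(5000, n_genes) + 200L)
}

#' Generate matched qPCR / RNA-seq fold changes with planted disagreements
#'
#' Fold-change directions agree between platforms except for a planted set
#' of discordant data points whose qPCR direction is flipped.
#'
#' @param n_genes,n_timepoints Grid dimensions.
#' @param n_discordant Number of planted discordant points.
#' @param seed Integer seed.
#' @return A list: `qpcr`, `rnaseq` (tibbles gene/timepoint/fold) and
#'   `truth` (tibble with `discordant` flag per point).
#' @export
gen_qpcr_concordance <- function(n_genes = 12L, n_timepoints = 13L,
                                 n_discordant = 23L, seed = 1L) {
  n <- n_genes * n_timepoints
  if (n_discordant < 0 || n_discordant > n) {
    abort("`n_discordant` must be between 0 and the number of data points.")
  }
  restore <- local_seed(seed)
  on.exit(restore())
  grid <- tidyr::expand_grid(
    gene = sprintf("G%03d", seq_len(n_genes)),
    timepoint = sprintf("T%02d", seq_len(n_timepoints))
  )
  l2 <- rnorm(n, 0, 2)
  l2[abs(l2) < 0.2] <- 0.2 * sign(l2[abs(l2) < 0.2] + 1e-9)  # keep directions clear
  flip <- rep(1, n)
  disc <- sample(n, n_discordant)
  flip[disc] <- -1
  list(
    rnaseq = mutate(grid, fold = 2^l2),
    qpcr = mutate(grid, fold = 2^(flip * l2 * runif(n, 0.7, 1.3))),
    truth = mutate(grid, discordant = seq_len(n) %in% disc)
  )
}
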