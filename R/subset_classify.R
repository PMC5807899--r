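# Protein-level arrangement calls, 11-way subset assignment, and
# duplication-status accounting.
#
# Adjacent fingers linked by < 12 residues form a tandem array; separations
# of > 11 residues make fingers dispersed. Gaps are measured from the end of
# the previous domain to the start of the next, exclusive, on the annotated
# window bounds when available and otherwise on the c1..h2 span.

SUBSET_LABELS <- c(
  "Gm-t1-SF", "Gm-t2-SF",
  "Gm-1i-Q-SF", "Gm-1i-M-SF", "Gm-1i-Z-SF", "Gm-1i-D-SF",
  "Gm-2i-Q-SF", "Gm-2i-M-SF", "Gm-2i-Mix-SF",
  "Gm-3i-SF", "Gm-4i-SF"
)

longest_run_of <- function(linked) {
  # linked: logical vector over adjacent pairs; run length in domains
  if (length(linked) == 0) return(1L)
  best <- cur <- 0L
  for (x in linked) {
    cur <- if (x) cur + 1L else 0L
    best <- max(best, cur)
  }
  best + 1L
}

#' Call the finger arrangement of each protein
#'
#' A consecutive pair of fingers is tandem-linked iff the gap between them is
#' at most 11 residues. A protein is `tandem` when all adjacent gaps are
#' <= 11, `dispersed` when all are >= 12, `mixed` otherwise, and `single`
#' with one finger.
#'
#' @param typed Typed domains from [type_domains()] (any number of proteins).
#' @return One row per protein: `protein_id`, `n_domains`, `arrangement`,
#'   `longest_tandem_run`, plus list-columns `gaps` (adjacent gaps) and
#'   `families` (ordered finger families).
#' @export
call_arrangements <- function(typed) {
  if (nrow(typed) == 0) {
    abort("`typed` must contain at least one domain.")
  }
  typed |>
    group_by(.data$protein_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      n_domains = n(),
      gaps = list({
        if (n() > 1 && any(.data$start[-1] <= .data$end[-n()])) {
          abort(sprintf("Overlapping domains in protein '%s'.", .data$protein_id[1]))
        }
        as.integer(.data$start[-1] - .data$end[-n()] - 1L)
      }),
      families = list(.data$family),
      .groups = "drop"
    ) |>
    mutate(
      longest_tandem_run = map_int(.data$gaps, function(g) longest_run_of(g <= 11L)),
      arrangement = map_chr(.data$gaps, function(g) {
        if (length(g) == 0) "single"
        else if (all(g <= 11L)) "tandem"
        else if (all(g >= 12L)) "dispersed"
        else "mixed"
      })
    ) |>
    select("protein_id", "n_domains", "arrangement", "longest_tandem_run",
           "gaps", "families")
}

assign_one_subset <- function(arrangement, n_domains, run, families, t2_policy) {
  lab <- function(label, reason = NA_character_, note = NA_character_) {
    list(label = label, reason = reason, note = note)
  }
  tandem_label <- function(run, note = NA_character_) {
    if (run <= 5L) return(lab("Gm-t1-SF", note = note))
    if (run <= 8L) {
      if (t2_policy == "unclassified") {
        return(lab("unclassified", reason = sprintf("tandem run of %d fingers", run)))
      }
      extra <- sprintf("tandem run of %d fingers assigned to the long-array subset", run)
      return(lab("Gm-t2-SF", note = if (is.na(note)) extra else paste(note, extra, sep = "; ")))
    }
    lab("Gm-t2-SF", note = note)
  }
  switch(arrangement,
    single = lab(sprintf("Gm-1i-%s-SF", families[1])),
    tandem = tandem_label(run),
    dispersed = {
      if (n_domains == 2L) {
        fams <- unique(families)
        if (length(fams) == 2L) lab("Gm-2i-Mix-SF")
        else if (fams == "Q") lab("Gm-2i-Q-SF")
        else if (fams == "M") lab("Gm-2i-M-SF")
        else lab("Gm-2i-Mix-SF",
                 note = sprintf("two %s-type fingers mapped to the mixed subset", fams))
      } else if (n_domains == 3L) lab("Gm-3i-SF")
      else if (n_domains == 4L) lab("Gm-4i-SF")
      else lab("unclassified",
               reason = sprintf("%d dispersed fingers exceed the four-finger scheme", n_domains))
    },
    mixed = {
      if (run >= 2L) tandem_label(run, note = "mixed arrangement; classified by longest tandem run")
      else lab("unclassified", reason = "mixed arrangement without a tandem run")
    }
  )
}

#' Assign the 11-way subset label to each protein
#'
#' Implements the arrangement/number/type classification: tandem arrays of
#' 2-5 fingers go to Gm-t1-SF and longer arrays to Gm-t2-SF; single fingers
#' to Gm-1i-Q/M/Z/D-SF by family (M1..M5 collapse to M, Z1/Z2 to Z);
#' dispersed pairs to Gm-2i-Q-SF, Gm-2i-M-SF or Gm-2i-Mix-SF; dispersed
#' triples and quadruples to Gm-3i-SF and Gm-4i-SF. Proteins with both a
#' tandem run and distant fingers are classified by their longest tandem run
#' and flagged in `note`; five or more dispersed fingers are `unclassified`
#' with a reason.
#'
#' @param typed Typed domains from [type_domains()].
#' @param t2_policy `"t2"` (default) sends tandem runs of 6-8 fingers to
#'   Gm-t2-SF with a note; `"unclassified"` leaves them unclassified.
#' @return A `zf_classification` tibble: `protein_id`, `n_domains`,
#'   `arrangement`, `longest_tandem_run`, `label`, `reason`, `note`.
#' @export
classify_proteins <- function(typed, t2_policy = c("t2", "unclassified")) {
  t2_policy <- match.arg(t2_policy)
  calls <- call_arrangements(typed)
  assigned <- pmap(
    list(calls$arrangement, calls$n_domains, calls$longest_tandem_run, calls$families),
    assign_one_subset, t2_policy = t2_policy
  )
  out <- calls |>
    mutate(
      label = map_chr(assigned, "label"),
      reason = map_chr(assigned, "reason"),
      note = map_chr(assigned, "note")
    ) |>
    select(-"gaps", -"families")
  n_long <- sum(out$longest_tandem_run >= 6 & out$longest_tandem_run <= 8 &
                  out$label == "Gm-t2-SF")
  if (n_long > 0) {
    warn(sprintf("%d protein(s) with tandem runs of 6-8 fingers assigned to Gm-t2-SF.", n_long))
  }
  class(out) <- c("zf_classification", class(out))
  out
}

#' Summarise a subset classification
#'
#' Mirrors the family-survey summary panels: protein counts per subset,
#' per finger number, and per number of Q-type fingers.
#'
#' @param classification A [classify_proteins()] result.
#' @param typed The typed domains it was computed from.
#' @return A `zf_subset_summary` list of tibbles: `by_subset`,
#'   `by_domain_number`, `by_q_count`.
#' @export
summarize_subsets <- function(classification, typed) {
  by_subset <- classification |>
    count(label = factor(.data$label, levels = c(SUBSET_LABELS, "unclassified")),
          name = "n", .drop = FALSE) |>
    mutate(label = as.character(.data$label))
  by_domain_number <- count(classification, .data$n_domains, name = "n")
  q_per_protein <- typed |>
    group_by(.data$protein_id) |>
    summarise(n_q = sum(.data$family == "Q"), .groups = "drop")
  by_q_count <- count(q_per_protein, .data$n_q, name = "n")
  structure(
    list(by_subset = by_subset, by_domain_number = by_domain_number,
         by_q_count = by_q_count, n_proteins = nrow(classification)),
    class = "zf_subset_summary"
  )
}

#' Account duplication status of genes
#'
#' Splits genes into whole-genome-duplication pairs retained on both sides,
#' singletons whose duplicate was lost or pseudogenised, and genes outside
#' any duplication block. Partner claims must be symmetric.
#'
#' @param records Tibble with `gene_id`, `partner_id` (NA when absent) and
#'   `block_id` (NA when the gene sits in no duplication block); an optional
#'   `ks` column is carried through.
#' @return The input with a `status` column added
#'   (`pair_retained` / `singleton_retained` / `not_duplicated`).
#' @export
classify_duplication_status <- function(records) {
  if (nrow(records) == 0) {
    return(mutate(records, status = character()))
  }
  if (!all(c("gene_id", "partner_id", "block_id") %in% names(records))) {
    abort("`records` needs columns gene_id, partner_id, block_id.")
  }
  partner_of <- setNames(records$partner_id, records$gene_id)
  has_partner <- !is.na(records$partner_id)
  claimed <- records$gene_id[has_partner]
  back <- partner_of[records$partner_id[has_partner]]
  bad <- claimed[is.na(back) | back != claimed]
  if (length(bad) > 0) {
    abort(sprintf("Asymmetric partner claim(s) for: %s", paste(bad, collapse = ", ")))
  }
  mutate(records, status = case_when(
    !is.na(.data$partner_id) ~ "pair_retained",
    !is.na(.data$block_id) ~ "singleton_retained",
    TRUE ~ "not_duplicated"
  ))
}

#' Count duplication pairs, singletons and non-duplicated genes
#'
#' @param records Output of [classify_duplication_status()].
#' @return Tibble with one row: `pairs` (unordered pairs counted once),
#'   `singletons`, `not_duplicated`, `genes`.
#' @export
duplication_counts <- function(records) {
  paired <- filter(records, .data$status == "pair_retained")
  n_pairs <- if (nrow(paired) == 0) 0L else {
    keys <- map2_chr_sorted(paired$gene_id, paired$partner_id)
    length(unique(keys))
  }
  tibble(
    pairs = n_pairs,
    singletons = sum(records$status == "singleton_retained"),
    not_duplicated = sum(records$status == "not_duplicated"),
    genes = nrow(records)
  )
}

map2_chr_sorted <- function(a, b) {
  map2(a, b, function(x, y) paste(sort(c(x, y)), collapse = "|")) |> unlist()
}

#' Build a chromosome link table for duplicated gene pairs
#'
#' One row per retained pair with the genomic coordinates of both genes,
#' suitable for plotting with external circular-layout tools.
#'
#' @param records Output of [classify_duplication_status()].
#' @param genes Tibble with `id`, `chromosome`, `start`, `end`.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `partner_id`, `partner_chrom`, `partner_start`, `partner_end`.
#' @export
link_table <- function(records, genes) {
  paired <- filter(records, .data$status == "pair_retained")
  if (nrow(paired) == 0) {
    return(tibble(gene_id = character(), chrom = character(), start = integer(),
                  end = integer(), partner_id = character(),
                  partner_chrom = character(), partner_start = integer(),
                  partner_end = integer()))
  }
  paired <- paired[!duplicated(map2_chr_sorted(paired$gene_id, paired$partner_id)), ]
  g <- select(genes, gene_id = "id", chrom = "chromosome", "start", "end")
  paired |>
    select("gene_id", "partner_id") |>
    left_join(g, by = "gene_id") |>
    left_join(
      rename(g, partner_id = "gene_id", partner_chrom = "chrom",
             partner_start = "start", partner_end = "end"),
      by = "partner_id"
    ) |>
    select("gene_id", "chrom", "start", "end", "partner_id",
           "partner_chrom", "partner_start", "partner_end")
}
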