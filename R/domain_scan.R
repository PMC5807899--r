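# Ab initio detection of C2H2 zinc-finger domains and ingestion of
# pre-computed (SMART-export-like) domain annotation tables.
#
# A finger is a quadruple of coordinating residues C..C..H..H whose spacings
# fall inside configurable windows around the consensus
# X2-C-X(1~4)-C-X12-H-X(1~8)-H. The six residues ending at the first
# histidine (the "hexamer") carry the plant-specific QALGGH motif used for
# typing. All coordinates are 1-based inclusive.

#' Scanning parameters for C2H2 zinc-finger detection
#'
#' Inclusive bounds on the three spacings of a finger: residues strictly
#' between the two cysteines (`c_gap`), between the second cysteine and the
#' first histidine (`spacer`), and between the two histidines (`h_gap`).
#' The canonical plant finger has `c_gap = 2`, `spacer = 12`, `h_gap = 3`;
#' the defaults are wide enough to admit the long-spacer (Z1) and
#' short-spacer (Z2) variants.
#'
#' @param c_gap_range,spacer_range,h_gap_range Integer length-2 vectors,
#'   inclusive lower/upper bounds (all lower bounds >= 1).
#' @return A list with class `zf_scan_params`.
#' @export
scan_params <- function(c_gap_range = c(1L, 4L),
                        spacer_range = c(6L, 25L),
                        h_gap_range = c(1L, 8L)) {
  for (r in list(c_gap_range, spacer_range, h_gap_range)) {
    if (length(r) != 2 || r[1] < 1 || r[2] < r[1]) {
      abort("Each range must be c(lower, upper) with 1 <= lower <= upper.")
    }
  }
  structure(
    list(c_gap_range = as.integer(c_gap_range),
         spacer_range = as.integer(spacer_range),
         h_gap_range = as.integer(h_gap_range)),
    class = "zf_scan_params"
  )
}

in_range <- function(x, r) x >= r[1] & x <= r[2]

# Candidate ranking: spacer closest to the canonical 12 first (ties to the
# smaller spacer), then smaller h_gap, then smaller c_gap.
pick_best_candidate <- function(cand) {
  o <- order(abs(cand$spacer - 12L), cand$spacer, cand$h_gap, cand$c_gap)
  cand[o[1], , drop = FALSE]
}

scan_one_sequence <- function(seq, params) {
  res <- strsplit(seq, "")[[1]]
  cpos <- which(res == "C")
  hpos <- which(res == "H")
  out <- list()
  cursor <- 1L
  repeat {
    cs <- cpos[cpos >= cursor]
    if (length(cs) == 0) break
    hit <- NULL
    for (c1 in cs) {
      c2s <- cpos[in_range(cpos - c1 - 1L, params$c_gap_range)]
      if (length(c2s) == 0) next
      cand <- list()
      for (c2 in c2s) {
        h1s <- hpos[in_range(hpos - c2 - 1L, params$spacer_range) & hpos >= 6L]
        for (h1 in h1s) {
          h2s <- hpos[in_range(hpos - h1 - 1L, params$h_gap_range)]
          if (length(h2s) == 0) next
          cand[[length(cand) + 1L]] <- data.frame(
            c1 = c1, c2 = c2, h1 = h1, h2 = h2s,
            c_gap = c2 - c1 - 1L, spacer = h1 - c2 - 1L, h_gap = h2s - h1 - 1L
          )
        }
      }
      if (length(cand) > 0) {
        hit <- pick_best_candidate(do.call(rbind, cand))
        break
      }
    }
    if (is.null(hit)) break
    hit$hexamer <- substr(seq, hit$h1 - 5L, hit$h1)
    out[[length(out) + 1L]] <- hit
    cursor <- hit$h2 + 1L
  }
  if (length(out) == 0) {
    return(tibble(
      start = integer(), end = integer(), c1 = integer(), c2 = integer(),
      h1 = integer(), h2 = integer(), c_gap = integer(), spacer = integer(),
      h_gap = integer(), hexamer = character()
    ))
  }
  d <- as_tibble(do.call(rbind, out))
  d$start <- d$c1
  d$end <- d$h2
  d[, c("start", "end", "c1", "c2", "h1", "h2", "c_gap", "spacer", "h_gap", "hexamer")]
}

#' Scan proteins for C2H2 zinc-finger domains
#'
#' Greedy left-to-right detection of non-overlapping two-histidine fingers.
#' At each step the leftmost cysteine admitting any valid (C, C, H, H)
#' quadruple is taken as the domain start; among its candidates the one with
#' spacer closest to 12 wins (ties broken toward the smaller spacer, then
#' smaller `h_gap`, then smaller `c_gap`), and scanning resumes after the
#' accepted second histidine. Fingers lacking the second histidine (D-type
#' candidates) are not called ab initio; ingest them with
#' [load_domain_annotations()].
#'
#' @param proteins Tibble with `id` and `sequence`.
#' @param params A [scan_params()] object.
#' @return Tibble of domains: `protein_id`, `start`, `end`, the four
#'   coordinating-residue positions `c1`,`c2`,`h1`,`h2`, the spacings
#'   `c_gap`,`spacer`,`h_gap`, the six-residue `hexamer` ending at `h1`,
#'   and `provenance = "scanned"`.
#' @export
#' @examples
#' scan_domains(tibble::tibble(id = "toy", sequence = "MACGACAAAAAAAQALGGHAAAH"))
scan_domains <- function(proteins, params = scan_params()) {
  validate_proteins(proteins)
  if (!inherits(params, "zf_scan_params")) abort("`params` must come from scan_params().")
  res <- map2(proteins$id, proteins$sequence, function(id, seq) {
    d <- scan_one_sequence(seq, params)
    if (nrow(d) > 0) d <- mutate(d, protein_id = id, .before = 1)
    d
  })
  res <- bind_rows(res)
  if (nrow(res) == 0) {
    res <- tibble(
      protein_id = character(), start = integer(), end = integer(),
      c1 = integer(), c2 = integer(), h1 = integer(), h2 = integer(),
      c_gap = integer(), spacer = integer(), h_gap = integer(),
      hexamer = character()
    )
  }
  mutate(res, provenance = "scanned")
}

#' Ingest a pre-computed domain annotation table
#'
#' Reads domain windows (e.g. exported from a SMART search) and locates the
#' coordinating residues inside each window: the first two cysteines, the
#' first histidine after the second cysteine, and the last histidine of the
#' window as the second coordinating histidine. Windows containing a single
#' histidine yield domains with `h2 = NA` — the D-type candidates.
#'
#' @param annotations A tibble with columns `protein_id`, `start`, `end`
#'   (1-based inclusive window bounds), or a path to such a TSV.
#' @param proteins Tibble with `id` and `sequence` covering every annotated id.
#' @return Tibble with the same columns as [scan_domains()],
#'   `provenance = "annotated"`. Rows whose window lacks two cysteines and one
#'   histidine (or is malformed) are rejected with a warning reporting the count.
#' @export
load_domain_annotations <- function(annotations, proteins) {
  validate_proteins(proteins)
  if (is.character(annotations) && length(annotations) == 1) {
    annotations <- readr::read_tsv(annotations, show_col_types = FALSE)
  }
  need <- c("protein_id", "start", "end")
  if (!all(need %in% names(annotations))) {
    abort("`annotations` needs columns protein_id, start, end.")
  }
  unknown <- setdiff(annotations$protein_id, proteins$id)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown protein id(s) in annotations: %s",
                  paste(unique(unknown), collapse = ", ")))
  }
  seqs <- setNames(proteins$sequence, proteins$id)
  n_rejected <- 0L
  rows <- pmap(annotations[need], function(protein_id, start, end) {
    seq <- seqs[[protein_id]]
    if (is.na(start) || is.na(end) || end < start || start < 1 || end > nchar(seq)) {
      n_rejected <<- n_rejected + 1L
      return(NULL)
    }
    win <- strsplit(substr(seq, start, end), "")[[1]]
    cpos <- which(win == "C") + start - 1L
    hpos <- which(win == "H") + start - 1L
    if (length(cpos) < 2 || length(hpos) < 1) {
      n_rejected <<- n_rejected + 1L
      return(NULL)
    }
    c1 <- cpos[1]; c2 <- cpos[2]
    h1s <- hpos[hpos > c2]
    if (length(h1s) == 0) {
      n_rejected <<- n_rejected + 1L
      return(NULL)
    }
    h1 <- h1s[1]
    h2 <- if (length(h1s) >= 2) h1s[length(h1s)] else NA_integer_
    tibble(
      protein_id = protein_id, start = as.integer(start), end = as.integer(end),
      c1 = c1, c2 = c2, h1 = h1, h2 = h2,
      c_gap = c2 - c1 - 1L, spacer = h1 - c2 - 1L,
      h_gap = if (is.na(h2)) NA_integer_ else h2 - h1 - 1L,
      hexamer = if (h1 >= 6) substr(seq, h1 - 5L, h1) else NA_character_
    )
  })
  if (n_rejected > 0) {
    warn(sprintf("Rejected %d malformed or finger-less annotation row(s).", n_rejected))
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      protein_id = character(), start = integer(), end = integer(),
      c1 = integer(), c2 = integer(), h1 = integer(), h2 = integer(),
      c_gap = integer(), spacer = integer(), h_gap = integer(),
      hexamer = character()
    )
  }
  out <- mutate(out, provenance = "annotated")
  arrange(out, match(.data$protein_id, proteins$id), .data$start)
}
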