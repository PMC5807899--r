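# Protein sequence I/O and physico-chemical properties.
#
# Proteins are carried as tibbles with at least `id` and `sequence` columns
# (optionally chromosome/start/end/strand), so every downstream verb can take
# the table first and pipe.

VALID_RESIDUES <- c(
  "A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X"
)

# Average residue masses in Da (amino acid minus one water).
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

#' EMBOSS-style pKa table for isoelectric-point calculation
#'
#' Dissociation constants for the ionizable groups used by the net-charge
#' model: the two termini plus the side chains of K, R, H (basic) and
#' D, E, C, Y (acidic). The default values are the EMBOSS `iep` constants;
#' supply your own named vector to use a different convention.
#'
#' @param nterm,cterm,K,R,H,D,E,C,Y pKa values (pH units).
#' @return A named numeric vector with class `zf_pka`.
#' @export
#' @examples
#' pka_emboss()
pka_emboss <- function(nterm = 8.6, cterm = 3.6, K = 10.8, R = 12.5,
                       H = 6.5, D = 3.9, E = 4.1, C = 8.5, Y = 10.1) {
  structure(
    c(nterm = nterm, cterm = cterm, K = K, R = R, H = H, D = D, E = E,
      C = C, Y = Y),
    class = "zf_pka"
  )
}

validate_proteins <- function(proteins, arg = "proteins") {
  if (!is.data.frame(proteins) || !all(c("id", "sequence") %in% names(proteins))) {
    abort(sprintf("`%s` must be a data frame with columns `id` and `sequence`.", arg))
  }
  dup <- proteins$id[duplicated(proteins$id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate protein id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  if (any(nchar(proteins$sequence) < 1)) {
    abort("All sequences must have length >= 1.")
  }
  bad <- stringr::str_locate(proteins$sequence,
                             sprintf("[^%s]", paste(VALID_RESIDUES, collapse = "")))
  bad_row <- which(!is.na(bad[, 1]))
  if (length(bad_row) > 0) {
    i <- bad_row[1]
    abort(sprintf(
      "Illegal residue '%s' at position %d of protein '%s'.",
      substr(proteins$sequence[i], bad[i, 1], bad[i, 1]), bad[i, 1], proteins$id[i]
    ))
  }
  invisible(proteins)
}

#' Read protein sequences from a FASTA file
#'
#' Identifiers are taken from the header line up to the first whitespace;
#' sequences are uppercased and validated against the 20 standard residues
#' plus `X`. Order of entries is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`, one row per entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "zf_missing_input")
  }
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, ">"))) {
    warn(sprintf("No FASTA entries in %s; returning empty table.", path))
    return(tibble(id = character(), sequence = character()))
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  out <- tibble(id = ids, sequence = unname(toupper(as.character(aa))))
  validate_proteins(out)
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  validate_proteins(proteins)
  aa <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

net_charge <- function(counts, n_term, c_term, ph, pka) {
  pos_groups <- c(K = unname(counts["K"]), R = unname(counts["R"]),
                  H = unname(counts["H"]), nterm = n_term)
  neg_groups <- c(D = unname(counts["D"]), E = unname(counts["E"]),
                  C = unname(counts["C"]), Y = unname(counts["Y"]), cterm = c_term)
  pos_pka <- pka[c("K", "R", "H", "nterm")]
  neg_pka <- pka[c("D", "E", "C", "Y", "cterm")]
  sum(pos_groups / (1 + 10^(ph - pos_pka))) -
    sum(neg_groups / (1 + 10^(neg_pka - ph)))
}

mw_one <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  mean_mass <- mean(RESIDUE_MASS)
  masses <- RESIDUE_MASS[res]
  masses[res == "X"] <- mean_mass
  sum(masses) + WATER_MASS
}

pi_one <- function(seq, pka, tol = 1e-4) {
  res <- strsplit(seq, "")[[1]]
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(res == a), integer(1))
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH (termini always ionizable)
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(counts, 1, 1, mid, pka)
    if (abs(q) < tol || (hi - lo) < 1e-12) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Compute molecular weight and isoelectric point
#'
#' Molecular weight is the sum of average residue masses plus one water;
#' `X` contributes the mean of the 20 standard residue masses and carries no
#' charge. The isoelectric point is the pH at which the Henderson-Hasselbalch
#' net charge of the ionizable groups crosses zero, located by bisection to
#' |charge| < 1e-4.
#'
#' @param proteins Tibble with `id` and `sequence`.
#' @param pka_table pKa set, see [pka_emboss()].
#' @return Tibble with columns `id`, `length`, `mw` (Da), `pi` (pH units).
#' @export
#' @examples
#' compute_properties(tibble::tibble(id = "p1", sequence = "GG"))
compute_properties <- function(proteins, pka_table = pka_emboss()) {
  validate_proteins(proteins)
  tibble(
    id = proteins$id,
    length = nchar(proteins$sequence),
    mw = map_dbl(proteins$sequence, mw_one),
    pi = map_dbl(proteins$sequence, pi_one, pka = pka_table)
  )
}
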