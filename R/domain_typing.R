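# Per-finger typing: Q, M1-M5, Z1, Z2 or D.
#
# Decision order (geometry first, motif second):
#   1. second histidine absent            -> D
#   2. spacer != 12                       -> Z (Z1 if > 12, Z2 if < 12)
#   3. spacer 12, QALGGH, c_gap 2, h_gap 3 -> Q
#   4. any other spacer-12 finger          -> M, subclass by the number of
#      degraded positions among the five variable hexamer residues (QALGG);
#      fingers canonical in motif but with modified C/H gaps stay M1 and are
#      flagged in `note`.

CANONICAL_HEXAMER <- "QALGGH"

hexamer_degradations <- function(hexamer) {
  map_int(hexamer, function(h) {
    if (is.na(h) || nchar(h) != 6) return(NA_integer_)
    sum(strsplit(substr(h, 1, 5), "")[[1]] != strsplit("QALGG", "")[[1]])
  })
}

#' Type C2H2 zinc-finger domains
#'
#' Assigns every finger exactly one of the types Q, M1-M5, Z1, Z2 or D.
#' The rule set is a total partition: D and Z are decided by geometry alone
#' (missing second histidine; non-canonical Cys2-His1 spacer), Q requires the
#' exact QALGGH hexamer with canonical gaps at spacer 12, and M is the
#' spacer-12 catch-all with its subclass M1..M5 given by the Hamming
#' mismatches of the five variable hexamer positions against "QALGG".
#'
#' @param domains Tibble of domains from [scan_domains()] or
#'   [load_domain_annotations()].
#' @return The input with columns `family` ("Q","M","Z","D"), `subclass`
#'   ("none", "M1".."M5", "Z1", "Z2"), `degradations` (0-5) and `note` added.
#' @export
#' @examples
#' d <- scan_domains(tibble::tibble(id = "toy", sequence = "MACGACAAAAAAAQALGGHAAAH"))
#' type_domains(d)
type_domains <- function(domains) {
  if (nrow(domains) == 0) {
    return(mutate(domains, family = character(), subclass = character(),
                  degradations = integer(), note = character()))
  }
  deg <- hexamer_degradations(domains$hexamer)
  typed <- pmap(
    list(domains$h2, domains$spacer, domains$hexamer, domains$c_gap,
         domains$h_gap, deg),
    function(h2, spacer, hexamer, c_gap, h_gap, m) {
      if (is.na(h2)) {
        return(list(family = "D", subclass = "none",
                    degradations = m, note = NA_character_))
      }
      if (spacer != 12L) {
        return(list(family = "Z",
                    subclass = if (spacer > 12L) "Z1" else "Z2",
                    degradations = m, note = NA_character_))
      }
      if (identical(hexamer, CANONICAL_HEXAMER) && c_gap == 2L && h_gap == 3L) {
        return(list(family = "Q", subclass = "none",
                    degradations = 0L, note = NA_character_))
      }
      note <- if (!is.na(m) && m == 0L) "canonical motif, modified C/H gaps" else NA_character_
      list(family = "M", subclass = paste0("M", max(1L, m)),
           degradations = m, note = note)
    }
  )
  mutate(domains,
         family = map_chr(typed, "family"),
         subclass = map_chr(typed, "subclass"),
         degradations = map_int(typed, function(x) as.integer(x$degradations)),
         note = map_chr(typed, "note"))
}

#' Count typed domains per family and subclass
#'
#' @param typed Output of [type_domains()].
#' @return Tibble with `family`, `subclass`, `n`; counts sum to `nrow(typed)`.
#' @export
type_counts <- function(typed) {
  if (nrow(typed) == 0) {
    return(tibble(family = character(), subclass = character(), n = integer()))
  }
  count(typed, .data$family, .data$subclass, name = "n")
}
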