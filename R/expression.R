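# Expression-pattern calls, heatmap ordering, and relative quantification
# of qPCR measurements with RNA-seq concordance counting.
#
# Expression matrices are wide tibbles: a `gene` column plus one non-negative
# (FPKM-like) column per condition.

expr_values <- function(m) {
  if (!is.data.frame(m) || !"gene" %in% names(m) || ncol(m) < 2) {
    abort("An expression matrix is a tibble with a `gene` column plus condition columns.")
  }
  cond_cols <- setdiff(names(m), "gene")
  if (!all(vapply(m[cond_cols], is.numeric, logical(1)))) {
    abort("Condition columns must be numeric.")
  }
  v <- as.matrix(m[cond_cols])
  if (nrow(v) == 0) v <- matrix(numeric(0), 0, length(cond_cols),
                                dimnames = list(NULL, cond_cols))
  if (any(v < 0)) abort("Expression values must be non-negative.")
  rownames(v) <- m$gene
  v
}

#' Classify per-gene tissue expression patterns
#'
#' A gene is expressed in a condition when its value is at least
#' `expressed_threshold`. Patterns: `silent` (expressed nowhere),
#' `constitutive` (everywhere), `symbiosis_specific` (in at least one
#' symbiotic tissue and nowhere else), `tissue_specific` (in exactly one
#' non-symbiotic condition), `broad` otherwise. Every gene receives exactly
#' one pattern.
#'
#' @param m Expression matrix (wide tibble with `gene`).
#' @param expressed_threshold Expression call threshold (FPKM-like units,
#'   default 1).
#' @param symbiotic_tissues Condition names counted as symbiosis-relative
#'   (default nodule, root, root_hair).
#' @return Tibble `gene`, `pattern`, `expressed_in` (comma-joined condition
#'   names), `threshold`.
#' @export
classify_tissue_pattern <- function(m, expressed_threshold = 1,
                                    symbiotic_tissues = c("nodule", "root", "root_hair")) {
  v <- expr_values(m)
  if (nrow(v) == 0) abort("Empty expression matrix.")
  conds <- colnames(v)
  symb <- intersect(symbiotic_tissues, conds)
  ex <- v >= expressed_threshold
  pattern <- map_chr(seq_len(nrow(v)), function(i) {
    s <- conds[ex[i, ]]
    if (length(s) == 0) return("silent")
    if (length(s) == length(conds)) return("constitutive")
    if (length(symb) > 0 && all(s %in% symb)) return("symbiosis_specific")
    if (length(s) == 1) return("tissue_specific")
    "broad"
  })
  tibble(
    gene = rownames(v),
    pattern = pattern,
    expressed_in = map_chr(seq_len(nrow(v)),
                           function(i) paste(conds[ex[i, ]], collapse = ",")),
    threshold = expressed_threshold
  )
}

#' Hierarchical-clustering row and column orders for a heatmap
#'
#' Values are transformed `log2(x + 1)`; distances are Euclidean and linkage
#' is average (UPGMA), the usual defaults of expression heatmaps. Leaf
#' orders are the deterministic merge orders of [stats::hclust].
#'
#' @param m Expression matrix (wide tibble with `gene`, >= 2 rows).
#' @return A list: `row_order`, `col_order` (integer permutations),
#'   `row_hclust`, `col_hclust`.
#' @export
hclust_order <- function(m) {
  v <- expr_values(m)
  if (nrow(v) < 2) abort("Need at least two genes to cluster.")
  lv <- log2(v + 1)
  if (all(lv == lv[1])) warn("Constant expression matrix; ordering is arbitrary but deterministic.")
  rh <- hclust(dist(lv), method = "average")
  ch <- if (ncol(lv) >= 2) hclust(dist(t(lv)), method = "average") else NULL
  list(
    row_order = rh$order,
    col_order = if (is.null(ch)) 1L else ch$order,
    row_hclust = rh,
    col_hclust = ch
  )
}

#' Relative expression by the delta-delta-Ct method
#'
#' Cycle thresholds are averaged over replicates first; then
#' `dCt = mean(Ct_target) - mean(Ct_reference)` for sample and calibrator,
#' `ddCt = dCt_sample - dCt_calibrator`, and the fold change is `2^-ddCt`.
#'
#' @param ct_target,ct_reference Sample Ct replicates (numeric vectors).
#' @param ct_target_cal,ct_reference_cal Calibrator Ct replicates.
#' @return The fold change (positive scalar).
#' @export
#' @examples
#' ddct_fold_change(c(20, 21, 22), 18, 23, 18)  # target 2 cycles lower -> 4
ddct_fold_change <- function(ct_target, ct_reference, ct_target_cal, ct_reference_cal) {
  for (x in list(ct_target, ct_reference, ct_target_cal, ct_reference_cal)) {
    if (length(x) < 1 || any(!is.finite(x)) || any(x <= 0)) {
      abort("Ct values must be positive finite numbers with >= 1 replicate.")
    }
  }
  dct_sample <- mean(ct_target) - mean(ct_reference)
  dct_cal <- mean(ct_target_cal) - mean(ct_reference_cal)
  2^(-(dct_sample - dct_cal))
}

#' Concordance between qPCR and RNA-seq fold changes
#'
#' A data point is concordant when the sign of its log2 fold change agrees
#' between platforms; a fold change of exactly 1 (log2 = 0) is a tie and
#' counts as concordant with either direction.
#'
#' @param qpcr,rnaseq Tibbles with `gene`, `timepoint`, `fold` (positive
#'   fold changes), matched one-to-one on (gene, timepoint).
#' @return Tibble with one row: `concordant`, `total`, `percent`.
#' @export
concordance <- function(qpcr, rnaseq) {
  need <- c("gene", "timepoint", "fold")
  if (!all(need %in% names(qpcr)) || !all(need %in% names(rnaseq))) {
    abort("Both inputs need columns gene, timepoint, fold.")
  }
  key <- function(d) paste(d$gene, d$timepoint, sep = "\r")
  only_q <- setdiff(key(qpcr), key(rnaseq))
  only_r <- setdiff(key(rnaseq), key(qpcr))
  if (length(only_q) > 0 || length(only_r) > 0) {
    abort(sprintf("Unmatched (gene, timepoint) keys: %s",
                  paste(gsub("\r", "/", c(only_q, only_r)), collapse = ", ")))
  }
  j <- inner_join(qpcr, rnaseq, by = c("gene", "timepoint"),
                  suffix = c("_qpcr", "_rnaseq"))
  sq <- sign(log2(j$fold_qpcr))
  sr <- sign(log2(j$fold_rnaseq))
  ok <- sq == sr | sq == 0 | sr == 0
  tibble(concordant = sum(ok), total = nrow(j),
         percent = 100 * sum(ok) / nrow(j))
}
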