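as_tibble_strip <- function(x) tibble::as_tibble(unclass(x))

make_typed <- function(starts, ends, families) {
  tibble::tibble(
    protein_id = "p", start = as.integer(starts), end = as.integer(ends),
    c1 = as.integer(starts), c2 = as.integer(starts) + 3L,
    h1 = as.integer(ends) - 4L, h2 = as.integer(ends),
    c_gap = 2L, spacer = 12L, h_gap = 3L, hexamer = "QALGGH",
    provenance = "annotated", family = families,
    subclass = ifelse(families == "M", "M1",
                      ifelse(families == "Z", "Z1", "none")),
    degradations = 0L, note = NA_character_
  )
}

test_that("arrangement calls follow the <12-residue tandem rule", {
  # two fingers, gap 5 -> tandem
  a <- call_arrangements(make_typed(c(1, 27), c(21, 47), c("M", "M")))
  expect_identical(a$arrangement, "tandem")
  # gap 12 -> dispersed
  b <- call_arrangements(make_typed(c(1, 34), c(21, 54), c("M", "M")))
  expect_identical(b$arrangement, "dispersed")
  # gap 11 is still tandem-linked, the boundary
  b11 <- call_arrangements(make_typed(c(1, 33), c(21, 53), c("M", "M")))
  expect_identical(b11$arrangement, "tandem")
  # one finger -> single
  s <- call_arrangements(make_typed(1, 21, "Q"))
  expect_identical(s$arrangement, "single")
  expect_identical(s$longest_tandem_run, 1L)
  # gaps (5, 20) -> mixed with run 2
  m <- call_arrangements(make_typed(c(1, 27, 88), c(21, 47, 108), c("M", "M", "M")))
  expect_identical(m$arrangement, "mixed")
  expect_identical(m$longest_tandem_run, 2L)
  # overlapping domains error
  expect_error(call_arrangements(make_typed(c(1, 10), c(21, 31), c("M", "M"))),
               "Overlapping")
})

test_that("subset labels follow the arrangement/number/type scheme", {
  lab <- function(starts, ends, fams, ...) {
    suppressWarnings(classify_proteins(make_typed(starts, ends, fams), ...))$label
  }
  gap <- function(n, g) {  # n fingers of length 21 separated by g
    s <- cumsum(c(1, rep(21 + g, n - 1)))
    list(s = s, e = s + 20)
  }
  # single fingers by family
  expect_identical(lab(1, 21, "Q"), "Gm-1i-Q-SF")
  expect_identical(lab(1, 21, "Z"), "Gm-1i-Z-SF")
  expect_identical(lab(1, 21, "D"), "Gm-1i-D-SF")
  # tandem runs
  g3 <- gap(3, 5)
  expect_identical(lab(g3$s, g3$e, rep("M", 3)), "Gm-t1-SF")
  g9 <- gap(9, 5)
  expect_identical(lab(g9$s, g9$e, rep("M", 9)), "Gm-t2-SF")
  g7 <- gap(7, 5)
  expect_identical(lab(g7$s, g7$e, rep("M", 7)), "Gm-t2-SF")
  expect_identical(lab(g7$s, g7$e, rep("M", 7), t2_policy = "unclassified"),
                   "unclassified")
  # dispersed pairs by type
  g2 <- gap(2, 15)
  expect_identical(lab(g2$s, g2$e, c("Q", "Q")), "Gm-2i-Q-SF")
  expect_identical(lab(g2$s, g2$e, c("M", "M")), "Gm-2i-M-SF")
  expect_identical(lab(g2$s, g2$e, c("Q", "M")), "Gm-2i-Mix-SF")
  expect_identical(lab(g2$s, g2$e, c("Z", "Z")), "Gm-2i-Mix-SF")
  # dispersed triples and quadruples
  g3d <- gap(3, 15)
  expect_identical(lab(g3d$s, g3d$e, c("Q", "Q", "Q")), "Gm-3i-SF")
  g4d <- gap(4, 15)
  expect_identical(lab(g4d$s, g4d$e, c("Q", "M", "Z", "D")), "Gm-4i-SF")
  g5d <- gap(5, 15)
  expect_identical(lab(g5d$s, g5d$e, rep("M", 5)), "unclassified")
  # mixed arrangement classified by longest tandem run, flagged
  cls <- suppressWarnings(classify_proteins(
    make_typed(c(1, 27, 88), c(21, 47, 108), rep("M", 3))))
  expect_identical(cls$label, "Gm-t1-SF")
  expect_match(cls$note, "mixed")
})

test_that("classification recovers planted labels and is permutation-invariant", {
  recipe <- setNames(rep(8L, 11), zfsubsets:::SUBSET_LABELS)
  g <- gen_proteins(recipe, seed = 99)
  typed <- type_domains(load_domain_annotations(g$annotations, g$proteins))
  cls <- suppressWarnings(classify_proteins(typed))
  merged <- dplyr::inner_join(cls, g$truth$proteins, by = "protein_id",
                              suffix = c("", "_truth"))
  expect_identical(nrow(merged), nrow(g$truth$proteins))
  expect_true(all(merged$label == merged$label_truth))
  # unclassified rows always carry a reason; classified never do
  expect_true(all(is.na(cls$reason[cls$label != "unclassified"])))
  # permutation invariance
  cls2 <- suppressWarnings(classify_proteins(typed[sample(nrow(typed)), ]))
  expect_identical(dplyr::arrange(as_tibble_strip(cls), protein_id),
                   dplyr::arrange(as_tibble_strip(cls2), protein_id))
})

test_that("subset summary counts are conserved and round-trip planted truth", {
  recipe <- setNames(rep(10L, 11), zfsubsets:::SUBSET_LABELS)
  g <- gen_proteins(recipe, seed = 3)
  typed <- type_domains(load_domain_annotations(g$annotations, g$proteins))
  cls <- suppressWarnings(classify_proteins(typed))
  summ <- summarize_subsets(cls, typed)
  expect_identical(sum(summ$by_subset$n), nrow(cls))
  expect_true(all(summ$by_subset$n[summ$by_subset$label %in%
                                     zfsubsets:::SUBSET_LABELS] == 10L))
  expect_identical(sum(summ$by_domain_number$n), nrow(cls))
  expect_identical(sum(summ$by_q_count$n), nrow(cls))
  gl <- glance(cls)
  expect_identical(gl$n_proteins, nrow(cls))
  expect_identical(gl$n_unclassified, 0L)
})

test_that("duplication accounting counts pairs once and balances totals", {
  toy <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e", "f"),
    partner_id = c("b", "a", "d", "c", NA, NA),
    block_id = c("B1", "B1", "B2", "B2", "B3", NA)
  )
  st <- classify_duplication_status(toy)
  cnt <- duplication_counts(st)
  expect_identical(cnt$pairs, 2L)
  expect_identical(cnt$singletons, 1L)
  expect_identical(cnt$not_duplicated, 1L)
  expect_identical(2L * cnt$pairs + cnt$singletons + cnt$not_duplicated, cnt$genes)

  empty <- duplication_counts(classify_duplication_status(toy[0, ]))
  expect_identical(empty$pairs, 0L)
  expect_identical(empty$genes, 0L)

  bad <- toy; bad$partner_id[2] <- "c"
  expect_error(classify_duplication_status(bad), "Asymmetric")
})

test_that("generated duplication tables reproduce their planted accounting", {
  d <- gen_duplication_table(n_pairs = 20, n_singletons = 5, n_not_dup = 3, seed = 8)
  cnt <- duplication_counts(classify_duplication_status(d))
  expect_identical(cnt$pairs, 20L)
  expect_identical(cnt$singletons, 5L)
  expect_identical(cnt$not_duplicated, 3L)
  genes <- dplyr::select(dplyr::rename(d, id = "gene_id"),
                         "id", "chromosome", "start", "end")
  lt <- link_table(classify_duplication_status(d), genes)
  expect_identical(nrow(lt), 20L)
  expect_false(any(is.na(lt$partner_chrom)))
})
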