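toy_expr <- function(values, conditions = c("flower", "leaf", "nodule", "root")) {
  m <- matrix(values, nrow = length(values) / length(conditions),
              byrow = TRUE)
  colnames(m) <- conditions
  dplyr::bind_cols(tibble::tibble(gene = sprintf("g%d", seq_len(nrow(m)))),
                   tibble::as_tibble(m))
}

test_that("tissue patterns partition genes by where they are expressed", {
  m <- toy_expr(c(
    0, 0, 0, 0,        # silent
    9, 8, 7, 9,        # constitutive
    0, 0, 5, 7,        # nodule+root only -> symbiosis-specific
    6, 0, 0, 0,        # flower only -> tissue-specific
    5, 5, 0, 5         # several but not all -> broad
  ))
  pat <- classify_tissue_pattern(m, expressed_threshold = 1)
  expect_identical(pat$pattern,
                   c("silent", "constitutive", "symbiosis_specific",
                     "tissue_specific", "broad"))
  expect_identical(pat$expressed_in[3], "nodule,root")
  # each gene gets exactly one pattern
  expect_identical(nrow(pat), 5L)
  expect_error(classify_tissue_pattern(m[0, ]), "Empty")
})

test_that("planted expression patterns are recovered (exactly without noise)", {
  g0 <- gen_expression(200, noise_sigma = 0, seed = 14)
  pat0 <- classify_tissue_pattern(g0$expr)
  expect_identical(pat0$pattern, g0$truth$pattern)

  g <- gen_expression(1000, noise_sigma = 0.2, seed = 15)
  pat <- classify_tissue_pattern(g$expr)
  expect_gte(mean(pat$pattern == g$truth$pattern), 0.95)

  silent <- gen_expression(20, pattern_mix = c(silent = 1, constitutive = 0,
                                               symbiosis_specific = 0,
                                               tissue_specific = 0, broad = 0),
                           seed = 16)
  expect_true(all(as.matrix(silent$expr[-1]) == 0))
  expect_error(gen_expression(10, noise_sigma = -1), "noise_sigma")
})

test_that("heatmap clustering keeps identical rows adjacent and matches hand linkage", {
  m <- toy_expr(c(
    10, 10, 0, 0,
    50, 0, 50, 0,
    10, 10, 0, 0
  ))
  ord <- hclust_order(m)
  pos <- match(c(1, 3), ord$row_order)
  expect_equal(abs(diff(pos)), 1)

  # three-row toy: merge heights equal hand-computed average linkage
  lv <- log2(as.matrix(m[-1]) + 1)
  d <- as.matrix(dist(lv))
  want <- oracle_avg_linkage3(d[1, 2], d[1, 3], d[2, 3])
  expect_equal(ord$row_hclust$height, unname(want), tolerance = 1e-12)

  # permuting rows leaves merge heights unchanged
  ord2 <- hclust_order(m[c(2, 3, 1), ])
  expect_equal(sort(ord2$row_hclust$height), sort(ord$row_hclust$height))

  expect_warning(hclust_order(toy_expr(rep(1, 8))), "Constant")
})

test_that("delta-delta-Ct fold changes obey their identities", {
  # sample == calibrator -> fold 1
  expect_equal(ddct_fold_change(20, 18, 20, 18), 1)
  # target two cycles lower than calibrator, references equal -> fold 4
  expect_equal(ddct_fold_change(19, 18, 21, 18), 4)
  # replicates are averaged before differencing
  expect_equal(ddct_fold_change(c(20, 21, 22), 18, 21, 18),
               ddct_fold_change(21, 18, 21, 18))
  # shifting every Ct by a constant leaves the fold unchanged
  expect_equal(ddct_fold_change(19 + 5, 18 + 5, 21 + 5, 18 + 5), 4)
  expect_error(ddct_fold_change(numeric(0), 18, 21, 18), "replicate")
})

test_that("concordance counts direction agreement with ties concordant", {
  q <- tibble::tibble(gene = c("a", "a", "b"), timepoint = c("t1", "t2", "t1"),
                      fold = c(2, 0.5, 1))
  r <- tibble::tibble(gene = c("a", "a", "b"), timepoint = c("t1", "t2", "t1"),
                      fold = c(4, 2, 0.25))
  cc <- concordance(q, r)
  # a/t1 agree up; a/t2 disagree; b/t1 qPCR tie counts concordant
  expect_identical(cc$concordant, 2L)
  expect_identical(cc$total, 3L)

  expect_error(concordance(q[1:2, ], r), "Unmatched")

  g <- gen_qpcr_concordance(n_genes = 12, n_timepoints = 13,
                            n_discordant = 23, seed = 6)
  expect_identical(nrow(g$qpcr), 156L)
  cc2 <- concordance(g$qpcr, g$rnaseq)
  expect_identical(cc2$concordant, 156L - 23L)
  expect_equal(cc2$percent, 100 * 133 / 156, tolerance = 1e-9)
})
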