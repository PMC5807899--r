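pair_expr <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  dplyr::bind_cols(tibble::tibble(gene = names(rows)),
                   tibble::as_tibble(m, .name_repair = ~ sprintf("c%d", seq_along(.x))))
}

test_that("co-expression edges respect the |r| > 0.9 threshold with signs", {
  expr <- pair_expr(
    tf = c(1, 2, 3, 4),
    up = c(2, 4, 6, 8),
    down = c(8, 6, 4, 2),
    flat = c(5, 5, 5, 5),
    noise = c(3, 1, 4, 1)
  )
  pairs <- tibble::tibble(regulator = "tf", target = c("up", "down", "flat", "noise"))
  expect_warning(edges <- coexpression_edges(expr, pairs), "zero-variance")
  expect_setequal(edges$target, c("up", "down"))
  expect_identical(edges$sign[edges$target == "up"], "up")
  expect_identical(edges$sign[edges$target == "down"], "down")
  expect_equal(edges$weight[edges$target == "up"], 1, tolerance = 1e-12)
  expect_equal(edges$weight[edges$target == "down"], -1, tolerance = 1e-12)
  expect_error(coexpression_edges(expr[, 1:3], pairs), "3 conditions")
})

test_that("Pearson r matches the textbook formula on random profiles", {
  set.seed(23)
  n_cond <- 10
  v <- matrix(stats::rexp(40 * n_cond, 1 / 50), nrow = 40)
  genes <- sprintf("g%02d", 1:40)
  expr <- dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(v, .name_repair = ~ sprintf("c%d", seq_len(n_cond)))
  )
  pairs <- tibble::tibble(regulator = sample(genes, 200, replace = TRUE),
                          target = sample(genes, 200, replace = TRUE))
  edges <- suppressWarnings(coexpression_edges(expr, pairs, r_threshold = 0))
  textbook_r <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in seq_len(nrow(edges))) {
    x <- v[match(edges$regulator[i], genes), ]
    y <- v[match(edges$target[i], genes), ]
    expect_equal(edges$weight[i], textbook_r(x, y), tolerance = 1e-12)
  }
  expect_true(all(abs(edges$weight) <= 1))
})

test_that("network intersection keeps only shared pairs and never adds edges", {
  map <- tibble::tibble(regulator = c("a", "b", "c"), target = c("x", "y", "z"))
  co <- tibble::tibble(regulator = c("x", "q"), target = c("a", "r"),
                       sign = c("up", "down"), weight = c(0.95, -0.99))
  inter <- intersect_networks(map, co)
  # co-expression matches orientation-free: (x,a) matches map edge a->x
  expect_identical(nrow(inter), 1L)
  expect_identical(inter$regulator, "a")
  expect_identical(inter$sign, "up")
  expect_identical(inter$provenance, "intersected")
  expect_lte(nrow(inter), min(nrow(map), nrow(co)))

  none <- intersect_networks(map, co[2, ])
  expect_identical(nrow(none), 0L)
  same <- intersect_networks(
    map,
    dplyr::mutate(map, sign = "up", weight = 0.99)
  )
  expect_identical(nrow(same), nrow(map))
})

test_that("planted network intersections are recovered exactly at 0, 0.3 and 1 overlap", {
  for (f in c(0, 0.3, 1)) {
    g <- gen_networks(n_tfs = 8, n_targets = 60, overlap_fraction = f, seed = 44)
    co <- suppressWarnings(
      coexpression_edges(g$expr, g$map_edges[, c("regulator", "target")])
    )
    inter <- intersect_networks(g$map_edges, co)
    got <- dplyr::arrange(inter[, c("regulator", "target")], regulator, target)
    want <- dplyr::arrange(g$truth_intersection, regulator, target)
    expect_identical(as.data.frame(got), as.data.frame(want),
                     label = sprintf("overlap %.1f", f))
  }
})

test_that("final filtering drops nodule-silent genes, de-duplicates, flags self-loops", {
  net <- tibble::tibble(
    regulator = c("a", "a", "b", "c", "c"),
    target = c("x", "x", "y", "c", "z"),
    sign = "up", weight = 0.95, provenance = "intersected",
    self_regulation = FALSE
  )
  nod <- pair_expr(
    a = c(5, 5, 5), x = c(2, 0, 0), b = c(4, 4, 4),
    y = c(0, 0, 0),  # silent across nodule stages
    c = c(3, 3, 3), z = c(1, 2, 3)
  )
  expect_silent(final <- filter_final_network(net, nod))
  # b->y dropped (y silent); duplicate a->x collapsed; c->c kept and flagged
  expect_identical(nrow(final), 3L)
  expect_false(any(final$target == "y"))
  expect_identical(sum(final$regulator == "a"), 1L)
  expect_true(final$self_regulation[final$regulator == "c" & final$target == "c"])
  expect_true(all(final$provenance == "final"))

  # genes missing from the matrix are treated as silent, with a warning
  expect_warning(f2 <- filter_final_network(net, nod[1:3, ]), "missing")
  expect_true(all(f2$target %in% c("x")))
})

test_that("edge sets export to SIF and GraphML", {
  edges <- tibble::tibble(regulator = c("a", "b"), target = c("x", "y"),
                          sign = c("up", "down"), weight = c(0.99, -0.95))
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(edges, sif)
  expect_identical(readLines(sif), c("a\tup\tx", "b\tdown\ty"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(edges, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), 2)
})
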