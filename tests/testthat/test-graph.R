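test_that("build_graph creates hubs, gene nodes and direction-coded edges", {
  coll <- toy_collection(A = c(g1 = 1), B = c(g1 = 2))
  g <- build_graph(coll)
  expect_equal(sum(g$nodes$kind == "EXPERIMENT"), 2L)
  gene_row <- g$nodes[g$nodes$kind == "GENE", ]
  expect_equal(nrow(gene_row), 1L)
  expect_equal(gene_row$color_class, "DISCORDANT") # yellow
  expect_equal(nrow(g$edges), 2L)
  expect_setequal(g$edges$direction, c(1L, 2L))
  # experiment palette index follows input order
  expect_equal(g$nodes$color_class[g$nodes$kind == "EXPERIMENT"], c("1", "2"))
})

test_that("gene degree equals its membership count", {
  specs <- setNames(lapply(1:8, function(i) c(hub = 1)), LETTERS[1:8])
  coll <- do.call(toy_collection, specs)
  g <- build_graph(coll)
  expect_equal(sum(g$edges$gene == "hub"), 8L)
  disj <- toy_collection(A = c(g1 = 1), B = c(g2 = 2))
  gd <- build_graph(disj)
  expect_true(all(table(gd$edges$gene) == 1L))
})

test_that("edge conservation holds on random collections", {
  for (seed in 1:25) {
    coll <- random_collection(seed)
    g <- build_graph(coll)
    expect_equal(nrow(g$edges),
                 sum(vapply(coll, function(gl) nrow(gl$records), 1L)))
    expect_true(all(c(g$edges$experiment, g$edges$gene) %in% g$nodes$id))
  }
})

test_that("gene color is yellow iff its edges carry both codes", {
  coll <- random_collection(50)
  g <- build_graph(coll)
  genes <- g$nodes[g$nodes$kind == "GENE", ]
  for (i in seq_len(nrow(genes))) {
    codes <- unique(g$edges$direction[g$edges$gene == genes$id[i]])
    expect_equal(genes$color_class[i] == "DISCORDANT", length(codes) == 2L)
  }
})

test_that("layout is deterministic under a fixed seed", {
  coll <- random_collection(7)
  g <- build_graph(coll)
  l1 <- layout_graph(g, iterations = 80, seed = 123)
  l2 <- layout_graph(g, iterations = 80, seed = 123)
  expect_identical(l1$positions, l2$positions)
  l3 <- layout_graph(g, iterations = 80, seed = 124)
  expect_false(identical(l1$positions, l3$positions))
  expect_true(all(is.finite(c(l1$positions$x, l1$positions$y))))
  expect_error(layout_graph(g, iterations = 0), class = "nv_value_error")
})

test_that("layout does not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(layout_graph(build_graph(toy_collection(
    A = c(g1 = 1), B = c(g2 = 2))), iterations = 10))
  expect_identical(runif(1), before)
})

test_that("two connected nodes sit at a positive, reproducible distance", {
  coll <- toy_collection(A = c(g1 = 1), B = c(g1 = 1))
  g <- build_graph(coll)
  lay <- layout_graph(g, iterations = 100, seed = 1)
  p <- lay$positions
  d <- dist(cbind(p$x, p$y))
  expect_true(all(d > 0))
})

test_that("subset_graph induces the subgraph and drops empty hubs", {
  coll <- toy_collection(A = c(g1 = 1, g2 = 1), B = c(g3 = 2))
  g <- build_graph(coll)
  expect_message(s <- subset_graph(g, c("g1", "g2")), "dropped.*B")
  expect_false("B" %in% s$nodes$id)
  expect_setequal(s$nodes$id[s$nodes$kind == "GENE"], c("g1", "g2"))
  # identity on the full gene set
  all_genes <- g$nodes$id[g$nodes$kind == "GENE"]
  expect_equal(subset_graph(g, all_genes), g)
  expect_error(subset_graph(g, "gX"), class = "nv_emptysubset_error")
})

test_that("subset_graph is monotone", {
  coll <- random_collection(12)
  g <- build_graph(coll)
  genes <- g$nodes$id[g$nodes$kind == "GENE"]
  small <- genes[1:5]; large <- genes[1:20]
  s_small <- subset_graph(g, small)
  s_large <- subset_graph(g, large)
  expect_true(all(s_small$nodes$id %in% s_large$nodes$id))
  expect_true(nrow(s_small$edges) <= nrow(s_large$edges))
})

test_that("highlight_genes squares targets, idempotently, preserving the rest", {
  coll <- toy_collection(A = c(g1 = 1, g2 = 2), B = c(g1 = 1))
  g <- build_graph(coll)
  h1 <- highlight_genes(g, "g1")
  expect_equal(h1$nodes$shape[h1$nodes$id == "g1"], "square")
  expect_true(all(h1$nodes$shape[h1$nodes$id != "g1"] == "circle"))
  expect_equal(highlight_genes(h1, "g1"), h1) # idempotent
  expect_equal(highlight_genes(g, character()), g) # empty = no-op
  expect_warning(h2 <- highlight_genes(g, c("g1", "nope")),
                 class = "nv_unknown_warning")
  expect_equal(h2$nodes$shape[h2$nodes$id == "g1"], "square")
})

test_that("graph JSON write -> read -> write is byte-identical", {
  dir <- withr::local_tempdir()
  g <- highlight_genes(build_graph(random_collection(3)), character())
  p1 <- file.path(dir, "g1.json"); p2 <- file.path(dir, "g2.json")
  write_graph_json(g, p1)
  g2 <- read_graph_json(p1)
  expect_equal(g2, g)
  write_graph_json(g2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("a gene id colliding with an experiment name is rejected", {
  coll <- toy_collection(A = c(B = 1), B = c(g2 = 2))
  expect_error(build_graph(coll), class = "nv_namecollision_error")
})
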