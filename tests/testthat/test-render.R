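test_that("SVG element counts match nodes and edges", {
  for (seed in c(2, 9)) {
    coll <- random_collection(seed)
    g <- build_graph(coll)
    lay <- layout_graph(g, iterations = 50)
    svg <- render_svg(g, lay, labels = "off")
    n_shapes <- lengths(regmatches(svg, gregexpr('class="node"', svg)))
    n_lines <- lengths(regmatches(svg, gregexpr('class="edge"', svg)))
    expect_equal(n_shapes, nrow(g$nodes))
    expect_equal(n_lines, nrow(g$edges))
  }
})

test_that("highlighted genes render as rect elements", {
  coll <- toy_collection(A = c(g1 = 1, g2 = 2), B = c(g1 = 1))
  g <- highlight_genes(build_graph(coll), "g1")
  svg <- render_svg(g, layout_graph(g, iterations = 50))
  expect_equal(lengths(regmatches(svg, gregexpr("<rect[^/]*class=\"node\"", svg))), 1L)
})

test_that("SVG output is deterministic and consistent with the layout", {
  coll <- random_collection(4)
  g <- build_graph(coll)
  lay <- layout_graph(g, iterations = 60, seed = 5)
  expect_identical(render_svg(g, lay), render_svg(g, lay))
  # pure: inputs unchanged by rendering
  g0 <- g; lay0 <- lay
  invisible(render_svg(g, lay))
  expect_identical(g, g0); expect_identical(lay, lay0)
  # missing node in layout
  lay$positions <- lay$positions[-1, ]
  expect_error(render_svg(g, lay), class = "nv_consistency_error")
})

test_that("PNG honors the canvas * dpi / 72 pixel contract", {
  dir <- withr::local_tempdir()
  coll <- toy_collection(A = c(g1 = 1), B = c(g1 = 2))
  g <- build_graph(coll)
  lay <- layout_graph(g, iterations = 30)
  style <- nv_style(canvas = c(width = 600, height = 400))
  p <- file.path(dir, "g.png")
  render_png(g, lay, p, style = style, dpi = 300)
  # read dimensions straight from the PNG IHDR chunk
  bytes <- readBin(p, "raw", 33)
  expect_identical(bytes[1:8],
                   as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)))
  dims <- readBin(bytes[17:24], "integer", n = 2, size = 4, endian = "big")
  expect_equal(dims, c(round(600 * 300 / 72), round(400 * 300 / 72)))
  expect_error(render_png(g, lay, p, dpi = 50), class = "nv_value_error")
})

test_that("info table has one sorted row per gene with exact codes", {
  coll <- toy_collection(A = c(g2 = 1, g1 = 1), B = c(g2 = 2))
  g <- build_graph(coll)
  tab <- info_table(g, toy_annotation())
  expect_equal(tab$gene_id, c("g1", "g2"))
  expect_equal(tab$A, c("1", "1"))
  expect_equal(tab$B, c("", "2"))
  expect_equal(tab$direction_class, c("UP", "DISCORDANT"))
  expect_equal(tab$description[1], "mercaptopyruvate sulfurtransferase")
  expect_match(tab$go_terms[2], "GO:0006979")
  expect_match(tab$pathway_terms[2], "ath00920")
  # unannotated gene -> empty cells
  expect_equal(tab$pathway_terms[1], "")
})

test_that("subset info table has exactly the subset's rows", {
  coll <- random_collection(8)
  g <- build_graph(coll)
  genes <- sort(g$nodes$id[g$nodes$kind == "GENE"])[1:4]
  s <- suppressMessages(subset_graph(g, genes))
  expect_equal(nrow(info_table(s)), 4L)
})

test_that("info table TSV round trip is lossless and byte-stable", {
  dir <- withr::local_tempdir()
  coll <- random_collection(21)
  g <- build_graph(coll)
  tab <- info_table(g, toy_annotation())
  p1 <- file.path(dir, "t1.tsv"); p2 <- file.path(dir, "t2.tsv")
  write_info_table(tab, p1)
  tab2 <- read_info_table(p1)
  expect_equal(tab2, tab)
  write_info_table(tab2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("enrichment TSV export is stable and re-parsable", {
  dir <- withr::local_tempdir()
  res <- enrich(c("g1", "g2", "g3"), toy_annotation(),
                background = paste0("g", 1:10), adjust = "bh")
  p <- file.path(dir, "enr.tsv")
  write_enrichment(res, p)
  back <- read.delim(p, check.names = FALSE)
  expect_equal(nrow(back), nrow(res))
  expect_equal(back$term_id, res$term_id)
  expect_equal(back$k, res$k)
})

test_that("style validation rejects bad colors and dimensions", {
  expect_error(nv_style(background = "white"), class = "nv_value_error")
  expect_error(nv_style(edge_width = 0), class = "nv_value_error")
  expect_error(nv_style(palette = "#000000"), class = "nv_value_error")
})
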