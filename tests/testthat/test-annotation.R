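test_that("GMT parsing reads term, category suffix and genes", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sets.gmt")
  writeLines(c("GO:0006979\toxidative stress|GO_BP\tg1\tg2",
               "ath00920\tSulfur metabolism|PATHWAY\tg2\tg3\tg3"), p)
  tab <- read_annotations(p)
  expect_equal(nrow(tab$terms), 2L)
  expect_equal(genes_for_term(tab, "GO:0006979"), c("g1", "g2"))
  expect_equal(genes_for_term(tab, "ath00920"), c("g2", "g3")) # deduped
  expect_equal(tab$terms$category, c("GO_BP", "PATHWAY"))
})

test_that("GMT category defaults follow the term-id prefix", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sets.gmt")
  writeLines(c("GO:0000001\tsomething\tg1", "map00010\tGlycolysis\tg1"), p)
  tab <- read_annotations(p)
  expect_equal(tab$terms$category, c("GO_BP", "PATHWAY"))
})

test_that("long TSV parsing dedups pairs and rejects bad categories", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "long.tsv")
  writeLines(c("g1\tGO:1\toxidative stress\tGO_BP",
               "g1\tGO:1\toxidative stress\tGO_BP",
               "g2\tGO:1\toxidative stress\tGO_BP"), p)
  tab <- read_annotations(p, format = "long_tsv")
  expect_equal(genes_for_term(tab, "GO:1"), c("g1", "g2"))

  writeLines("g1\tGO:1\tname\tNOT_A_CATEGORY", p)
  expect_error(read_annotations(p, format = "long_tsv"),
               class = "nv_format_error")
  writeLines(c("g1\tGO:1\tname A\tGO_BP", "g2\tGO:1\tname B\tGO_BP"), p)
  expect_error(read_annotations(p, format = "long_tsv"),
               class = "nv_conflict_error")
})

test_that("empty annotation file yields a valid empty table with warning", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "empty.gmt")
  writeLines(character(), p)
  expect_warning(tab <- read_annotations(p), class = "nv_empty_warning")
  expect_equal(nrow(tab$terms), 0L)
})

test_that("inverse maps are exact after load", {
  tab <- toy_annotation()
  for (t in names(tab$term_genes)) {
    for (g in tab$term_genes[[t]]) {
      expect_true(t %in% tab$gene_terms[[g]])
    }
  }
  for (g in names(tab$gene_terms)) {
    for (t in tab$gene_terms[[g]]) {
      expect_true(g %in% tab$term_genes[[t]])
    }
  }
})

test_that("keyword search is case-insensitive substring, stable by term_id", {
  tab <- toy_annotation()
  hit <- search_terms(tab, "OXIDATIVE STRESS")
  expect_equal(hit$term_id, "GO:0006979")
  expect_equal(search_terms(tab, "sulfur metabolism")$term_id, "ath00920")
  expect_equal(nrow(search_terms(tab, "zzz-no-such")), 0L)
  # idempotent + subset of terms, category filter honored
  expect_equal(search_terms(tab, "e"), search_terms(tab, "e"))
  expect_true(all(search_terms(tab, "e")$term_id %in% tab$terms$term_id))
  expect_equal(search_terms(tab, "e", category = "PATHWAY")$term_id,
               "ath00920")
  # search by id substring
  expect_equal(search_terms(tab, "0006979")$term_id, "GO:0006979")
  expect_error(search_terms(tab, ""), class = "nv_value_error")
})

test_that("genes_for_term copies and errors on unknown ids", {
  tab <- toy_annotation()
  g <- genes_for_term(tab, "GO:0006979")
  g[1] <- "mutated"
  expect_equal(genes_for_term(tab, "GO:0006979"), c("g1", "g2", "g3"))
  expect_error(genes_for_term(tab, "GO:404"), class = "nv_notfound_error")
})

test_that("annotate_gene handles all annotation states", {
  tab <- toy_annotation()
  a <- annotate_gene(tab, "g2")
  expect_equal(a$description, "cysteine desulfhydrase")
  expect_setequal(a$terms$term_id, c("GO:0006979", "ath00920"))
  none <- annotate_gene(tab, "gX")
  expect_equal(none$description, "")
  expect_equal(nrow(none$terms), 0L)
  desc_only <- set_descriptions(tab, c(gY = "desc only"))
  a2 <- annotate_gene(desc_only, "gY")
  expect_equal(a2$description, "desc only")
  expect_equal(nrow(a2$terms), 0L)
})

test_that("merge_annotations combines tables and rejects shared ids", {
  tab <- toy_annotation()
  other <- annotation_table(
    data.frame(term_id = "GO:0008150", term_name = "biological process",
               category = "GO_BP", stringsAsFactors = FALSE),
    list("GO:0008150" = "g9"))
  merged <- merge_annotations(tab, other)
  expect_equal(nrow(merged$terms), 4L)
  expect_error(merge_annotations(tab, tab), class = "nv_conflict_error")
})

test_that("GMT write -> read recovers the table", {
  dir <- withr::local_tempdir()
  tab <- toy_annotation()
  p <- file.path(dir, "out.gmt")
  write_gmt(tab, p)
  tab2 <- read_annotations(p)
  expect_equal(tab2$terms, tab$terms)
  expect_equal(tab2$term_genes[order(names(tab2$term_genes))],
               tab$term_genes[order(names(tab$term_genes))])
})
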