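test_that("make_counts counts the 2x2 table and drops out-of-universe genes", {
  bg <- paste0("g", 1:10)
  c1 <- make_counts(c("g1", "g2"), "g1", bg)
  expect_equal(unclass(c1)[c("k", "K", "n", "N")],
               list(k = 1L, K = 1L, n = 2L, N = 10L))
  expect_equal(make_counts(c("g1", "g2"), c("g5", "g6"), bg)$k, 0L)
  expect_warning(c2 <- make_counts(c("g1", "gZ"), "g1", bg),
                 class = "nv_dropped_warning")
  expect_equal(c2$n, 1L)
  expect_error(make_counts("g1", "g1", character()), class = "nv_value_error")
  expect_error(suppressWarnings(make_counts("gZ", "g1", bg)),
               class = "nv_value_error")
})

test_that("fisher_p reproduces the enumerated tail example", {
  # (k=4, K=5, n=6, N=20): tail = [C(5,4)C(15,2) + C(5,5)C(15,1)] / C(20,6)
  expect_equal(fisher_p(list(k = 4, K = 5, n = 6, N = 20)), 540 / 38760,
               tolerance = 1e-12)
  expect_equal(fisher_p(list(k = 0, K = 5, n = 6, N = 20)), 1)
  # EASE at k equals the standard tail at k-1 on the same margins
  expect_equal(fisher_p(list(k = 4, K = 5, n = 6, N = 20), variant = "ease"),
               fisher_p(list(k = 3, K = 5, n = 6, N = 20)))
  expect_error(fisher_p(list(k = 7, K = 5, n = 6, N = 20)),
               class = "nv_value_error")
})

test_that("fisher_p agrees with stats::fisher.test one-sided", {
  set.seed(11)
  for (i in 1:25) {
    N <- sample(10:60, 1); n <- sample(1:N, 1); K <- sample(1:N, 1)
    lo <- max(0, n + K - N); hi <- min(n, K) # keep all four cells >= 0
    k <- lo + sample.int(hi - lo + 1, 1) - 1
    m <- matrix(c(k, n - k, K - k, N - K - n + k), 2, byrow = TRUE)
    expect_equal(fisher_p(list(k = k, K = K, n = n, N = N)),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("adjust_pvalues implements BH step-up and validates input", {
  expect_equal(adjust_pvalues(0.03, "bh"), 0.03)
  # hand-derived step-up: min over j >= i of p_(j) * m / j
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  p <- c(0.5, 0.01, 0.2)
  expect_equal(adjust_pvalues(p, "none"), p)
  # order preserved, monotone vs raw, capped at 1
  set.seed(3)
  q <- runif(20)
  adj <- adjust_pvalues(q, "bh")
  expect_true(all(adj >= q) && all(adj <= 1))
  expect_error(adjust_pvalues(c(0.1, 0), "bh"), class = "nv_value_error")
  expect_error(adjust_pvalues(c(0.1, 1.2), "bh"), class = "nv_value_error")
})

test_that("enrich ranks terms by p, adjusts within category, keeps K >= 1", {
  tab <- toy_annotation()
  bg <- paste0("g", 1:20)
  res <- enrich(c("g1", "g2", "g3"), tab, background = bg, adjust = "bh")
  expect_s3_class(res, "nv_enrichment")
  expect_equal(res$term_id[1], "GO:0006979") # all 3 selected genes in term
  expect_false(is.unsorted(res$p_raw))
  expect_true(all(res$p_adj >= res$p_raw))
  expect_true(all(res$K >= 1))
  expect_equal(res$n[1], 3L)
  expect_equal(res$N[1], 20L)
})

test_that("selected == background makes every term's p exactly 1", {
  tab <- toy_annotation()
  bg <- paste0("g", 1:6)
  res <- enrich(bg, tab, background = bg)
  expect_true(all(res$p_raw == 1))
})

test_that("a term covering no selected gene yields p = 1", {
  tab <- annotation_table(
    data.frame(term_id = "T1", term_name = "only term", category = "PATHWAY",
               stringsAsFactors = FALSE),
    list(T1 = c("g9", "g10")))
  res <- enrich(c("g1", "g2"), tab, background = paste0("g", 1:10))
  expect_equal(nrow(res), 1L)
  expect_equal(res$p_raw, 1)
  expect_equal(res$odds_ratio, 0)
})

test_that("annotated_genome background is the union of annotated genes", {
  tab <- toy_annotation()
  res <- enrich(c("g1", "g2"), tab)
  expect_equal(unique(res$N), length(unique(unlist(tab$term_genes))))
})

test_that("p is non-increasing in k at fixed margins", {
  for (K in c(5, 12)) {
    p <- vapply(0:K, function(k) fisher_p(list(k = k, K = K, n = 15, N = 40)),
                1.0)
    expect_true(all(diff(p) <= 1e-15))
  }
})
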