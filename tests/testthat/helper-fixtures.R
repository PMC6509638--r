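# Shared in-code fixtures: tiny collections, annotation tables, and the
# independent brute-force oracles used against the implementation.

# build an nv_collection from named lists of gene_id -> code,
# e.g. toy_collection(A = c(g1 = 1, g2 = 2), B = c(g1 = 2))
toy_collection <- function(...) {
  specs <- list(...)
  as_gene_collection(lapply(names(specs), function(nm) {
    parse_gene_list(sprintf("%s\t%d", names(specs[[nm]]),
                            as.integer(specs[[nm]])), name = nm)
  }))
}

# write a gene list spec to a temp TSV file, return the path
toy_list_file <- function(genes, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  writeLines(sprintf("%s\t%d", names(genes), as.integer(genes)), path)
  path
}

# small two-category annotation table used across tests
toy_annotation <- function() {
  annotation_table(
    terms = data.frame(
      term_id = c("GO:0006979", "GO:0009999", "ath00920"),
      term_name = c("response to oxidative stress", "unrelated process",
                    "Sulfur metabolism"),
      category = c("GO_BP", "GO_BP", "PATHWAY"),
      stringsAsFactors = FALSE),
    term_genes = list(
      "GO:0006979" = c("g1", "g2", "g3"),
      "GO:0009999" = c("g4", "g5"),
      "ath00920" = c("g2", "g6")),
    descriptions = c(g1 = "mercaptopyruvate sulfurtransferase",
                     g2 = "cysteine desulfhydrase")
  )
}

# independent oracle: hypergeometric upper tail P[X >= k] by direct
# enumeration of binomial coefficients (never via phyper/dhyper)
oracle_tail <- function(k, K, n, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- seq.int(max(k, 0L), hi)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# independent oracle: signature of each gene by scanning every list
oracle_signatures <- function(collection) {
  genes <- unique(unlist(lapply(collection, function(gl) gl$records$gene_id)))
  vapply(genes, function(g) {
    paste(names(collection)[vapply(collection, function(gl) {
      g %in% gl$records$gene_id
    }, TRUE)], collapse = "+")
  }, "")
}

# random collection of 2-8 lists over a small gene pool (for properties)
random_collection <- function(seed) {
  set.seed(seed)
  n_exp <- sample(2:8, 1)
  pool <- sprintf("g%03d", seq_len(sample(20:120, 1)))
  as_gene_collection(lapply(seq_len(n_exp), function(i) {
    genes <- sample(pool, sample(3:length(pool), 1))
    parse_gene_list(sprintf("%s\t%d", genes, sample(1:2, length(genes), TRUE)),
                    name = LETTERS[i])
  }))
}
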