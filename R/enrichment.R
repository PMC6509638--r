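## Over-representation analysis: one-sided Fisher exact test of a gene
## selection against each annotated term, DAVID-style.
##
## The 2x2 table for a term is
##
##                 in term   not in term
##   selected         k         n - k
##   not selected   K - k    N - K - n + k
##
## over a background universe of N genes of which K carry the term and n
## are selected.  Under the null, k ~ Hypergeometric(N, K, n) and the
## over-representation p-value is the upper tail P[X >= k].  The EASE
## variant (DAVID's "modified Fisher exact test") recomputes the tail after
## discounting one overlapping gene: P[X >= max(k - 1, 0)], which is always
## at least as large (more conservative).

#' Build the 2x2 contingency counts for one term
#'
#' Selected genes absent from the background universe are dropped (with a
#' warning giving the count) before counting, so the table is always
#' consistent with the universe.
#'
#' @param selected character vector of selected gene ids.
#' @param term_genes character vector of gene ids annotated to the term.
#' @param background character vector: the gene universe.
#' @return An object of class `nv_counts`: list with integers `k` (selected
#'   and in term), `K` (in term), `n` (selected), `N` (universe size).
#' @export
make_counts <- function(selected, term_genes, background) {
  background <- unique(as.character(background))
  if (length(background) == 0L) {
    nv_abort("background universe is empty", "nv_value_error")
  }
  selected <- unique(as.character(selected))
  dropped <- setdiff(selected, background)
  if (length(dropped)) {
    nv_warn(sprintf("%d selected gene(s) absent from the background were dropped",
                    length(dropped)), "nv_dropped_warning")
  }
  sel <- intersect(selected, background)
  if (length(sel) == 0L) {
    nv_abort("no selected gene lies in the background universe; cannot form counts",
             "nv_value_error")
  }
  tg <- intersect(unique(as.character(term_genes)), background)
  structure(list(k = length(intersect(sel, tg)),
                 K = length(tg),
                 n = length(sel),
                 N = length(background)),
            class = "nv_counts")
}

#' One-sided Fisher exact p-value for over-representation
#'
#' Computes the hypergeometric upper tail `P[X >= k]` for
#' `X ~ Hypergeometric(N, K, n)`.  With `variant = "ease"` the observed
#' overlap is first reduced to `max(k - 1, 0)` (the EASE score), a
#' deliberately conservative variant that damps significance arising from a
#' single overlapping gene.
#'
#' @param counts an `nv_counts` from [make_counts()], or a list with
#'   elements `k`, `K`, `n`, `N`.
#' @param variant `"standard"` or `"ease"`.
#' @return The p-value, a number in `(0, 1]`.
#' @export
#' @examples
#' fisher_p(list(k = 4, K = 5, n = 6, N = 20)) # 540/38760
fisher_p <- function(counts, variant = c("standard", "ease")) {
  variant <- match.arg(variant)
  k <- as.integer(counts$k); K <- as.integer(counts$K)
  n <- as.integer(counts$n); N <- as.integer(counts$N)
  if (anyNA(c(k, K, n, N)) || k < 0L || K > N || n > N || k > min(n, K)) {
    nv_abort("invalid contingency counts", "nv_value_error")
  }
  if (variant == "ease") k <- max(k - 1L, 0L)
  # upper tail P[X >= k]; phyper(k - 1, ...) with lower.tail = FALSE
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1) # clamp underflow; contract is (0, 1]
}

# sample odds ratio of the 2x2 table; +Inf when the null-cell product is 0
# and the overlap is positive, 0 when the overlap itself is 0
odds_ratio_counts <- function(k, K, n, N) {
  a <- k; b <- n - k; c_ <- K - k; d <- N - K - n + k
  num <- as.numeric(a) * d
  den <- as.numeric(b) * c_
  ifelse(den > 0, num / den, ifelse(a > 0, Inf, 0))
}

#' Adjust p-values for multiple testing
#'
#' `"bh"` applies the Benjamini-Hochberg step-up procedure (monotone,
#' capped at 1); `"none"` returns the input unchanged.  Output order
#' matches input order.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @param method `"none"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("none", "bh")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    nv_abort("p-values must lie in (0, 1]", "nv_value_error")
  }
  switch(method,
         none = p,
         bh = stats::p.adjust(p, method = "BH"))
}

#' Test every term for over-representation in a gene selection
#'
#' Runs [fisher_p()] for each term with at least one background-resident
#' annotated gene.  The paper-style default reports raw p-values
#' (`adjust = "none"`); Benjamini-Hochberg correction is available and is
#' applied within each annotation category separately (pathways and the
#' three GO aspects are distinct term families).
#'
#' @param selected character vector of selected gene ids (e.g. a Venn
#'   region, a subset graph's genes, or every gene in the graph).
#' @param table an `nv_annotation`.
#' @param background `"annotated_genome"` (default: every gene annotated to
#'   any term in the table) or a character vector giving a custom universe
#'   (e.g. the union of all input lists).
#' @param variant `"standard"` or `"ease"`; see [fisher_p()].
#' @param adjust `"none"` or `"bh"`; see [adjust_pvalues()].
#' @return A data.frame of class `nv_enrichment`, sorted by ascending
#'   `p_raw` with ties broken by `term_id`, with columns `category`,
#'   `term_id`, `term_name`, `k`, `K`, `n`, `N`, `odds_ratio`, `p_raw`,
#'   `p_adj`.
#' @export
enrich <- function(selected, table,
                   background = "annotated_genome",
                   variant = c("standard", "ease"),
                   adjust = c("none", "bh")) {
  stopifnot(inherits(table, "nv_annotation"))
  variant <- match.arg(variant)
  adjust <- match.arg(adjust)
  if (length(selected) == 0L) {
    nv_abort("selection is empty", "nv_value_error")
  }
  if (nrow(table$terms) == 0L) {
    nv_abort("annotation table has no terms", "nv_empty_error")
  }
  if (identical(background, "annotated_genome")) {
    background <- names(table$gene_terms)
  }
  background <- unique(as.character(background))
  if (length(background) == 0L) {
    nv_abort("background universe is empty", "nv_value_error")
  }
  selected <- unique(as.character(selected))
  dropped <- setdiff(selected, background)
  if (length(dropped)) {
    nv_warn(sprintf("%d selected gene(s) absent from the background were dropped",
                    length(dropped)), "nv_dropped_warning")
  }
  sel <- intersect(selected, background)
  if (length(sel) == 0L) {
    nv_abort("no selected gene lies in the background universe", "nv_value_error")
  }

  in_bg <- stats::setNames(rep(TRUE, length(background)), background)
  in_sel <- stats::setNames(background %in% sel, background)
  n <- length(sel); N <- length(background)

  tg_bg <- lapply(table$term_genes, function(g) {
    g <- unique(g)
    g[!is.na(in_bg[g])]
  })
  K <- vapply(tg_bg, length, 1L)
  keep <- K >= 1L
  tids <- names(tg_bg)[keep]
  K <- K[keep]
  k <- vapply(tg_bg[keep], function(g) sum(in_sel[g]), 1L)

  p_raw <- stats::phyper(
    (if (variant == "ease") pmax(k - 1L, 0L) else k) - 1L,
    K, N - K, n, lower.tail = FALSE)
  p_raw <- pmin(pmax(p_raw, .Machine$double.xmin), 1)

  meta <- table$terms[match(tids, table$terms$term_id), , drop = FALSE]
  res <- data.frame(category = meta$category,
                    term_id = tids,
                    term_name = meta$term_name,
                    k = k, K = K, n = n, N = N,
                    odds_ratio = odds_ratio_counts(k, K, n, N),
                    p_raw = p_raw,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$p_adj <- res$p_raw
  if (adjust == "bh") {
    for (cat_ in unique(res$category)) {
      i <- res$category == cat_
      res$p_adj[i] <- adjust_pvalues(res$p_raw[i], "bh")
    }
  }
  res <- res[order(res$p_raw, res$term_id, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("nv_enrichment", "data.frame")
  res
}

#' Write an enrichment table as TSV
#'
#' @param res an `nv_enrichment` from [enrich()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(res, path) {
  stopifnot(inherits(res, "nv_enrichment"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- "category\tterm_id\tterm_name\tk\tK\tn\tN\todds_ratio\tp_raw\tp_adj"
  body <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%s\t%s\t%s",
                  res$category, res$term_id, res$term_name,
                  res$k, res$K, res$n, res$N,
                  format_num(res$odds_ratio), format_num(res$p_raw),
                  format_num(res$p_adj))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# fixed significant-digit formatting so repeated writes are byte-identical
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (!is.finite(v)) return(if (is.infinite(v)) "Inf" else "NA")
    sprintf("%.6g", v)
  }, "")
  out
}
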