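## Local annotation store: gene <-> term maps (KEGG pathway / GO), gene
## descriptions, keyword search.  Replaces a live pathway/GO database with
## plain files the user supplies (GMT or long TSV), so the method runs
## fully offline and species choice is implicit in the file.

#' Construct an annotation table from in-memory pieces
#'
#' @param terms data.frame with columns `term_id`, `term_name`, `category`
#'   (one of `"PATHWAY"`, `"GO_BP"`, `"GO_MF"`, `"GO_CC"`).
#' @param term_genes named list: `term_id` -> character vector of gene ids.
#' @param descriptions optional named character vector: gene id -> free-text
#'   description.
#' @return An object of class `nv_annotation` with elements `terms`,
#'   `term_genes`, `gene_terms` (the exact inverse map) and `descriptions`.
#' @export
annotation_table <- function(terms, term_genes, descriptions = character()) {
  stopifnot(is.data.frame(terms),
            all(c("term_id", "term_name", "category") %in% names(terms)))
  if (anyDuplicated(terms$term_id)) {
    nv_abort("duplicate term_id in terms table", "nv_conflict_error")
  }
  bad <- setdiff(unique(terms$category), ANNOTATION_CATEGORIES)
  if (length(bad)) {
    nv_abort(sprintf("unknown annotation category '%s' (allowed: %s)",
                     bad[1L], paste(ANNOTATION_CATEGORIES, collapse = ", ")),
             "nv_format_error")
  }
  if (!all(names(term_genes) %in% terms$term_id)) {
    nv_abort("term_genes contains term ids absent from the terms table",
             "nv_format_error")
  }
  term_genes <- lapply(term_genes, function(g) unique(as.character(g)))
  # invert to gene -> terms
  if (length(term_genes)) {
    long_t <- rep(names(term_genes), lengths(term_genes))
    long_g <- unlist(term_genes, use.names = FALSE)
    gene_terms <- split(long_t, long_g)
  } else {
    gene_terms <- list()
  }
  structure(list(terms = terms[, c("term_id", "term_name", "category")],
                 term_genes = term_genes,
                 gene_terms = gene_terms,
                 descriptions = descriptions),
            class = "nv_annotation")
}

# long TSV: gene_id <TAB> term_id <TAB> term_name <TAB> category
read_annotations_long <- function(lines, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # tolerate a literal header row
  if (length(fields) && identical(tolower(fields[[1L]][1L]), "gene_id")) {
    fields <- fields[-1L]
    nf <- nf[-1L]
  }
  if (any(nf != 4L)) {
    nv_abort(sprintf("%s: long-TSV annotation lines need 4 fields (gene_id, term_id, term_name, category)",
                     path), "nv_format_error")
  }
  gene <- trim_ws(vapply(fields, `[[`, "", 1L))
  tid <- trim_ws(vapply(fields, `[[`, "", 2L))
  tname <- trim_ws(vapply(fields, `[[`, "", 3L))
  cat_ <- trim_ws(vapply(fields, `[[`, "", 4L))
  bad <- which(!(cat_ %in% ANNOTATION_CATEGORIES))
  if (length(bad)) {
    nv_abort(sprintf("%s: unknown category token '%s'", path, cat_[bad[1L]]),
             "nv_format_error")
  }
  # a term id must not carry conflicting names or categories
  for (col in list(tname, cat_)) {
    n_per <- tapply(col, tid, function(x) length(unique(x)))
    if (any(n_per > 1L)) {
      nv_abort(sprintf("%s: term '%s' has conflicting name/category across lines",
                       path, names(n_per)[n_per > 1L][1L]), "nv_conflict_error")
    }
  }
  first <- !duplicated(tid)
  terms <- data.frame(term_id = tid[first], term_name = tname[first],
                      category = cat_[first], stringsAsFactors = FALSE)
  annotation_table(terms, split(gene, tid))
}

# GMT: term_id <TAB> term_name[|CATEGORY] <TAB> gene1 <TAB> gene2 ...
read_annotations_gmt <- function(lines, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    nv_abort(sprintf("%s: GMT lines need at least term id and description",
                     path), "nv_format_error")
  }
  tid <- trim_ws(vapply(fields, `[[`, "", 1L))
  desc <- vapply(fields, `[[`, "", 2L)
  has_cat <- grepl("|", desc, fixed = TRUE)
  tname <- trim_ws(ifelse(has_cat, sub("\\|[^|]*$", "", desc), desc))
  cat_ <- ifelse(has_cat, trim_ws(sub("^.*\\|", "", desc)),
                 ifelse(startsWith(tid, "GO:"), "GO_BP", "PATHWAY"))
  bad <- which(!(cat_ %in% ANNOTATION_CATEGORIES))
  if (length(bad)) {
    nv_abort(sprintf("%s: unknown category token '%s'", path, cat_[bad[1L]]),
             "nv_format_error")
  }
  if (anyDuplicated(tid)) {
    nv_abort(sprintf("%s: term '%s' appears on more than one GMT line",
                     path, tid[duplicated(tid)][1L]), "nv_conflict_error")
  }
  genes <- lapply(fields, function(f) {
    g <- trim_ws(f[-(1:2)])
    g[nzchar(g)]
  })
  terms <- data.frame(term_id = tid, term_name = tname, category = cat_,
                      stringsAsFactors = FALSE)
  annotation_table(terms, stats::setNames(genes, tid))
}

#' Read an annotation table from disk
#'
#' Two formats are supported:
#' * `"gmt"` — one gene set per line: term id, description, then member
#'   genes, tab-separated.  The description may carry a category suffix
#'   (`name|GO_BP` etc.); without one, ids starting `"GO:"` default to
#'   `GO_BP` and everything else to `PATHWAY`.
#' * `"long_tsv"` — four columns per line: `gene_id`, `term_id`,
#'   `term_name`, `category`.
#'
#' `format = "auto"` picks `long_tsv` for `.tsv`/`.txt` and `gmt` for
#' `.gmt` extensions.
#'
#' @param path annotation file.
#' @param format `"auto"`, `"gmt"` or `"long_tsv"`.
#' @return An `nv_annotation`; see [annotation_table()].  An empty file
#'   yields an empty (valid but unusable) table with a warning.
#' @export
read_annotations <- function(path, format = c("auto", "gmt", "long_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    nv_abort(sprintf("annotation file not found: %s", path), "nv_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "long_tsv"
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^[ \t]*$", lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    nv_warn(sprintf("%s: empty annotation file; enrichment will be impossible",
                    path), "nv_empty_warning")
    return(annotation_table(
      data.frame(term_id = character(), term_name = character(),
                 category = character(), stringsAsFactors = FALSE),
      list()
    ))
  }
  switch(format,
         gmt = read_annotations_gmt(lines, path),
         long_tsv = read_annotations_long(lines, path))
}

#' Write an annotation table as GMT
#'
#' @param table an `nv_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(table, path) {
  stopifnot(inherits(table, "nv_annotation"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  t <- table$terms
  lines <- vapply(seq_len(nrow(t)), function(i) {
    genes <- table$term_genes[[t$term_id[i]]] %||% character()
    paste(c(t$term_id[i], paste0(t$term_name[i], "|", t$category[i]), genes),
          collapse = "\t")
  }, "")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a gene-description table (gene_id TAB description)
#'
#' @param path two-column TSV.
#' @return Named character vector of descriptions.
#' @export
read_gene_descriptions <- function(path) {
  if (!file.exists(path)) {
    nv_abort(sprintf("description file not found: %s", path), "nv_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trim_ws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) return(character())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    nv_abort(sprintf("%s: description lines need 2 tab-separated fields", path),
             "nv_format_error")
  }
  g <- trim_ws(vapply(fields, `[[`, "", 1L))
  d <- vapply(fields, `[[`, "", 2L)
  stats::setNames(d, g)[!duplicated(g)]
}

#' Attach gene descriptions to an annotation table
#'
#' @param table an `nv_annotation`.
#' @param descriptions named character vector (gene id -> description).
#' @return The updated `nv_annotation`.
#' @export
set_descriptions <- function(table, descriptions) {
  stopifnot(inherits(table, "nv_annotation"))
  table$descriptions <- descriptions
  table
}

#' Merge two annotation tables (e.g. a pathway GMT and a GO GMT)
#'
#' @param a,b `nv_annotation` objects with disjoint term ids.
#' @return A combined `nv_annotation`.
#' @export
merge_annotations <- function(a, b) {
  stopifnot(inherits(a, "nv_annotation"), inherits(b, "nv_annotation"))
  if (length(intersect(a$terms$term_id, b$terms$term_id))) {
    nv_abort("annotation tables share term ids; cannot merge",
             "nv_conflict_error")
  }
  desc <- c(a$descriptions, b$descriptions)
  annotation_table(rbind(a$terms, b$terms),
                   c(a$term_genes, b$term_genes),
                   desc[!duplicated(names(desc))])
}

#' Search terms by keyword
#'
#' Case-insensitive substring match (or regular expression with
#' `regex = TRUE`) against term names and term ids, optionally restricted
#' to a category; ordering is stable, by term id.
#'
#' @param table an `nv_annotation`.
#' @param keyword non-empty search string.
#' @param category optional category filter (`"PATHWAY"`, `"GO_BP"`, ...).
#' @param regex interpret `keyword` as a regular expression.
#' @return The matching rows of `table$terms` (possibly zero rows).
#' @export
search_terms <- function(table, keyword, category = NULL, regex = FALSE) {
  stopifnot(inherits(table, "nv_annotation"))
  if (!is_string(keyword) || !nzchar(keyword)) {
    nv_abort("keyword must be a non-empty string", "nv_value_error")
  }
  t <- table$terms
  if (regex) {
    hit <- grepl(keyword, t$term_name, ignore.case = TRUE) |
      grepl(keyword, t$term_id, ignore.case = TRUE)
  } else { # literal substring; fold case manually (fixed ignores ignore.case)
    kw <- tolower(keyword)
    hit <- grepl(kw, tolower(t$term_name), fixed = TRUE) |
      grepl(kw, tolower(t$term_id), fixed = TRUE)
  }
  if (!is.null(category)) hit <- hit & t$category %in% category
  out <- t[hit, , drop = FALSE]
  out[order(out$term_id), , drop = FALSE]
}

#' Genes annotated to a term
#'
#' @param table an `nv_annotation`.
#' @param term_id term identifier; must exist in the table.
#' @return Character vector of gene ids (possibly empty); a copy, never a
#'   reference into the store.
#' @export
genes_for_term <- function(table, term_id) {
  stopifnot(inherits(table, "nv_annotation"))
  if (!(term_id %in% table$terms$term_id)) {
    nv_abort(sprintf("unknown term id '%s'", term_id), "nv_notfound_error")
  }
  as.character(table$term_genes[[term_id]] %||% character())
}

#' Description and terms for one gene
#'
#' Genes without annotation are legal: they yield an empty description and
#' an empty term table.
#'
#' @param table an `nv_annotation`.
#' @param gene_id gene identifier.
#' @return A list with `description` (string, `""` if unknown) and `terms`
#'   (data.frame of the gene's terms, zero rows if none).
#' @export
annotate_gene <- function(table, gene_id) {
  stopifnot(inherits(table, "nv_annotation"))
  tids <- table$gene_terms[[gene_id]] %||% character()
  d <- table$descriptions[gene_id]
  d <- if (length(d) == 1L && !is.na(d)) unname(d) else ""
  list(description = d,
       terms = table$terms[table$terms$term_id %in% tids, , drop = FALSE])
}

#' @export
print.nv_annotation <- function(x, ...) {
  cat(sprintf("<annotation table: %d terms (%s), %d annotated genes, %d descriptions>\n",
              nrow(x$terms),
              paste(sprintf("%s:%d", names(table(x$terms$category)),
                            as.integer(table(x$terms$category))),
                    collapse = ", "),
              length(x$gene_terms), length(x$descriptions)))
  invisible(x)
}
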