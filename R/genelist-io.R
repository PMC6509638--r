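## Reading and validating two-column gene lists.
##
## Input contract: plain UTF-8 TSV, one gene per line, column 1 = gene id,
## column 2 = regulation code "1" (upregulated) or "2" (downregulated).
## Blank lines and lines starting with "#" are ignored.  A single header
## line is tolerated only when its second field is not "1"/"2".

#' Parse a two-column gene list from text lines
#'
#' Each non-blank, non-comment line must contain exactly two tab-separated
#' fields: a gene identifier and a regulation code, `"1"` for upregulated or
#' `"2"` for downregulated (relative to whatever fold-change cutoff the user
#' applied upstream; this package never calls differential expression).
#'
#' Gene ids are stripped of surrounding whitespace; case is preserved unless
#' `case_insensitive = TRUE`, which folds ids to upper case (gene-id
#' namespaces such as AGI or UniProt are case-meaningful, so folding is
#' opt-in).  A duplicated id with the same code is silently deduplicated
#' (with a warning); a duplicated id with conflicting codes is an error,
#' because a silent overwrite would corrupt the up/down/discordant
#' classification downstream.
#'
#' @param lines character vector of raw lines (as from [readLines()]).
#' @param name experiment name; non-empty, unique within a collection.
#' @param case_insensitive fold gene ids to upper case at parse time.
#' @return An object of class `nv_genelist`: a list with elements `name`
#'   (string) and `records` (data.frame with columns `gene_id`, `direction`).
#' @seealso [read_gene_list()], [read_gene_collection()], [write_gene_list()]
#' @export
#' @examples
#' gl <- parse_gene_list(c("AT1G79230\t1", "AT5G28030\t2"), name = "WT")
#' gl$records
parse_gene_list <- function(lines, name, case_insensitive = FALSE) {
  if (!is_string(name) || !nzchar(name)) {
    nv_abort("experiment name must be a non-empty string", "nv_value_error")
  }
  lineno <- seq_along(lines)
  keep <- !grepl("^[ \t]*$", lines) & !startsWith(trim_ws(lines), "#")
  lines <- sub("\r$", "", lines[keep])
  lineno <- lineno[keep]

  if (length(lines) == 0L) {
    nv_abort(sprintf("gene list '%s' contains no data lines", name),
             "nv_empty_error")
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)

  # header auto-detection: only the first data-candidate line, and only when
  # its second field is not a valid code (otherwise it is data)
  if (nf[1L] >= 2L && !(trim_ws(fields[[1L]][2L]) %in% c("1", "2"))) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
    nf <- nf[-1L]
    if (length(fields) == 0L) {
      nv_abort(sprintf("gene list '%s' contains a header but no data", name),
               "nv_empty_error")
    }
  }

  bad <- which(nf != 2L)
  if (length(bad)) {
    nv_abort(sprintf(
      "gene list '%s': line %d has %d tab-separated field(s), expected 2",
      name, lineno[bad[1L]], nf[bad[1L]]
    ), "nv_parse_error")
  }

  gene_id <- trim_ws(vapply(fields, `[[`, "", 1L))
  code <- trim_ws(vapply(fields, `[[`, "", 2L))
  if (case_insensitive) gene_id <- toupper(gene_id)

  empty <- which(!nzchar(gene_id))
  if (length(empty)) {
    nv_abort(sprintf("gene list '%s': line %d has an empty gene id",
                     name, lineno[empty[1L]]), "nv_parse_error")
  }
  badcode <- which(!(code %in% c("1", "2")))
  if (length(badcode)) {
    i <- badcode[1L]
    nv_abort(sprintf(
      "gene list '%s': line %d has regulation code '%s'; must be \"1\" (up) or \"2\" (down)",
      name, lineno[i], code[i]
    ), "nv_value_error")
  }
  direction <- as.integer(code)

  # conflicting duplicates are an error; identical duplicates collapse
  tab <- tapply(direction, gene_id, function(d) length(unique(d)))
  conflicted <- names(tab)[tab > 1L]
  if (length(conflicted)) {
    nv_abort(sprintf(
      "gene list '%s': gene '%s' appears with both codes 1 and 2",
      name, conflicted[1L]
    ), "nv_conflict_error")
  }
  dup <- duplicated(gene_id)
  if (any(dup)) {
    nv_warn(sprintf("gene list '%s': %d duplicate line(s) deduplicated",
                    name, sum(dup)), "nv_dedup_warning")
    gene_id <- gene_id[!dup]
    direction <- direction[!dup]
  }

  structure(
    list(name = name,
         records = data.frame(gene_id = gene_id, direction = direction,
                              stringsAsFactors = FALSE, row.names = NULL)),
    class = "nv_genelist"
  )
}

#' Read a gene list from a two-column TSV file
#'
#' @param path file path (UTF-8 text, LF or CRLF line endings).
#' @param name experiment name; defaults to the file name without extension.
#' @inheritParams parse_gene_list
#' @return An `nv_genelist`; see [parse_gene_list()].
#' @export
read_gene_list <- function(path, name = NULL, case_insensitive = FALSE) {
  if (!file.exists(path)) {
    nv_abort(sprintf("gene list file not found: %s", path), "nv_io_error")
  }
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  parse_gene_list(readLines(path, encoding = "UTF-8", warn = FALSE),
                  name = name, case_insensitive = case_insensitive)
}

#' Write a gene list back to two-column TSV
#'
#' Inverse of [parse_gene_list()]: writing then re-reading yields an equal
#' list, and a second write is byte-identical (LF line endings, no header).
#'
#' @param x an `nv_genelist`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(x, path) {
  stopifnot(inherits(x, "nv_genelist"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d", x$records$gene_id, x$records$direction),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Assemble 2-8 gene lists into a validated collection
#'
#' The tool compares at least two and at most eight experiments (a hard
#' limit).  Input order is meaningful: it fixes the experiment display order
#' and the automatic palette color assigned to each experiment node.
#'
#' @param lists a list of `nv_genelist` objects.
#' @return An object of class `nv_collection` (a named list of
#'   `nv_genelist`, in input order).
#' @export
as_gene_collection <- function(lists) {
  if (!is.list(lists) || !all(vapply(lists, inherits, TRUE, "nv_genelist"))) {
    nv_abort("'lists' must be a list of nv_genelist objects", "nv_value_error")
  }
  n <- length(lists)
  if (n < 2L) {
    nv_abort("at least two gene lists are required", "nv_toofew_error")
  }
  if (n > 8L) {
    nv_abort(sprintf("at most eight gene lists are supported; got %d", n),
             "nv_toomany_error")
  }
  names_ <- vapply(lists, `[[`, "", "name")
  if (anyDuplicated(names_)) {
    nv_abort(sprintf("duplicate experiment name: '%s'",
                     names_[duplicated(names_)][1L]), "nv_namecollision_error")
  }
  names(lists) <- names_
  structure(lists, class = "nv_collection")
}

#' Read a collection of gene-list files
#'
#' @param paths character vector of 2-8 file paths.
#' @param names experiment names, same length as `paths`; defaults to file
#'   names without extension.
#' @inheritParams parse_gene_list
#' @return An `nv_collection`; see [as_gene_collection()].
#' @export
read_gene_collection <- function(paths, names = NULL,
                                 case_insensitive = FALSE) {
  names <- names %||% sub("\\.[^.]*$", "", basename(paths))
  if (length(names) != length(paths)) {
    nv_abort("'names' must match 'paths' in length", "nv_value_error")
  }
  as_gene_collection(Map(function(p, nm) {
    read_gene_list(p, name = nm, case_insensitive = case_insensitive)
  }, paths, names))
}

#' @export
print.nv_genelist <- function(x, ...) {
  cat(sprintf("<gene list '%s': %d genes (%d up, %d down)>\n",
              x$name, nrow(x$records),
              sum(x$records$direction == 1L),
              sum(x$records$direction == 2L)))
  invisible(x)
}

#' @export
print.nv_collection <- function(x, ...) {
  cat(sprintf("<collection of %d experiments: %s>\n",
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}
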