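## Venn-region decomposition and per-gene regulation classification.
##
## The graph generalizes the Venn diagram: the "region" of a gene is the
## exact set of experiments that contain it, and its direction class says
## whether its codes agree (all up, all down) or disagree (discordant).

#' Build the gene membership map for a collection
#'
#' For every gene appearing in any list, records which experiments contain
#' it and with which direction code.  This is the substrate both for the
#' Venn-region decomposition and for the graph.
#'
#' @param collection an `nv_collection` from [as_gene_collection()].
#' @return An object of class `nv_membership`: a list with `tab` (long
#'   data.frame: `gene_id`, `experiment`, `direction`) and `experiments`
#'   (character vector in input order).
#' @export
build_membership <- function(collection) {
  stopifnot(inherits(collection, "nv_collection"))
  tab <- do.call(rbind, lapply(collection, function(gl) {
    data.frame(gene_id = gl$records$gene_id,
               experiment = gl$name,
               direction = gl$records$direction,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(tab = tab, experiments = names(collection)),
            class = "nv_membership")
}

#' Extract one gene's membership profile
#'
#' @param membership an `nv_membership`.
#' @param gene_id gene identifier.
#' @return Named integer vector: direction code per containing experiment
#'   (names in experiment input order).  Error if the gene is absent.
#' @export
membership_profile <- function(membership, gene_id) {
  stopifnot(inherits(membership, "nv_membership"))
  rows <- membership$tab[membership$tab$gene_id == gene_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    nv_abort(sprintf("gene '%s' not found in any experiment", gene_id),
             "nv_notfound_error")
  }
  ord <- order(match(rows$experiment, membership$experiments))
  stats::setNames(rows$direction[ord], rows$experiment[ord])
}

#' Classify a membership profile as UP, DOWN or DISCORDANT
#'
#' `UP` when every containing experiment reports code 1, `DOWN` when every
#' one reports code 2, `DISCORDANT` when both codes occur (up in at least
#' one experiment and down in at least one other).  These map to the red,
#' blue and yellow gene-node colors of the graph.
#'
#' @param profile integer vector of direction codes (1/2), e.g. from
#'   [membership_profile()].
#' @return One of `"UP"`, `"DOWN"`, `"DISCORDANT"`.
#' @export
#' @examples
#' classify_direction(c(A = 1, B = 1)) # "UP"
#' classify_direction(c(A = 1, B = 2)) # "DISCORDANT"
classify_direction <- function(profile) {
  codes <- unique(as.integer(profile))
  if (length(codes) == 0L || !all(codes %in% c(1L, 2L))) {
    nv_abort("profile codes must be 1 or 2", "nv_value_error")
  }
  if (length(codes) == 2L) "DISCORDANT" else if (codes == 1L) "UP" else "DOWN"
}

# vectorized classification for all genes in a membership; named character
direction_classes <- function(membership) {
  tab <- membership$tab
  has_up <- tapply(tab$direction == 1L, tab$gene_id, any)
  has_down <- tapply(tab$direction == 2L, tab$gene_id, any)
  cls <- ifelse(has_up & has_down, "DISCORDANT",
                ifelse(has_up, "UP", "DOWN"))
  stats::setNames(as.character(cls), names(has_up))
}

#' Decompose a collection into Venn regions
#'
#' A region is the set of genes whose containing-experiment signature is
#' exactly a given subset of the inputs ("A∩B only" in Venn terms).  Regions
#' partition the gene universe; signatures realized by no gene are omitted.
#'
#' @param membership an `nv_membership` from [build_membership()].
#' @return A data.frame of class `nv_regions`, ordered by signature
#'   cardinality (descending) then lexicographically by signature string,
#'   with columns: `signature` (experiment names joined by `"+"`, in input
#'   order), `n_genes`, `n_up`, `n_down`, `n_discordant`, and list-column
#'   `genes` (sorted gene ids).
#' @export
venn_regions <- function(membership) {
  stopifnot(inherits(membership, "nv_membership"))
  tab <- membership$tab
  if (nrow(tab) == 0L) nv_abort("empty membership", "nv_empty_error")
  exps <- membership$experiments

  ord <- order(tab$gene_id, match(tab$experiment, exps))
  tab <- tab[ord, , drop = FALSE]
  sig_by_gene <- tapply(tab$experiment, tab$gene_id,
                        function(e) paste(e, collapse = "+"))
  cls <- direction_classes(membership)

  genes <- names(sig_by_gene)
  sig <- as.character(sig_by_gene)
  split_genes <- split(genes, sig)
  card <- vapply(strsplit(names(split_genes), "+", fixed = TRUE), length, 1L)
  o <- order(-card, names(split_genes), method = "radix")
  split_genes <- split_genes[o]

  res <- data.frame(
    signature = names(split_genes),
    n_genes = vapply(split_genes, length, 1L),
    n_up = vapply(split_genes, function(g) sum(cls[g] == "UP"), 1L),
    n_down = vapply(split_genes, function(g) sum(cls[g] == "DOWN"), 1L),
    n_discordant = vapply(split_genes,
                          function(g) sum(cls[g] == "DISCORDANT"), 1L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$genes <- lapply(split_genes, function(g) sort(unname(g)))
  class(res) <- c("nv_regions", "data.frame")
  res
}

#' Write the region table as TSV
#'
#' One row per realized region: signature, size, direction breakdown, and
#' the member gene ids joined by `";"`.
#'
#' @param regions an `nv_regions` from [venn_regions()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "nv_regions"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- "signature\tn_genes\tn_up\tn_down\tn_discordant\tgenes"
  body <- sprintf("%s\t%d\t%d\t%d\t%d\t%s",
                  regions$signature, regions$n_genes, regions$n_up,
                  regions$n_down, regions$n_discordant,
                  vapply(regions$genes, paste, "", collapse = ";"))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
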