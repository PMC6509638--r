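## Synthetic fixtures with known ground truth: gene-list collections whose
## Venn-region sizes are exact by construction, direction codes drawn
## independently per experiment, and annotation tables with one planted
## over-represented term among uniform null terms.  Everything is
## reproducible from a single integer seed.

# parse a signature like "A+B" into its experiment names
split_signature <- function(sig) strsplit(sig, "+", fixed = TRUE)

#' Simulate a gene-list collection with exact region sizes
#'
#' Gene ids `"SG000001"`, ... are distributed over the requested Venn
#' regions exactly; each (gene, experiment) membership then receives an
#' independent Bernoulli(`p_up`) draw for its direction code (1 with
#' probability `p_up`, else 2).  A gene shared by two experiments is
#' therefore discordant with probability `2 p_up (1 - p_up)`.
#'
#' This emulates the shape of multi-genotype differential-expression
#' comparisons (shared and private DE genes, partially concordant
#' regulation); it does not model fold-change magnitudes, gene-gene
#' correlation, or annotation structure beyond flat gene sets.
#'
#' @param region_sizes named integer vector; names are region signatures
#'   with experiment names joined by `"+"` (e.g.
#'   `c(A = 10, B = 10, "A+B" = 5)`).
#' @param p_up probability that a membership code is 1 (up), per
#'   experiment, independently.
#' @param seed integer seed; same seed, same fixture, byte-identical files.
#' @param experiments optional explicit experiment order; defaults to the
#'   order of first appearance in `names(region_sizes)`.
#' @return A list with `collection` (an `nv_collection`) and `truth`
#'   (list: `regions` = named list signature -> gene ids, `codes` = long
#'   data.frame of every membership's direction).
#' @export
simulate_collection <- function(region_sizes, p_up = 0.5, seed = 1L,
                                experiments = NULL) {
  if (is.null(names(region_sizes)) || any(!nzchar(names(region_sizes)))) {
    nv_abort("region_sizes must be named by signature (e.g. 'A+B')",
             "nv_value_error")
  }
  if (anyDuplicated(names(region_sizes))) {
    nv_abort("duplicate region signature in region_sizes", "nv_value_error")
  }
  if (any(region_sizes < 0) || sum(region_sizes) < 1) {
    nv_abort("region sizes must be non-negative and sum to at least 1",
             "nv_value_error")
  }
  if (!is.numeric(p_up) || p_up < 0 || p_up > 1) {
    nv_abort("p_up must lie in [0, 1]", "nv_value_error")
  }
  sigs <- split_signature(names(region_sizes))
  experiments <- experiments %||% unique(unlist(sigs))
  if (length(experiments) < 2L || length(experiments) > 8L) {
    nv_abort("fixtures need 2-8 experiments", "nv_value_error")
  }
  if (!all(unlist(sigs) %in% experiments)) {
    nv_abort("signature names an unknown experiment", "nv_value_error")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  total <- sum(region_sizes)
  gene_ids <- sprintf("SG%06d", seq_len(total))
  region_of <- rep(seq_along(region_sizes), region_sizes)
  regions <- split(gene_ids, names(region_sizes)[region_of])
  regions <- regions[names(region_sizes)[region_sizes > 0]] # original order

  # every membership gets its own independent code draw
  codes <- do.call(rbind, lapply(seq_along(regions), function(i) {
    sig <- split_signature(names(regions)[i])[[1L]]
    g <- regions[[i]]
    expand <- expand.grid(gene_id = g, experiment = sig,
                          stringsAsFactors = FALSE)
    expand
  }))
  codes$direction <- ifelse(stats::runif(nrow(codes)) < p_up, 1L, 2L)

  lists <- lapply(experiments, function(e) {
    rows <- codes[codes$experiment == e, , drop = FALSE]
    if (nrow(rows) == 0L) {
      nv_abort(sprintf("experiment '%s' receives no genes under region_sizes",
                       e), "nv_value_error")
    }
    rows <- rows[order(rows$gene_id), , drop = FALSE]
    structure(list(name = e,
                   records = data.frame(gene_id = rows$gene_id,
                                        direction = rows$direction,
                                        stringsAsFactors = FALSE,
                                        row.names = NULL)),
              class = "nv_genelist")
  })
  list(collection = as_gene_collection(lists),
       truth = list(regions = regions, codes = codes, p_up = p_up,
                    seed = as.integer(seed)))
}

#' Simulate an annotation table with an optional planted enriched term
#'
#' The planted term takes `k_star` genes from the target region plus
#' `K - k_star` filler genes from the rest of the universe, so its overlap
#' with the region is exact by construction.  Null terms sample their genes
#' uniformly from the whole universe, independent of region structure.
#' The universe is the collection's genes padded with background ids
#' (`"BG000001"`, ...) up to `universe_size`.
#'
#' Defaults (universe 2,000; K = 40; k* = 25; 100 null terms of size 40)
#' give a planted-term signal far below p = 0.05 against a 100-gene
#' selection while null terms stay at the nominal level.
#'
#' @param truth the `truth` element returned by [simulate_collection()].
#' @param target_signature region signature the planted term is enriched
#'   in; `NULL` plants nothing (null-only table, for type-I calibration).
#' @param K planted term size.
#' @param k_star planted overlap with the target region.
#' @param n_null number of null terms.
#' @param null_size integer vector of candidate null-term sizes (sampled
#'   uniformly per term).
#' @param universe_size total gene universe (>= genes in the collection).
#' @param category annotation category for all simulated terms.
#' @param seed integer seed.
#' @return A list with `annotation` (an `nv_annotation`), `universe`
#'   (character vector) and `truth` (list: `planted` term id or `NULL`,
#'   `target_signature`, `k_star`).
#' @export
simulate_annotations <- function(truth, target_signature = NULL,
                                 K = 40L, k_star = 25L,
                                 n_null = 100L, null_size = 40L,
                                 universe_size = 2000L,
                                 category = "GO_BP", seed = 1L) {
  collection_genes <- sort(unique(unlist(truth$regions, use.names = FALSE)))
  if (universe_size < length(collection_genes)) {
    nv_abort("universe_size smaller than the collection's gene universe",
             "nv_value_error")
  }
  universe <- c(collection_genes,
                sprintf("BG%06d", seq_len(universe_size - length(collection_genes))))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  term_genes <- list()
  term_ids <- character()
  planted_id <- NULL
  if (!is.null(target_signature)) {
    region <- truth$regions[[target_signature]]
    if (is.null(region)) {
      nv_abort(sprintf("target signature '%s' not realized in the collection",
                       target_signature), "nv_value_error")
    }
    if (k_star > min(length(region), K)) {
      nv_abort("k_star exceeds min(region size, K); planted term infeasible",
               "nv_value_error")
    }
    outside <- setdiff(universe, region)
    if (K - k_star > length(outside)) {
      nv_abort("not enough genes outside the region to pad the planted term",
               "nv_value_error")
    }
    planted_id <- "SIM:PLANTED"
    term_genes[[planted_id]] <- c(sample(region, k_star),
                                  sample(outside, K - k_star))
    term_ids <- planted_id
  }
  if (n_null > 0L) {
    null_ids <- sprintf("SIM:N%04d", seq_len(n_null))
    sizes <- if (length(null_size) == 1L) rep(null_size, n_null)
             else sample(null_size, n_null, replace = TRUE)
    for (i in seq_len(n_null)) {
      term_genes[[null_ids[i]]] <- sample(universe, sizes[i])
    }
    term_ids <- c(term_ids, null_ids)
  }
  if (length(term_ids) == 0L) {
    nv_abort("nothing to simulate: no planted term and n_null = 0",
             "nv_value_error")
  }
  terms <- data.frame(
    term_id = term_ids,
    term_name = ifelse(term_ids == "SIM:PLANTED",
                       "planted enriched term",
                       sub("SIM:", "null term ", term_ids)),
    category = category, stringsAsFactors = FALSE)
  list(annotation = annotation_table(terms, term_genes),
       universe = universe,
       truth = list(planted = planted_id,
                    target_signature = target_signature,
                    k_star = if (is.null(planted_id)) NULL else as.integer(k_star),
                    seed = as.integer(seed)))
}

#' Write a simulated collection to per-experiment TSV files
#'
#' @param collection an `nv_collection`.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "nv_collection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(collection, function(gl) {
    p <- file.path(dir, paste0(gl$name, ".tsv"))
    write_gene_list(gl, p)
    p
  }, "")
  paths
}
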