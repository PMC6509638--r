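## The experiment-gene graph: one hub node per experiment, one node per
## distinct gene, one edge per (experiment, gene) membership carrying the
## direction code.  Gene nodes are colored by their cross-experiment
## regulation class (red = up everywhere, blue = down everywhere, yellow =
## discordant); experiment nodes take a fixed palette color by input order.

#' Build the experiment-gene graph
#'
#' @param collection an `nv_collection`.
#' @param membership optional `nv_membership`; computed from `collection`
#'   when omitted.
#' @param seed layout seed stored with the model (defaults to 42; every
#'   downstream layout of this model is deterministic given it).
#' @return An object of class `nv_graph`: list with `nodes` (data.frame:
#'   `id`, `kind`, `color_class`, `shape`, `label`), `edges` (data.frame:
#'   `experiment`, `gene`, `direction`) and `seed`.  `color_class` is the
#'   palette index (as character) for experiment nodes and one of
#'   `"UP"`/`"DOWN"`/`"DISCORDANT"` for gene nodes.
#' @export
build_graph <- function(collection, membership = NULL, seed = DEFAULT_SEED) {
  stopifnot(inherits(collection, "nv_collection"))
  membership <- membership %||% build_membership(collection)
  stopifnot(inherits(membership, "nv_membership"))

  exps <- membership$experiments
  cls <- direction_classes(membership)
  gene_ids <- membership$tab$gene_id[!duplicated(membership$tab$gene_id)]
  clash <- intersect(exps, gene_ids)
  if (length(clash)) {
    nv_abort(sprintf("gene id '%s' collides with an experiment name; rename the experiment",
                     clash[1L]), "nv_namecollision_error")
  }

  nodes <- data.frame(
    id = c(exps, gene_ids),
    kind = c(rep("EXPERIMENT", length(exps)), rep("GENE", length(gene_ids))),
    color_class = c(as.character(seq_along(exps)), unname(cls[gene_ids])),
    shape = c(rep("circle", length(exps) + length(gene_ids))),
    label = c(exps, gene_ids),
    stringsAsFactors = FALSE, row.names = NULL
  )
  edges <- data.frame(experiment = membership$tab$experiment,
                      gene = membership$tab$gene_id,
                      direction = membership$tab$direction,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = edges, seed = as.integer(seed)),
            class = "nv_graph")
}

#' @export
print.nv_graph <- function(x, ...) {
  cat(sprintf("<graph: %d experiments, %d genes, %d edges (seed %d)>\n",
              sum(x$nodes$kind == "EXPERIMENT"),
              sum(x$nodes$kind == "GENE"), nrow(x$edges), x$seed))
  invisible(x)
}

#' Compute a seeded force-directed layout
#'
#' Fruchterman-Reingold spring embedding via [igraph::layout_with_fr()],
#' made deterministic by seeding the RNG: identical (model, iterations,
#' seed) yields bit-identical coordinates.  With `pin_experiments = TRUE`
#' the experiment hubs are fixed on a circle, which stabilizes very large
#' graphs at the cost of a less organic arrangement.
#'
#' @param model an `nv_graph`.
#' @param iterations number of embedding iterations (>= 1).
#' @param seed integer RNG seed; defaults to the model's stored seed.
#' @param pin_experiments fix experiment nodes on a circle.
#' @return An object of class `nv_layout`: list with `positions`
#'   (data.frame `node_id`, `x`, `y`) and `bounds`
#'   (`c(xmin, xmax, ymin, ymax)`).
#' @export
layout_graph <- function(model, iterations = 500L, seed = NULL,
                         pin_experiments = FALSE) {
  stopifnot(inherits(model, "nv_graph"))
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 1) {
    nv_abort("iterations must be a positive integer", "nv_value_error")
  }
  seed <- as.integer(seed %||% model$seed)
  ids <- model$nodes$id
  if (length(ids) == 0L) nv_abort("empty graph model", "nv_empty_error")

  if (length(ids) == 1L) {
    pos <- data.frame(node_id = ids, x = 0, y = 0, stringsAsFactors = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = model$edges$experiment, to = model$edges$gene,
                 stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = ids, stringsAsFactors = FALSE)
    )
    args <- list(g, niter = as.integer(iterations))
    if (pin_experiments) {
      is_exp <- model$nodes$kind == "EXPERIMENT"
      n_exp <- sum(is_exp)
      theta <- 2 * pi * (seq_len(n_exp) - 1L) / max(n_exp, 1L)
      r <- sqrt(length(ids)) # hub circle radius grows with graph size
      minx <- rep(-Inf, length(ids)); maxx <- rep(Inf, length(ids))
      miny <- rep(-Inf, length(ids)); maxy <- rep(Inf, length(ids))
      minx[is_exp] <- maxx[is_exp] <- r * cos(theta)
      miny[is_exp] <- maxy[is_exp] <- r * sin(theta)
      args <- c(args, list(minx = minx, maxx = maxx, miny = miny, maxy = maxy))
    }
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    xy <- do.call(igraph::layout_with_fr, args)
    pos <- data.frame(node_id = ids, x = xy[, 1L], y = xy[, 2L],
                      stringsAsFactors = FALSE)
  }
  if (!all(is.finite(pos$x)) || !all(is.finite(pos$y))) {
    nv_abort("layout produced non-finite coordinates", "nv_value_error")
  }
  structure(list(positions = pos,
                 bounds = c(xmin = min(pos$x), xmax = max(pos$x),
                            ymin = min(pos$y), ymax = max(pos$y))),
            class = "nv_layout")
}

# save/restore the global RNG state so layouts do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Restrict the graph to a gene subset
#'
#' Keeps the genes of `gene_subset` present in the model (e.g. the genes of
#' one pathway or GO term), their edges, and every experiment node that
#' retains at least one edge; experiment hubs left without edges are
#' dropped with a message.  Colors and directions are preserved.
#'
#' @param model an `nv_graph`.
#' @param gene_subset character vector of gene ids.
#' @return A new `nv_graph` (the induced subgraph).
#' @export
subset_graph <- function(model, gene_subset) {
  stopifnot(inherits(model, "nv_graph"))
  genes <- model$nodes$id[model$nodes$kind == "GENE"]
  keep_genes <- intersect(genes, unique(as.character(gene_subset)))
  if (length(keep_genes) == 0L) {
    nv_abort("gene subset has empty intersection with the graph",
             "nv_emptysubset_error")
  }
  edges <- model$edges[model$edges$gene %in% keep_genes, , drop = FALSE]
  keep_exps <- unique(edges$experiment)
  dropped <- setdiff(model$nodes$id[model$nodes$kind == "EXPERIMENT"],
                     keep_exps)
  if (length(dropped)) {
    message(sprintf("subset_graph: dropped %d experiment node(s) with no remaining edges: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  keep <- (model$nodes$kind == "GENE" & model$nodes$id %in% keep_genes) |
    (model$nodes$kind == "EXPERIMENT" & model$nodes$id %in% keep_exps)
  nodes <- model$nodes[keep, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, seed = model$seed),
            class = "nv_graph")
}

#' Highlight genes of interest as square nodes
#'
#' Re-draws the listed genes with square markers, leaving everything else
#' untouched; idempotent.  Unknown gene ids are ignored with a warning.
#'
#' @param model an `nv_graph`.
#' @param gene_subset character vector of gene ids (may be empty).
#' @return The modified `nv_graph`.
#' @export
highlight_genes <- function(model, gene_subset) {
  stopifnot(inherits(model, "nv_graph"))
  gene_subset <- unique(as.character(gene_subset))
  if (length(gene_subset) == 0L) return(model)
  known <- model$nodes$id[model$nodes$kind == "GENE"]
  unknown <- setdiff(gene_subset, known)
  if (length(unknown)) {
    nv_warn(sprintf("highlight_genes: %d gene id(s) not in the graph were ignored",
                    length(unknown)), "nv_unknown_warning")
  }
  hit <- model$nodes$kind == "GENE" & model$nodes$id %in% gene_subset
  model$nodes$shape[hit] <- "square"
  model
}

## Graph JSON document ------------------------------------------------------
## {"nodes":[{"id","kind","color","shape","label"}],
##  "links":[{"source","target","direction"}], "seed":int}

#' Serialize a graph model to its JSON document
#'
#' @param model an `nv_graph`.
#' @param path output path.
#' @return `path`, invisibly.  Output is deterministic: the same model
#'   always writes byte-identical JSON.
#' @export
write_graph_json <- function(model, path) {
  stopifnot(inherits(model, "nv_graph"))
  doc <- list(
    nodes = data.frame(id = model$nodes$id, kind = model$nodes$kind,
                       color = model$nodes$color_class,
                       shape = model$nodes$shape,
                       label = model$nodes$label,
                       stringsAsFactors = FALSE),
    links = data.frame(source = model$edges$experiment,
                       target = model$edges$gene,
                       direction = model$edges$direction,
                       stringsAsFactors = FALSE),
    seed = jsonlite::unbox(model$seed)
  )
  json <- jsonlite::toJSON(doc, dataframe = "rows", pretty = 2L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a graph model back from its JSON document
#'
#' Inverse of [write_graph_json()]; write -> read -> write is
#' byte-identical.
#'
#' @param path JSON file.
#' @return An `nv_graph`.
#' @export
read_graph_json <- function(path) {
  if (!file.exists(path)) {
    nv_abort(sprintf("graph JSON not found: %s", path), "nv_io_error")
  }
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  nodes <- doc$nodes
  nodes <- data.frame(id = as.character(nodes$id),
                      kind = as.character(nodes$kind),
                      color_class = as.character(nodes$color),
                      shape = as.character(nodes$shape),
                      label = as.character(nodes$label),
                      stringsAsFactors = FALSE)
  links <- doc$links
  if (is.null(links) || length(links) == 0L || NROW(links) == 0L) {
    edges <- data.frame(experiment = character(), gene = character(),
                        direction = integer(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(experiment = as.character(links$source),
                        gene = as.character(links$target),
                        direction = as.integer(links$direction),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, seed = as.integer(doc$seed)),
            class = "nv_graph")
}
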