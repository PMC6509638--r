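## Figure and table export.  The SVG writer is a fixed-format serializer:
## stable element order (edges beneath nodes, nodes in model order) and
## fixed numeric formatting, so identical inputs give byte-identical files.
## PNG draws the same scene on a raster device at the requested dpi.

#' Style configuration for rendering
#'
#' @param node_radius named numeric: marker radius in px for `experiment`
#'   and `gene` nodes.
#' @param edge_width edge stroke width in px.
#' @param palette 8 hex colors for experiment nodes (input order).
#' @param gene_colors named hex colors for `UP`, `DOWN`, `DISCORDANT`.
#' @param edge_colors named hex colors for direction codes `"1"` and `"2"`.
#' @param font_family,font_size label font.
#' @param canvas `c(width, height)` in px (at the nominal 72 dpi).
#' @param margin canvas margin in px kept clear of node centers.
#' @param background canvas background color.
#' @return A list of class `nv_style`.
#' @export
nv_style <- function(node_radius = c(experiment = 14, gene = 5),
                     edge_width = 1,
                     palette = EXPERIMENT_PALETTE,
                     gene_colors = GENE_COLORS,
                     edge_colors = EDGE_COLORS,
                     font_family = "Helvetica",
                     font_size = 11,
                     canvas = c(width = 800, height = 600),
                     margin = 40,
                     background = "#FFFFFF") {
  hexes <- c(palette, gene_colors, edge_colors, background)
  if (!all(grepl("^#[0-9A-Fa-f]{6}$", hexes))) {
    nv_abort("style colors must be 6-digit hex like #RRGGBB", "nv_value_error")
  }
  dims <- c(node_radius, edge_width, font_size, canvas, margin)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    nv_abort("style dimensions must be positive", "nv_value_error")
  }
  if (length(palette) != 8L) {
    nv_abort("palette must provide exactly 8 experiment colors",
             "nv_value_error")
  }
  structure(list(node_radius = node_radius, edge_width = edge_width,
                 palette = palette, gene_colors = gene_colors,
                 edge_colors = edge_colors, font_family = font_family,
                 font_size = font_size, canvas = canvas, margin = margin,
                 background = background),
            class = "nv_style")
}

# resolve each node's fill color from its class
node_fill <- function(model, style) {
  fill <- character(nrow(model$nodes))
  is_exp <- model$nodes$kind == "EXPERIMENT"
  fill[is_exp] <- style$palette[as.integer(model$nodes$color_class[is_exp])]
  fill[!is_exp] <- unname(style$gene_colors[model$nodes$color_class[!is_exp]])
  fill
}

# map layout coordinates into the canvas, margin respected; degenerate
# (single-point) extents land mid-canvas
scale_positions <- function(layout, style) {
  pos <- layout$positions
  w <- style$canvas[["width"]]; h <- style$canvas[["height"]]
  m <- style$margin
  rng <- function(v) {
    r <- range(v)
    if (diff(r) == 0) r + c(-0.5, 0.5) else r
  }
  rx <- rng(pos$x); ry <- rng(pos$y)
  data.frame(node_id = pos$node_id,
             x = m + (pos$x - rx[1L]) / diff(rx) * (w - 2 * m),
             y = m + (pos$y - ry[1L]) / diff(ry) * (h - 2 * m),
             stringsAsFactors = FALSE)
}

# decide which gene labels to draw
label_flags <- function(model, labels = c("auto", "on", "off"),
                        auto_threshold = 200L) {
  labels <- match.arg(labels)
  is_exp <- model$nodes$kind == "EXPERIMENT"
  show_genes <- switch(labels,
                       on = TRUE,
                       off = FALSE,
                       auto = sum(!is_exp) <= auto_threshold)
  is_exp | show_genes # experiment labels are always visible
}

#' Render the graph scene as a standalone SVG document
#'
#' Edges are drawn first (beneath nodes), colored by direction (up = red,
#' down = blue); nodes follow in model order as circles or squares filled
#' by their color class; labels last.  Identical (model, layout, style)
#' always produce byte-identical SVG text.
#'
#' @param model an `nv_graph`.
#' @param layout an `nv_layout` covering every model node.
#' @param style an `nv_style`.
#' @param labels `"auto"` (gene labels shown up to 200 gene nodes), `"on"`
#'   or `"off"`; experiment labels are always shown.
#' @return The SVG document as a single character string.
#' @export
render_svg <- function(model, layout, style = nv_style(),
                       labels = c("auto", "on", "off")) {
  stopifnot(inherits(model, "nv_graph"), inherits(layout, "nv_layout"),
            inherits(style, "nv_style"))
  missing <- setdiff(model$nodes$id, layout$positions$node_id)
  if (length(missing)) {
    nv_abort(sprintf("layout is missing %d node(s), e.g. '%s'",
                     length(missing), missing[1L]), "nv_consistency_error")
  }
  pos <- scale_positions(layout, style)
  xy <- pos[match(model$nodes$id, pos$node_id), , drop = FALSE]
  ex <- pos[match(model$edges$experiment, pos$node_id), , drop = FALSE]
  gx <- pos[match(model$edges$gene, pos$node_id), , drop = FALSE]

  fmt <- function(v) sprintf("%.2f", v)
  w <- style$canvas[["width"]]; h <- style$canvas[["height"]]

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            round(w), round(h), round(w), round(h)),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="%s"/>',
            round(w), round(h), style$background)
  )
  if (nrow(model$edges)) {
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s" class="edge"/>',
      fmt(ex$x), fmt(ex$y), fmt(gx$x), fmt(gx$y),
      unname(style$edge_colors[as.character(model$edges$direction)]),
      fmt(rep(style$edge_width, nrow(model$edges)))
    ))
  }
  fill <- node_fill(model, style)
  r <- ifelse(model$nodes$kind == "EXPERIMENT",
              style$node_radius[["experiment"]], style$node_radius[["gene"]])
  is_square <- model$nodes$shape == "square"
  shapes <- character(nrow(model$nodes))
  shapes[!is_square] <- sprintf(
    '<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="#333333" stroke-width="0.5" class="node"/>',
    fmt(xy$x[!is_square]), fmt(xy$y[!is_square]), fmt(r[!is_square]),
    fill[!is_square])
  shapes[is_square] <- sprintf(
    '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#333333" stroke-width="0.5" class="node"/>',
    fmt(xy$x[is_square] - r[is_square]), fmt(xy$y[is_square] - r[is_square]),
    fmt(2 * r[is_square]), fmt(2 * r[is_square]), fill[is_square])
  out <- c(out, shapes)

  show <- label_flags(model, labels)
  if (any(show)) {
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-family="%s" font-size="%s" fill="#222222">%s</text>',
      fmt(xy$x[show] + r[show] + 2), fmt(xy$y[show] + style$font_size / 3),
      style$font_family, fmt(rep(style$font_size, sum(show))),
      xml_escape(model$nodes$label[show])
    ))
  }
  paste0(paste(c(out, "</svg>"), collapse = "\n"), "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write the SVG document to a file
#'
#' @inheritParams render_svg
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(model, layout, path, style = nv_style(),
                      labels = c("auto", "on", "off")) {
  svg <- render_svg(model, layout, style, labels)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(svg, con, eos = NULL, useBytes = TRUE)
  invisible(path)
}

#' Render the graph scene as a PNG file
#'
#' Draws the same scene as [render_svg()] on a raster device.  Pixel
#' dimensions are `canvas * dpi / 72` (rounded), so a 600x400 canvas at
#' 300 dpi gives a 2500x1667 px image.
#'
#' @inheritParams render_svg
#' @param path output PNG path.
#' @param dpi resolution, at least 72.
#' @return `path`, invisibly.
#' @export
render_png <- function(model, layout, path, style = nv_style(), dpi = 150,
                       labels = c("auto", "on", "off")) {
  stopifnot(inherits(model, "nv_graph"), inherits(layout, "nv_layout"))
  if (!is.numeric(dpi) || length(dpi) != 1L || dpi < 72) {
    nv_abort("dpi must be at least 72", "nv_value_error")
  }
  missing <- setdiff(model$nodes$id, layout$positions$node_id)
  if (length(missing)) {
    nv_abort(sprintf("layout is missing %d node(s)", length(missing)),
             "nv_consistency_error")
  }
  w <- style$canvas[["width"]]; h <- style$canvas[["height"]]
  px_w <- round(w * dpi / 72); px_h <- round(h * dpi / 72)
  grDevices::png(path, width = px_w, height = px_h, res = dpi,
                 type = "cairo", bg = style$background)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  # y grows downward to match the SVG coordinate system
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, w), ylim = c(h, 0))

  pos <- scale_positions(layout, style)
  xy <- pos[match(model$nodes$id, pos$node_id), , drop = FALSE]
  if (nrow(model$edges)) {
    ex <- pos[match(model$edges$experiment, pos$node_id), , drop = FALSE]
    gx <- pos[match(model$edges$gene, pos$node_id), , drop = FALSE]
    graphics::segments(ex$x, ex$y, gx$x, gx$y,
                       col = unname(style$edge_colors[as.character(model$edges$direction)]),
                       lwd = style$edge_width)
  }
  fill <- node_fill(model, style)
  r <- ifelse(model$nodes$kind == "EXPERIMENT",
              style$node_radius[["experiment"]], style$node_radius[["gene"]])
  sq <- model$nodes$shape == "square"
  if (any(!sq)) {
    graphics::symbols(xy$x[!sq], xy$y[!sq], circles = r[!sq], inches = FALSE,
                      add = TRUE, bg = fill[!sq], fg = "#333333")
  }
  if (any(sq)) {
    graphics::rect(xy$x[sq] - r[sq], xy$y[sq] - r[sq],
                   xy$x[sq] + r[sq], xy$y[sq] + r[sq],
                   col = fill[sq], border = "#333333")
  }
  show <- label_flags(model, labels)
  if (any(show)) {
    graphics::text(xy$x[show] + r[show] + 2, xy$y[show],
                   labels = model$nodes$label[show], adj = c(0, 0.5),
                   cex = style$font_size / 12)
  }
  invisible(path)
}

#' Build the gene-information table
#'
#' One row per gene node, sorted by gene id, with the per-experiment
#' direction codes printed as `"1"`/`"2"` (blank when the gene is absent
#' from an experiment), the cross-experiment direction class, the gene
#' description, the gene's pathway and GO terms (semicolon-joined
#' `id:name`), and, when an enrichment result is attached, the raw
#' p-values of those terms (semicolon-joined `id=p`).
#'
#' @param model an `nv_graph`.
#' @param annotation optional `nv_annotation` supplying descriptions and
#'   terms.
#' @param enrichment optional `nv_enrichment` supplying per-term p-values.
#' @return A data.frame (all character columns): `gene_id`, one column per
#'   experiment (named by it), `direction_class`, `description`,
#'   `pathway_terms`, `go_terms`, `pathway_p`, `go_p`.
#' @export
info_table <- function(model, annotation = NULL, enrichment = NULL) {
  stopifnot(inherits(model, "nv_graph"))
  exps <- model$nodes$id[model$nodes$kind == "EXPERIMENT"]
  genes <- sort(model$nodes$id[model$nodes$kind == "GENE"])
  cls <- stats::setNames(model$nodes$color_class, model$nodes$id)

  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (e in exps) {
    codes <- stats::setNames(rep("", length(genes)), genes)
    ed <- model$edges[model$edges$experiment == e, , drop = FALSE]
    codes[ed$gene] <- as.character(ed$direction)
    out[[e]] <- unname(codes[genes])
  }
  out$direction_class <- unname(cls[genes])

  pull_terms <- function(g, cats) {
    if (is.null(annotation)) return("")
    t <- annotate_gene(annotation, g)$terms
    t <- t[t$category %in% cats, , drop = FALSE]
    if (!nrow(t)) return("")
    paste(sprintf("%s:%s", t$term_id, t$term_name), collapse = ";")
  }
  pull_p <- function(g, cats) {
    if (is.null(annotation) || is.null(enrichment)) return("")
    t <- annotate_gene(annotation, g)$terms
    t <- t[t$category %in% cats, , drop = FALSE]
    hit <- enrichment[enrichment$term_id %in% t$term_id, , drop = FALSE]
    if (!nrow(hit)) return("")
    paste(sprintf("%s=%s", hit$term_id, format_num(hit$p_raw)), collapse = ";")
  }
  desc <- function(g) {
    if (is.null(annotation)) return("")
    annotate_gene(annotation, g)$description
  }
  go_cats <- c("GO_BP", "GO_MF", "GO_CC")
  out$description <- vapply(genes, desc, "")
  out$pathway_terms <- vapply(genes, pull_terms, "", cats = "PATHWAY")
  out$go_terms <- vapply(genes, pull_terms, "", cats = go_cats)
  out$pathway_p <- vapply(genes, pull_p, "", cats = "PATHWAY")
  out$go_p <- vapply(genes, pull_p, "", cats = go_cats)
  rownames(out) <- NULL
  out
}

#' Write the information table as TSV
#'
#' Stable, re-parsable output: header row, LF line endings, tab field
#' separators; cells never contain tabs (they are replaced by spaces).
#'
#' @param tab a data.frame from [info_table()] (or [read_info_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_info_table <- function(tab, path) {
  stopifnot(is.data.frame(tab))
  cells <- vapply(seq_len(nrow(tab)), function(i) {
    paste(gsub("[\t\n]", " ", as.character(unlist(tab[i, ], use.names = FALSE))),
          collapse = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(tab), collapse = "\t"), cells), con,
             sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read an information table written by [write_info_table()]
#'
#' @param path TSV file.
#' @return A data.frame of character columns.
#' @export
read_info_table <- function(path) {
  if (!file.exists(path)) {
    nv_abort(sprintf("info table not found: %s", path), "nv_io_error")
  }
  utils::read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL, quote = "", comment.char = "")
}
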