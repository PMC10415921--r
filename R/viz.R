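# Two-row bipartite diagrams: every node is drawn twice, as a source (top
# row) and as a destination (bottom row), left to right by rank; each edge
# is a straight line colored by its label. Under a valid Wheeler ordering
# roots sit leftmost and no two same-color lines cross, which makes the
# Wheeler properties visually obvious.

#' Count crossings between same-label edges under an ordering
#'
#' Two distinct edges with the same label cross iff their source ranks and
#' destination ranks are oppositely ordered, i.e.
#' `(rank u - rank u') * (rank v - rank v') < 0`. Zero crossings for every
#' label is exactly the same-label Wheeler condition (ii) under `ord`. The
#' count is combinatorial (computed from ranks, not geometry).
#'
#' @param g a [wg_graph()].
#' @param ord a node ordering (bijection, named integer vector).
#' @return Integer total over all labels; per-label counts in attribute
#'   `"by_label"`.
#' @export
count_same_label_crossings <- function(g, ord) {
  stopifnot(inherits(g, "wg_graph"))
  r <- as_node_ordering(g, ord)
  gi <- graph_int(g)
  by_label <- stats::setNames(integer(length(g$alphabet)), g$alphabet)
  ru <- r[gi$from]; rv <- r[gi$to]
  for (l in seq_along(g$alphabet)) {
    idx <- which(gi$lab == l)
    m <- length(idx)
    if (m < 2L) next
    du <- outer(ru[idx], ru[idx], `-`)
    dv <- outer(rv[idx], rv[idx], `-`)
    by_label[l] <- sum(du * dv < 0) / 2L
  }
  structure(sum(by_label), by_label = by_label)
}

# fixed palette, assigned by alphabet order, cycling beyond 10 labels
wg_palette <- c("#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00",
                "#a65628", "#f781bf", "#17becf", "#666666", "#b2df8a")

# positions, colors and crossing counts for the two-row diagram
bipartite_layout <- function(g, ord, unit = 60) {
  r <- as_node_ordering(g, ord)
  gi <- graph_int(g)
  list(
    x = r * unit, unit = unit,
    color = wg_palette[(seq_along(g$alphabet) - 1L) %% length(wg_palette) + 1L],
    edge_color_idx = gi$lab,
    crossings = count_same_label_crossings(g, ord)
  )
}

svg_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the two-row bipartite diagram of an ordered graph
#'
#' Writes an SVG file: the top row holds the source replica of every node
#' and the bottom row the destination replica, both ordered left to right
#' by rank; one straight line per edge, colored by label (same label, same
#' color); a legend maps colors to labels and reports the per-label
#' crossing counts. Output is deterministic for a given graph and
#' ordering.
#'
#' @param g a [wg_graph()].
#' @param ord a node ordering (any bijection; crossings are drawn and
#'   counted if the ordering is not Wheeler).
#' @param out_path output SVG path.
#' @return `out_path`, invisibly; the crossing count in attribute
#'   `"crossings"`.
#' @export
render_bipartite <- function(g, ord, out_path) {
  stopifnot(inherits(g, "wg_graph"))
  r <- as_node_ordering(g, ord)
  lay <- bipartite_layout(g, ord)
  gi <- graph_int(g)
  n <- gi$n
  y_top <- 80; y_bot <- 280
  width <- max(lay$unit * (n + 1), 300) + 180
  height <- y_bot + 120
  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    '<rect width="100%" height="100%" fill="white"/>',
    sprintf('<text x="10" y="20" font-family="monospace" font-size="13">bipartite Wheeler diagram: n=%d e=%d sigma=%d, same-label crossings=%d</text>',
            n, gi$e, gi$sigma, as.integer(lay$crossings))
  )
  # edges first (under the node glyphs)
  if (gi$e) {
    out <- c(out, sprintf(
      '<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="%s" stroke-width="1.5" stroke-opacity="0.85"/>',
      lay$x[gi$from], y_top + 8, lay$x[gi$to], y_bot - 8,
      lay$color[lay$edge_color_idx]))
  }
  for (row_y in c(y_top, y_bot)) {
    anchor <- if (row_y == y_top) "source" else "destination"
    out <- c(out,
      sprintf('<circle cx="%d" cy="%d" r="6" fill="%s" stroke="black"/>',
              lay$x, row_y, "#f0f0f0"),
      sprintf('<text x="%d" y="%d" text-anchor="middle" font-family="monospace" font-size="11">%s</text>',
              lay$x, row_y + ifelse(row_y == y_top, -12, 22),
              svg_esc(g$nodes)),
      sprintf('<text x="10" y="%d" font-family="monospace" font-size="11">%s</text>',
              row_y + 4, anchor))
  }
  # legend
  ly <- y_bot + 50
  bl <- attr(lay$crossings, "by_label")
  for (i in seq_along(g$alphabet)) {
    out <- c(out,
      sprintf('<rect x="%d" y="%d" width="12" height="12" fill="%s"/>',
              10 + (i - 1L) * 160, ly, lay$color[i]),
      sprintf('<text x="%d" y="%d" font-family="monospace" font-size="12">%s (crossings: %d)</text>',
              26 + (i - 1L) * 160, ly + 11, svg_esc(g$alphabet[i]), bl[i]))
  }
  out <- c(out, "</svg>")
  writeLines(out, out_path)
  invisible(structure(out_path, crossings = as.integer(lay$crossings)))
}
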