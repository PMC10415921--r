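# DOT input/output for labeled digraphs.
#
# Only the restricted dialect used throughout the toolkit is supported:
#   digraph { a -> b [label="A"]; c; }
# Every edge must carry a label attribute; other attributes are ignored on
# read and never written. Statements are separated by ';' or newlines.

#' Parse a DOT document into a labeled digraph
#'
#' @param text a DOT-format string (single string or character vector of
#'   lines) describing a directed graph. Every edge statement must carry a
#'   `label` attribute. Node statements without edges yield isolated nodes.
#'   Duplicate identical `(source, destination, label)` triples are
#'   collapsed to one with a warning.
#' @return A [wg_graph()].
#' @examples
#' parse_dot('digraph { a -> b [label="A"]; }')
#' @export
parse_dot <- function(text) {
  txt <- paste(text, collapse = "\n")
  # strip comments
  txt <- gsub("/\\*.*?\\*/", " ", txt, perl = TRUE)
  txt <- gsub("(//|#)[^\n]*", "", txt, perl = TRUE)
  header <- regmatches(txt, regexpr("^\\s*(strict\\s+)?(di)?graph\\b[^{]*\\{",
                                    txt, perl = TRUE))
  if (!length(header))
    stop("format error: not a DOT graph document")
  if (!grepl("\\bdigraph\\b", header))
    stop("format error: undirected graph; only 'digraph' is supported")
  body <- sub("^\\s*(strict\\s+)?(di)?graph\\b[^{]*\\{", "", txt, perl = TRUE)
  body <- sub("\\}\\s*$", "", body, perl = TRUE)
  stmts <- strsplit(body, "[;\n]+")[[1]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]

  id_re <- '("(?:[^"\\\\]|\\\\.)*"|[A-Za-z0-9_.]+)'
  unquote <- function(s) {
    if (startsWith(s, '"')) gsub('\\\\(.)', "\\1",
                                 substr(s, 2L, nchar(s) - 1L)) else s
  }
  edge_re <- paste0("^", id_re, "\\s*->\\s*", id_re,
                    "\\s*(\\[(?<attrs>[^]]*)\\])?\\s*$")
  node_re <- paste0("^", id_re, "\\s*(\\[[^]]*\\])?\\s*$")

  from <- character(); to <- character(); lab <- character()
  nodes <- character()
  for (s in stmts) {
    m <- regexec(edge_re, s, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      parts <- regmatches(s, list(m))[[1]]
      u <- unquote(parts[2]); v <- unquote(parts[3])
      attrs <- if (length(parts) >= 5) parts[5] else ""
      lm <- regexec('label\\s*=\\s*("(?:[^"\\\\]|\\\\.)*"|[A-Za-z0-9_.]+)',
                    attrs, perl = TRUE)[[1]]
      if (lm[1] == -1L)
        stop(sprintf("format error: edge %s->%s has no label", u, v))
      l <- unquote(regmatches(attrs, list(lm))[[1]][2])
      from <- c(from, u); to <- c(to, v); lab <- c(lab, l)
      next
    }
    m <- regexec(node_re, s, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      parts <- regmatches(s, list(m))[[1]]
      id <- unquote(parts[2])
      if (id %in% c("node", "edge", "graph")) next  # default-attr statements
      nodes <- c(nodes, id)
      next
    }
    if (grepl("--", s, fixed = TRUE))
      stop("format error: undirected edge statement: ", s)
    stop("format error: unsupported DOT statement: ", s)
  }
  wg_graph(from, to, lab, nodes = nodes)
}

dot_quote <- function(x) {
  needs <- !grepl("^[A-Za-z0-9_]+$", x)
  x[needs] <- paste0('"', gsub('"', '\\\\"', x[needs]), '"')
  x
}

#' Serialize a labeled digraph to DOT
#'
#' Deterministic output: isolated nodes first (sorted by identifier), then
#' edges in stored order. `parse_dot(write_dot(g))` reproduces `g`.
#'
#' @param g a [wg_graph()].
#' @return A single DOT-format string.
#' @export
write_dot <- function(g) {
  stopifnot(inherits(g, "wg_graph"))
  incident <- unique(c(g$edges$from, g$edges$to))
  isolated <- setdiff(g$nodes, incident)  # g$nodes already sorted
  lines <- character()
  if (length(isolated))
    lines <- c(lines, paste0("  ", dot_quote(isolated), ";"))
  if (nrow(g$edges))
    lines <- c(lines, sprintf('  %s -> %s [label="%s"];',
                              dot_quote(g$edges$from), dot_quote(g$edges$to),
                              gsub('"', '\\\\"', g$edges$label)))
  if (!length(lines)) return("digraph {\n}")
  paste0("digraph {\n", paste(lines, collapse = "\n"), "\n}")
}
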