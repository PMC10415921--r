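#' Construct an edge-labeled directed graph
#'
#' The basic container of the package: a directed graph whose edges carry a
#' single label each. This is the object the recognizers decide over and the
#' generators produce. Nodes are identified by strings; the alphabet is the
#' sorted set of distinct edge labels, compared by code point.
#'
#' @param from,to,label character vectors of equal length describing the
#'   edges: `from[i] -> to[i]` labeled `label[i]`. Edges are kept in the
#'   order given; duplicated identical `(from, to, label)` triples are
#'   collapsed to one occurrence with a warning.
#' @param nodes optional character vector of node identifiers. Endpoints of
#'   the edges are always included; listing extra names here creates
#'   isolated nodes. Stored sorted by code point.
#' @return An object of class `wg_graph`: a list with elements `nodes`
#'   (sorted character vector), `edges` (data frame with columns `from`,
#'   `to`, `label`) and `alphabet` (sorted distinct labels).
#' @examples
#' g <- wg_graph(from = c("a", "a"), to = c("b", "c"), label = c("A", "A"))
#' g
#' @export
wg_graph <- function(from = character(), to = character(),
                     label = character(), nodes = NULL) {
  from <- as.character(from); to <- as.character(to); label <- as.character(label)
  if (length(from) != length(to) || length(from) != length(label))
    stop("'from', 'to' and 'label' must have equal length")
  if (length(label) && any(!nzchar(label)))
    stop("edge labels must be non-empty strings")
  key <- paste(from, to, label, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate identical edge triples collapsed to one occurrence")
    keep <- !duplicated(key)
    from <- from[keep]; to <- to[keep]; label <- label[keep]
  }
  all_nodes <- sort_cp(unique(c(from, to, as.character(nodes %||% character()))))
  g <- list(
    nodes = all_nodes,
    edges = data.frame(from = from, to = to, label = label,
                       stringsAsFactors = FALSE),
    alphabet = sort_cp(unique(label))
  )
  class(g) <- "wg_graph"
  g
}

#' @export
print.wg_graph <- function(x, ...) {
  cat(sprintf("Labeled digraph: n=%d nodes, e=%d edges, sigma=%d labels\n",
              length(x$nodes), nrow(x$edges), length(x$alphabet)))
  if (length(x$alphabet))
    cat("  alphabet:", paste(x$alphabet, collapse = " "), "\n")
  if (nrow(x$edges)) {
    show <- utils::head(x$edges, 10L)
    cat(paste0("  ", show$from, " -> ", show$to, " [", show$label, "]",
               collapse = "\n"), "\n")
    if (nrow(x$edges) > 10L) cat(sprintf("  ... and %d more edges\n",
                                         nrow(x$edges) - 10L))
  }
  invisible(x)
}

# Integer view of a graph used by the heavier algorithms: nodes as indices
# 1..n (in stored, i.e. code-point, order), labels as indices into the
# alphabet.
graph_int <- function(g) {
  list(
    n = length(g$nodes),
    e = nrow(g$edges),
    from = match(g$edges$from, g$nodes),
    to = match(g$edges$to, g$nodes),
    lab = match(g$edges$label, g$alphabet),
    sigma = length(g$alphabet)
  )
}

# indegree / outdegree by node (in stored node order)
node_degrees <- function(g) {
  gi <- graph_int(g)
  list(indeg = tabulate(gi$to, nbins = gi$n),
       outdeg = tabulate(gi$from, nbins = gi$n))
}

#' Zero-indegree nodes of a graph
#'
#' In a Wheeler ordering all 0-indegree nodes (the "roots") must come before
#' every node that has an incoming edge.
#'
#' @param g a [wg_graph()].
#' @return Character vector of the 0-indegree node identifiers, sorted by
#'   code point.
#' @export
find_roots <- function(g) {
  stopifnot(inherits(g, "wg_graph"))
  g$nodes[node_degrees(g)$indeg == 0L]
}

# Validate that `ord` is a node ordering (bijection node -> 1..n) for g.
# Returns the ordering as an integer vector named by node, in stored node
# order.
as_node_ordering <- function(g, ord) {
  n <- length(g$nodes)
  if (is.null(names(ord)) || length(ord) != n)
    stop("ordering must be an integer vector named by all nodes of the graph")
  if (anyNA(match(g$nodes, names(ord))) || anyDuplicated(names(ord)))
    stop("ordering names must be exactly the nodes of the graph")
  r <- as.integer(ord[g$nodes])
  if (anyNA(r) || !setequal(r, seq_len(n)))
    stop("ordering must be a bijection onto 1..n")
  names(r) <- g$nodes
  r
}

#' Check the Wheeler properties under a candidate node ordering
#'
#' Decides whether `ord` is a valid Wheeler ordering of `g`, i.e. whether
#' (a) every 0-indegree node ranks before every positive-indegree node,
#' (b) for every pair of edges `(u,v)` labeled `a` and `(u',v')` labeled
#' `a'` with `a` before `a'`, `rank(v) < rank(v')`, and (c) for every pair
#' of same-labeled edges with `rank(u) < rank(u')`, `rank(v) <= rank(v')`.
#'
#' @param g a [wg_graph()].
#' @param ord a candidate ordering: integer vector of ranks `1..n` named by
#'   node identifier (a bijection).
#' @return A list with `valid` (logical) and `violation` (`NULL` when valid,
#'   otherwise a human-readable certificate naming the first offending
#'   condition and edge pair under a deterministic scan).
#' @examples
#' g <- wg_graph("a", "b", "A")
#' check_wheeler(g, c(a = 1, b = 2))$valid
#' @export
check_wheeler <- function(g, ord) {
  stopifnot(inherits(g, "wg_graph"))
  r <- as_node_ordering(g, ord)
  gi <- graph_int(g)
  deg <- node_degrees(g)

  # (a) roots strictly before all positive-indegree nodes
  is_root <- deg$indeg == 0L
  if (any(is_root) && any(!is_root) &&
      max(r[is_root]) > min(r[!is_root])) {
    bad_root <- g$nodes[is_root][which.max(r[is_root])]
    bad_other <- g$nodes[!is_root][which.min(r[!is_root])]
    return(list(valid = FALSE, violation = sprintf(
      "condition (a): 0-indegree node '%s' (rank %d) ranks after node '%s' (rank %d)",
      bad_root, r[[bad_root]], bad_other, r[[bad_other]])))
  }

  ru <- r[gi$from]; rv <- r[gi$to]
  ok <- TRUE
  # (b) destination ranks of smaller labels strictly below larger labels:
  # max dest rank per label must be < min dest rank of every later label.
  if (gi$e && gi$sigma > 1L) {
    mx <- tapply(rv, gi$lab, max)
    mn <- tapply(rv, gi$lab, min)
    labs_present <- sort(unique(gi$lab))
    mx <- mx[as.character(labs_present)]; mn <- mn[as.character(labs_present)]
    if (length(labs_present) > 1L &&
        any(cummax(mx[-length(mx)]) >= mn[-1L])) ok <- FALSE
  }
  # (c) per label: sorting edges by source rank must give non-decreasing
  # destination ranks (running max over strictly smaller source ranks).
  if (ok && gi$e > 1L) {
    for (l in unique(gi$lab)) {
      sel <- gi$lab == l
      if (sum(sel) < 2L) next
      o <- order(ru[sel], rv[sel])
      su <- ru[sel][o]; sv <- rv[sel][o]
      # for each edge, max dest among edges with strictly smaller source rank
      run_max <- cummax(sv)
      prev_idx <- findInterval(su - 1L, su)  # last index with source rank < su
      bad <- prev_idx > 0L & sv < run_max[pmax(prev_idx, 1L)]
      if (any(bad)) { ok <- FALSE; break }
    }
  }
  if (ok) return(list(valid = TRUE, violation = NULL))
  list(valid = FALSE, violation = first_pair_violation(g, gi, r))
}

# Deterministic certificate: scan edge pairs (i, j), i < j, in stored edge
# order, reporting the first pair violating condition (b) or (c).
first_pair_violation <- function(g, gi, r) {
  ed <- g$edges
  ru <- r[gi$from]; rv <- r[gi$to]
  for (i in seq_len(gi$e - 1L)) {
    for (j in (i + 1L):gi$e) {
      li <- gi$lab[i]; lj <- gi$lab[j]
      if (li != lj) {
        a <- if (li < lj) i else j
        b <- if (li < lj) j else i
        if (rv[a] >= rv[b])
          return(sprintf(
            "condition (b): edge %s->%s [%s] and edge %s->%s [%s]: label '%s' precedes '%s' but rank(%s)=%d >= rank(%s)=%d",
            ed$from[a], ed$to[a], ed$label[a], ed$from[b], ed$to[b], ed$label[b],
            ed$label[a], ed$label[b], ed$to[a], rv[a], ed$to[b], rv[b]))
      } else {
        a <- i; b <- j
        if (ru[a] > ru[b]) { a <- j; b <- i }
        if (ru[a] < ru[b] && rv[a] > rv[b])
          return(sprintf(
            "condition (c): same-label edges %s->%s and %s->%s [%s]: rank(%s)=%d < rank(%s)=%d but rank(%s)=%d > rank(%s)=%d",
            ed$from[a], ed$to[a], ed$from[b], ed$to[b], ed$label[a],
            ed$from[a], ru[a], ed$from[b], ru[b], ed$to[a], rv[a], ed$to[b], rv[b]))
      }
    }
  }
  "wheeler conditions violated"
}

#' Build the O/I/L index arrays of a recognized Wheeler graph
#'
#' Given a graph and a valid Wheeler ordering, constructs the succinct index
#' triple: `O` concatenates, over nodes in rank order, the unary code
#' `'0' x outdegree` followed by a `'1'` terminator; `I` does the same for
#' indegrees; `L` lists the edge labels with edges sorted by
#' (source rank, label, destination rank).
#'
#' @param g a [wg_graph()].
#' @param ord a valid Wheeler ordering (see [check_wheeler()]); an invalid
#'   ordering is an error.
#' @return An object of class `wg_index`: list with character scalars `O`,
#'   `I` (bitstrings of length `n + e` with exactly `n` ones) and `L`
#'   (length-`e` label string).
#' @examples
#' g <- wg_graph("a", "b", "A")
#' build_index(g, c(a = 1, b = 2))
#' @export
build_index <- function(g, ord) {
  chk <- check_wheeler(g, ord)
  if (!chk$valid)
    stop("ordering is not a valid Wheeler ordering: ", chk$violation)
  r <- as_node_ordering(g, ord)
  gi <- graph_int(g)
  deg <- node_degrees(g)
  by_rank <- order(r)  # node indices in rank order
  unary <- function(d) paste(vapply(d, function(k)
    paste0(strrep("0", k), "1"), character(1)), collapse = "")
  O <- unary(deg$outdeg[by_rank])
  I <- unary(deg$indeg[by_rank])
  eo <- order(r[gi$from], g$edges$label, r[gi$to], method = "radix")
  L <- paste(g$edges$label[eo], collapse = "")
  structure(list(O = O, I = I, L = L), class = "wg_index")
}

#' @export
print.wg_index <- function(x, ...) {
  cat("O:", x$O, "\n", sep = "")
  cat("I:", x$I, "\n", sep = "")
  cat("L:", x$L, "\n", sep = "")
  invisible(x)
}

#' Maximum same-label outdegree (the d of a d-NFA)
#'
#' The largest number of outgoing edges sharing one label at any node. A
#' graph with value `d` is a d-NFA; De Bruijn graphs and tries are 1-NFAs,
#' and recognition hardness grows with `d`.
#'
#' @param g a [wg_graph()].
#' @return Integer; 0 for an edgeless graph.
#' @export
max_same_label_outdegree <- function(g) {
  stopifnot(inherits(g, "wg_graph"))
  if (!nrow(g$edges)) return(0L)
  max(table(paste(g$edges$from, g$edges$label, sep = "\r")))
}

#' Write a node ordering to a file
#'
#' One `node<TAB>rank` line per node, sorted by rank.
#'
#' @param ord named integer vector of ranks.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ordering <- function(ord, path) {
  o <- ord[order(ord)]
  writeLines(paste(names(o), o, sep = "\t"), path)
  invisible(path)
}

#' Write a Wheeler index to a file
#'
#' Three lines: `O:<bits>`, `I:<bits>`, `L:<chars>`.
#'
#' @param idx a `wg_index` from [build_index()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_index <- function(idx, path) {
  stopifnot(inherits(idx, "wg_index"))
  writeLines(c(paste0("O:", idx$O), paste0("I:", idx$I), paste0("L:", idx$L)),
             path)
  invisible(path)
}
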