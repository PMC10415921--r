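# Graph generators: tries, De Bruijn and pseudo-De Bruijn graphs and
# reverse deterministic graphs built from multiple sequence alignments, and
# random Wheeler graphs (complete, edge-sampled, d-NFA). The MSA-based
# generators strip gap characters first; the random generators fix the node
# ordering up front and place edges so the Wheeler properties hold by
# construction.

#' Read a gapped FASTA multiple sequence alignment
#'
#' @param file path to a FASTA file, or the FASTA text itself (detected by
#'   an embedded newline). Gap character is `-`; residues are uppercased.
#'   All aligned rows must have equal length.
#' @return An object of class `wg_msa`: list with `ids` and `seqs`
#'   (character vector of aligned rows, named by identifier).
#' @export
read_msa <- function(file) {
  if (length(file) == 1L && grepl("\n", file)) {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    writeLines(file, tmp)
    file <- tmp
  }
  set <- Biostrings::readBStringSet(file)
  if (!length(set)) stop("empty FASTA: no alignment records")
  seqs <- toupper(as.character(set))
  w <- nchar(seqs)
  if (all(w == 0L)) stop("empty FASTA: records contain no residues")
  if (length(unique(w)) != 1L)
    stop("alignment rows have unequal lengths (", paste(unique(w), collapse = ", "), ")")
  structure(list(ids = names(set), seqs = stats::setNames(seqs, names(set))),
            class = "wg_msa")
}

#' @export
print.wg_msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns\n", length(x$seqs),
              nchar(x$seqs[[1]])))
  invisible(x)
}

#' Truncate an alignment to a column range
#'
#' Applied before any gap removal; columns are 1-based and inclusive.
#'
#' @param msa a `wg_msa`.
#' @param first,last column range, `1 <= first <= last <= width`.
#' @return The truncated `wg_msa`.
#' @export
truncate_columns <- function(msa, first, last) {
  stopifnot(inherits(msa, "wg_msa"))
  width <- nchar(msa$seqs[[1]])
  if (first < 1 || last > width || first > last)
    stop("column range [", first, ", ", last, "] invalid for alignment width ",
         width)
  msa$seqs <- substr(msa$seqs, first, last)
  msa
}

#' Generate a random (optionally gapped) alignment
#'
#' Synthetic-data source for the sequence-based generators: independent
#' uniform residues, with optional independent gap positions.
#'
#' @param n_seq number of rows.
#' @param length alignment width.
#' @param alphabet residue characters (default DNA).
#' @param gap_rate per-position gap probability (default 0).
#' @param seed RNG seed.
#' @return A `wg_msa`.
#' @export
random_msa <- function(n_seq, length, alphabet = c("A", "C", "G", "T"),
                       gap_rate = 0, seed = 1L) {
  with_seed(seed, {
    rows <- vapply(seq_len(n_seq), function(i) {
      chars <- sample(alphabet, length, replace = TRUE)
      if (gap_rate > 0)
        chars[stats::runif(length) < gap_rate] <- "-"
      paste(chars, collapse = "")
    }, character(1))
  })
  ids <- sprintf("seq%d", seq_len(n_seq))
  structure(list(ids = ids, seqs = stats::setNames(rows, ids)),
            class = "wg_msa")
}

strip_gaps <- function(msa) gsub("-", "", unname(msa$seqs), fixed = TRUE)

#' Build a trie from alignment sequences
#'
#' Gap-stripped rows are inserted character by character; one node per
#' distinct prefix, edges labeled by the appended character. Node names are
#' breadth-first search orders starting from the root.
#'
#' @param msa a `wg_msa`.
#' @return A [wg_graph()]; always a Wheeler graph and a 1-NFA.
#' @export
gen_trie <- function(msa) {
  stopifnot(inherits(msa, "wg_msa"))
  rows <- strip_gaps(msa)
  # trie as parallel vectors: children keyed by "nodeid|char"
  children <- new.env(parent = emptyenv(), hash = TRUE)
  n_nodes <- 1L  # node 1 = root (empty prefix)
  edge_child <- integer(); edge_parent <- integer(); edge_char <- character()
  for (row in rows) {
    cur <- 1L
    for (ch in strsplit(row, "", fixed = TRUE)[[1]]) {
      key <- paste0(cur, "|", ch)
      nxt <- children[[key]]
      if (is.null(nxt)) {
        n_nodes <- n_nodes + 1L
        nxt <- n_nodes
        children[[key]] <- nxt
        edge_parent <- c(edge_parent, cur)
        edge_child <- c(edge_child, nxt)
        edge_char <- c(edge_char, ch)
      }
      cur <- nxt
    }
  }
  # BFS renaming (children visited in label order)
  bfs_name <- integer(n_nodes)
  bfs_name[1L] <- 1L
  queue <- 1L; next_name <- 1L
  kids_of <- split(seq_along(edge_parent), edge_parent)
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    ks <- kids_of[[as.character(cur)]]
    if (!is.null(ks)) {
      ks <- ks[order_cp(edge_char[ks])]
      for (ei in ks) {
        next_name <- next_name + 1L
        bfs_name[edge_child[ei]] <- next_name
        queue <- c(queue, edge_child[ei])
      }
    }
  }
  wg_graph(as.character(bfs_name[edge_parent]),
           as.character(bfs_name[edge_child]),
           edge_char,
           nodes = as.character(seq_len(n_nodes)))
}

row_kmers <- function(rows, k) {
  if (any(nchar(rows) < k - 1L))
    stop("gap-stripped rows shorter than k-1 = ", k - 1L)
  lapply(rows, function(s) {
    L <- nchar(s)
    starts <- seq_len(L - (k - 1L) + 1L)
    substring(s, starts, starts + k - 2L)
  })
}

debruijn_labels <- function(dest_kmers, convention) {
  if (convention == "last") substring(dest_kmers, nchar(dest_kmers),
                                      nchar(dest_kmers))
  else substring(dest_kmers, 1L, 1L)
}

#' Build a De Bruijn graph from alignment sequences
#'
#' One node per distinct (k-1)-mer over all gap-stripped rows; one
#' (deduplicated) edge per adjacent (k-1)-mer pair within a row. Under the
#' default `"last"` label convention the edge label is the last character
#' of the destination (k-1)-mer, which makes the output a Wheeler graph
#' under co-lexicographic node order; `"first"` labels with the first
#' character of the destination instead (not Wheeler-guaranteed). Nodes are
#' named by their (k-1)-mer.
#'
#' @param msa a `wg_msa`.
#' @param k k-mer length (>= 2); every gap-stripped row must have length at
#'   least `k - 1`.
#' @param label_convention `"last"` (default) or `"first"`.
#' @param pad_start if `TRUE`, prefix every row with `k - 1` copies of the
#'   sentinel `$` before building the graph. The sampled, unpadded graph
#'   (the default) is *not* guaranteed to have the Wheeler properties: its
#'   0-indegree (k-1)-mers can be forced away from the front of any
#'   otherwise-consistent ordering. Padding restores the classical
#'   guarantee: the unique root `$...$` is co-lexicographically smallest
#'   and the co-lex order is then always a valid Wheeler ordering (under
#'   the `"last"` convention).
#' @return A [wg_graph()].
#' @examples
#' m <- read_msa(">s1\nACGT\n")
#' gen_debruijn(m, k = 3)
#' @export
gen_debruijn <- function(msa, k, label_convention = c("last", "first"),
                         pad_start = FALSE) {
  stopifnot(inherits(msa, "wg_msa"), k >= 2)
  label_convention <- match.arg(label_convention)
  rows <- strip_gaps(msa)
  if (pad_start) rows <- paste0(strrep("$", k - 1L), rows)
  kl <- row_kmers(rows, k)
  from <- character(); to <- character()
  for (km in kl) {
    if (length(km) > 1L) {
      from <- c(from, km[-length(km)])
      to <- c(to, km[-1L])
    }
  }
  keep <- !duplicated(paste(from, to, sep = "\r"))
  from <- from[keep]; to <- to[keep]
  wg_graph(from, to, debruijn_labels(to, label_convention),
           nodes = unique(unlist(kl)))
}

#' Build a pseudo-De Bruijn graph (no (k-1)-mer collapsing)
#'
#' Like [gen_debruijn()] but with one node per `(row, position)` occurrence
#' of a (k-1)-mer, so identical (k-1)-mers are never merged: each row
#' becomes a simple chain. The output is not guaranteed to be a Wheeler
#' graph.
#'
#' @inheritParams gen_debruijn
#' @return A [wg_graph()].
#' @export
gen_pseudo_debruijn <- function(msa, k, label_convention = c("last", "first")) {
  stopifnot(inherits(msa, "wg_msa"), k >= 2)
  label_convention <- match.arg(label_convention)
  kl <- row_kmers(strip_gaps(msa), k)
  from <- character(); to <- character(); lab_src <- character()
  nodes <- character()
  for (r in seq_along(kl)) {
    km <- kl[[r]]
    nm <- sprintf("%s.%d.%d", km, r, seq_along(km))
    nodes <- c(nodes, nm)
    if (length(km) > 1L) {
      from <- c(from, nm[-length(nm)])
      to <- c(to, nm[-1L])
      lab_src <- c(lab_src, km[-1L])
    }
  }
  wg_graph(from, to, debruijn_labels(lab_src, label_convention),
           nodes = nodes)
}

#' Build a reverse deterministic graph from an alignment
#'
#' One node per distinct non-gap character in each column; for each row,
#' consecutive ungapped characters produce an edge from the earlier
#' column's node to the later one, labeled with the destination character
#' (edges point toward the end of the alignment, as in the reverse
#' deterministic automata used for pangenome indexing). Duplicate edges
#' are collapsed. Not guaranteed Wheeler.
#'
#' @param msa a `wg_msa`.
#' @return A [wg_graph()] with nodes named `c<column>_<char>`.
#' @export
gen_revdet <- function(msa) {
  stopifnot(inherits(msa, "wg_msa"))
  rows <- unname(msa$seqs)
  width <- nchar(rows[1])
  chars <- lapply(rows, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  node_name <- function(col, ch) sprintf("c%d_%s", col, ch)
  nodes <- character()
  for (col in seq_len(width)) {
    here <- sort_cp(unique(vapply(chars, `[[`, character(1), col)))
    here <- here[here != "-"]
    nodes <- c(nodes, node_name(col, here))
  }
  from <- character(); to <- character(); lab <- character()
  for (cv in chars) {
    pos <- which(cv != "-")
    if (length(pos) > 1L) {
      p <- pos[-length(pos)]; q <- pos[-1L]
      from <- c(from, node_name(p, cv[p]))
      to <- c(to, node_name(q, cv[q]))
      lab <- c(lab, cv[q])
    }
  }
  keep <- !duplicated(paste(from, to, lab, sep = "\r"))
  wg_graph(from[keep], to[keep], lab[keep], nodes = nodes)
}

#' Maximum edge count of a Wheeler graph
#'
#' The closed-form bound `e_max = n*sigma + n - sigma - r` (equivalently
#' `(n-1)(sigma+1) - r + 1`) on the number of edges of a Wheeler graph with
#' `n` nodes, `sigma` labels and `r` 0-indegree nodes; attained by complete
#' Wheeler graphs.
#'
#' @param n node count (>= 1).
#' @param sigma alphabet size (>= 1).
#' @param r root count (`0 <= r <= n`).
#' @return Integer edge count.
#' @examples
#' e_max(7, 2, 1)  # 18
#' @export
e_max <- function(n, sigma, r) {
  if (n < 1 || sigma < 1 || r < 0 || r > n)
    stop("need n >= 1, sigma >= 1, 0 <= r <= n")
  as.integer(n * sigma + n - sigma - r)
}

# block sizes n_i, as equal as possible, remainder to earlier labels
label_block_sizes <- function(total, sigma) {
  base <- total %/% sigma
  as.integer(base + (seq_len(sigma) <= total %% sigma))
}

# Monotone staircase of label-i edges: every source rank 1..n emits one
# edge; each of the n_i - 1 breakpoint sources emits one extra edge to the
# next destination. Returns a 2-column matrix (source rank, dest offset
# 1..n_i) in deterministic order.
staircase_edges <- function(n, n_i, breakpoints) {
  bp <- sort(breakpoints)
  src <- integer(0); dst <- integer(0)
  for (s in seq_len(n)) {
    j <- 1L + sum(bp < s)
    src <- c(src, s); dst <- c(dst, j)
    if (s %in% bp) { src <- c(src, s); dst <- c(dst, j + 1L) }
  }
  cbind(src, dst)
}

#' Generate a complete Wheeler graph
#'
#' A Wheeler graph to which no further edge can be added without breaking
#' the Wheeler properties; its edge count attains [e_max()]. Ranks `1..r`
#' are roots; the remaining ranks split into per-label destination blocks
#' of near-equal size. Within each label every source emits one edge along
#' a random monotone staircase over the block, with `n_i - 1` randomly
#' chosen breakpoint sources emitting one extra edge each.
#'
#' @param n,sigma,r node count, alphabet size, root count
#'   (`n - r >= sigma` so each label gets a destination).
#' @param seed RNG seed (breakpoint choice).
#' @return list with `graph` (a [wg_graph()], exactly `e_max(n, sigma, r)`
#'   edges) and `ordering` (a valid Wheeler ordering; node `v<rank>` has
#'   rank `<rank>`).
#' @export
gen_complete_wg <- function(n, sigma, r, seed = 1L) {
  if (n < 1 || sigma < 1 || r < 0 || n - r < sigma)
    stop("infeasible parameters: need n - r >= sigma >= 1")
  labels <- LETTERS[seq_len(sigma)]
  if (sigma > 26L) labels <- sprintf("L%02d", seq_len(sigma))
  sizes <- label_block_sizes(n - r, sigma)
  lo <- r + c(1L, utils::head(cumsum(sizes), -1L) + 1L)
  nm <- pad_names(n)
  from <- character(); to <- character(); lab <- character()
  with_seed(seed, {
    for (i in seq_len(sigma)) {
      bp <- if (sizes[i] > 1L) sample(n, sizes[i] - 1L) else integer()
      sc <- staircase_edges(n, sizes[i], bp)
      from <- c(from, nm[sc[, 1L]])
      to <- c(to, nm[lo[i] - 1L + sc[, 2L]])
      lab <- c(lab, rep(labels[i], nrow(sc)))
    }
  })
  g <- wg_graph(from, to, lab, nodes = nm)
  ord <- stats::setNames(seq_len(n), nm)
  list(graph = g, ordering = ord)
}

#' Generate a random Wheeler graph by edge sampling
#'
#' Samples `e` edges from a complete Wheeler graph with one root, always
#' keeping each non-root node's first staircase in-edge so no node loses
#' all incoming edges (which would break the 0-indegree-first condition).
#' The result is Wheeler under the complete graph's ordering.
#'
#' @param n,e,sigma node, edge and label counts;
#'   `n - 1 <= e <= e_max(n, sigma, 1)`.
#' @param seed RNG seed.
#' @return A [wg_graph()] with exactly `e` edges.
#' @export
gen_random_wg <- function(n, e, sigma, seed = 1L) {
  emax <- e_max(n, sigma, 1L)
  if (e < n - 1L || e > emax)
    stop("need n - 1 <= e <= e_max(n, sigma, 1) = ", emax)
  with_seed(seed, {
    comp <- gen_complete_wg(n, sigma, 1L, seed = sample.int(.Machine$integer.max, 1L))
    ed <- comp$graph$edges
    # first stored in-edge per destination (staircase order): forced
    forced <- which(!duplicated(ed$to))
    pool <- setdiff(seq_len(nrow(ed)), forced)
    extra <- sample(pool, e - length(forced))
    keep <- sort(c(forced, extra))
  })
  wg_graph(ed$from[keep], ed$to[keep], ed$label[keep],
           nodes = comp$graph$nodes)
}

#' Solve for a d-NFA out-multiplicity profile
#'
#' Per label, `x_k` counts the source nodes with `k` outgoing edges of that
#' label. The profile satisfies `sum(k * x_k) = e_i` exactly (with all
#' `x_k` set equal and the residual added to `x_1`) and the capacity bound
#' `n_min = 1 + sum((k-1) * x_k) <= n_i` (a node with `k` same-label edges
#' needs `k` distinct destinations, and consecutive sources can share at
#' most one). Infeasible parameters are an error naming the violated
#' inequality.
#'
#' @param n,e,sigma,d graph parameters; one root is assumed; label blocks
#'   take near-equal shares of `n - 1` nodes and `e` edges.
#' @return An object of class `wg_dnfa_profile`: list with `d`, `labels`,
#'   `n_i`, `e_i`, and matrix `x` (`sigma` rows, `d` columns).
#' @export
solve_dnfa_profile <- function(n, e, sigma, d) {
  if (n < 2 || e < 1 || sigma < 1 || d < 1)
    stop("need n >= 2, e >= 1, sigma >= 1, d >= 1")
  n_i <- label_block_sizes(n - 1L, sigma)
  e_i <- label_block_sizes(e, sigma)
  tri <- as.integer(d * (d + 1L) / 2)
  x <- matrix(0L, nrow = sigma, ncol = d)
  for (i in seq_len(sigma)) {
    q <- as.integer(e_i[i] %/% tri)
    xi <- rep.int(q, as.integer(d))
    xi[1L] <- as.integer(xi[1L] + e_i[i] - q * tri)
    x[i, ] <- xi
    if (sum(seq_len(d) * xi) != e_i[i])
      stop("internal error: sum(k * x_k) != e_i")
    n_min <- 1L + if (d > 1L) sum((2:d - 1L) * xi[2:d]) else 0L
    if (n_min > n_i[i])
      stop(sprintf(
        "infeasible: label %d needs n_min = 1 + sum((k-1)*x_k) = %d destinations but n_i = %d (violates n_min <= n_i)",
        i, n_min, n_i[i]))
    if (e_i[i] < n_i[i])
      stop(sprintf(
        "infeasible: label %d has e_i = %d < n_i = %d, so not every destination can receive an edge (violates e_i >= n_i)",
        i, e_i[i], n_i[i]))
    if (sum(xi) > n)
      stop(sprintf(
        "infeasible: label %d requires %d distinct source nodes but only n = %d exist (violates sum(x_k) <= n)",
        i, sum(xi), n))
  }
  if (all(x[, d] < 1L))
    stop("infeasible: no label attains x_d >= 1; the output would not be a d-NFA (violates x_d >= 1)")
  structure(list(d = as.integer(d), n_i = n_i, e_i = e_i, x = x),
            class = "wg_dnfa_profile")
}

#' Generate a random d-NFA Wheeler graph
#'
#' Builds the out-multiplicity profile with [solve_dnfa_profile()], assigns
#' the multiplicities to seeded-shuffled source nodes, and maps the
#' resulting source slots (sources in rank order, repeated by multiplicity)
#' onto each label's destination block through a seeded-random monotone
#' surjection, with destinations strictly increasing within one source's
#' slots. The output is Wheeler by construction, every block node has an
#' incoming edge, and the maximum same-label outdegree is exactly `d`.
#'
#' @inheritParams solve_dnfa_profile
#' @param seed RNG seed.
#' @return A [wg_graph()] with `n` nodes and `e` edges.
#' @export
gen_dnfa_wg <- function(n, e, sigma, d, seed = 1L) {
  prof <- solve_dnfa_profile(n, e, sigma, d)
  labels <- LETTERS[seq_len(sigma)]
  if (sigma > 26L) labels <- sprintf("L%02d", seq_len(sigma))
  nm <- pad_names(n)
  lo <- 1L + c(1L, utils::head(cumsum(prof$n_i), -1L) + 1L)
  from <- character(); to <- character(); lab <- character()
  with_seed(seed, {
    for (i in seq_len(sigma)) {
      mult <- rep.int(seq_len(d), prof$x[i, ])     # out-multiplicities
      S <- length(mult)
      srcs <- sample(n, S)                         # shuffled source choice
      o <- order(srcs)
      srcs <- srcs[o]; mult <- mult[o]             # rank order
      slots_src <- rep.int(srcs, mult)
      n_slots <- length(slots_src)
      # monotone surjection onto n_i destinations: within-source slot gaps
      # must step (distinct destinations); distribute the remaining steps
      # over the between-source gaps. Gap g sits between slots g and g+1.
      within <- unlist(lapply(mult, function(m) c(FALSE, rep(TRUE, m - 1L))),
                       use.names = FALSE)[-1L]
      step <- within
      n_extra <- prof$n_i[i] - (1L + sum(within))
      between <- which(!within)
      if (n_extra > 0L)
        step[between[sort(sample(length(between), n_extra))]] <- TRUE
      dest_off <- cumsum(c(1L, as.integer(step)))
      from <- c(from, nm[slots_src])
      to <- c(to, nm[lo[i] - 1L + dest_off])
      lab <- c(lab, rep(labels[i], n_slots))
    }
  })
  wg_graph(from, to, lab, nodes = nm)
}
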