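# Shared fixtures and independent reference implementations.

mk_g <- function(from = character(), to = character(), label = character(),
                 nodes = NULL) {
  wg_graph(from, to, label, nodes = nodes)
}

# uniform random labeled digraph (duplicate triples dropped)
rand_graph <- function(n, e, sigma, seed) {
  set.seed(seed)
  nm <- paste0("n", seq_len(n))
  from <- sample(nm, e, replace = TRUE)
  to <- sample(nm, e, replace = TRUE)
  lab <- sample(LETTERS[seq_len(sigma)], e, replace = TRUE)
  keep <- !duplicated(paste(from, to, lab))
  wg_graph(from[keep], to[keep], lab[keep], nodes = nm)
}

# add or delete one random edge of a graph
perturb_graph <- function(g, seed) {
  set.seed(seed)
  ed <- g$edges
  labs <- if (length(g$alphabet)) g$alphabet else "A"
  if (nrow(ed) > 1 && runif(1) < 0.5) {
    drop <- sample(nrow(ed), 1)
    wg_graph(ed$from[-drop], ed$to[-drop], ed$label[-drop], nodes = g$nodes)
  } else {
    for (i in 1:20) {
      u <- sample(g$nodes, 1); v <- sample(g$nodes, 1); l <- sample(labs, 1)
      if (!any(ed$from == u & ed$to == v & ed$label == l))
        return(wg_graph(c(ed$from, u), c(ed$to, v), c(ed$label, l),
                        nodes = g$nodes))
    }
    g
  }
}

# direct triple-loop implementation of the Wheeler conditions, independent
# of check_wheeler's vectorized shortcuts
naive_check_wheeler <- function(g, ord) {
  r <- ord[g$nodes]
  indeg <- table(factor(g$edges$to, levels = g$nodes))
  roots <- g$nodes[indeg == 0]
  others <- setdiff(g$nodes, roots)
  if (length(roots) && length(others) && max(r[roots]) > min(r[others]))
    return(FALSE)
  ed <- g$edges
  e <- nrow(ed)
  if (e < 2) return(TRUE)
  for (a in seq_len(e - 1)) for (b in (a + 1):e) {
    la <- ed$label[a]; lb <- ed$label[b]
    ra <- r[[ed$from[a]]]; rb <- r[[ed$from[b]]]
    va <- r[[ed$to[a]]]; vb <- r[[ed$to[b]]]
    if (la == lb) {
      if ((ra < rb && va > vb) || (rb < ra && vb > va)) return(FALSE)
    } else if (la < lb) {
      if (va >= vb) return(FALSE)
    } else {
      if (vb >= va) return(FALSE)
    }
  }
  TRUE
}

# quadratic same-label crossing counter
naive_crossings <- function(g, ord) {
  r <- ord[g$nodes]
  ed <- g$edges
  cnt <- 0L
  if (nrow(ed) < 2) return(0L)
  for (a in seq_len(nrow(ed) - 1)) for (b in (a + 1):nrow(ed)) {
    if (ed$label[a] != ed$label[b]) next
    du <- r[[ed$from[a]]] - r[[ed$from[b]]]
    dv <- r[[ed$to[a]]] - r[[ed$to[b]]]
    if (du * dv < 0) cnt <- cnt + 1L
  }
  cnt
}

# all valid Wheeler orderings of a tiny graph (exhaustive, n <= 6)
all_valid_orderings <- function(g) {
  n <- length(g$nodes)
  stopifnot(n <= 6)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  res <- list()
  for (p in perms(seq_len(n))) {
    ord <- stats::setNames(p, g$nodes)
    if (naive_check_wheeler(g, ord)) res[[length(res) + 1]] <- ord
  }
  res
}

verdicts_all <- function(g, timeout = 30) {
  c(pr = wheelie_pr(g, renaming_heuristic(g), wg_config("pr", timeout = timeout))$verdict,
    smt = wheelie_smt(g, wg_config("smt", timeout = timeout))$verdict,
    pure = pure_smt(g, wg_config("pure-smt", timeout = timeout))$verdict,
    brute = brute_force_recognize(g)$verdict)
}

msa_from_rows <- function(rows) {
  ids <- sprintf("s%d", seq_along(rows))
  structure(list(ids = ids, seqs = stats::setNames(toupper(rows), ids)),
            class = "wg_msa")
}
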