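# Solvers resolving the tie groups left by the renaming heuristic:
# Wheelie-Pr (exhaustive permutations within tie groups), Wheelie-SMT and a
# pure constraint mode (integer difference logic formulas discharged by the
# package's built-in IDL solver), plus the `recognize()` orchestrator.

#' Solver configuration
#'
#' @param solver one of `"smt"` (renaming heuristic + IDL constraint solver,
#'   the default), `"pr"` (renaming heuristic + exhaustive tie-group
#'   permutations), `"pure-smt"` (IDL encoding of the full definition,
#'   without the heuristic) or `"brute"` (factorial search over all node
#'   permutations; small graphs only).
#' @param timeout wall-clock budget in seconds (default 30).
#' @param exhaustive logical; for `"pr"`, disable early stopping and run
#'   the permutation search to completion (a found ordering is still
#'   reported at the end).
#' @param seed integer carried in the configuration for callers that pair a
#'   recognition run with seeded generation; the solvers themselves are
#'   deterministic.
#' @return An object of class `wg_config`.
#' @export
wg_config <- function(solver = c("smt", "pr", "pure-smt", "brute"),
                      timeout = 30, exhaustive = FALSE, seed = 1L) {
  solver <- match.arg(solver)
  if (!is.numeric(timeout) || timeout <= 0) stop("timeout must be > 0")
  structure(list(solver = solver, timeout = timeout,
                 exhaustive = isTRUE(exhaustive), seed = as.integer(seed)),
            class = "wg_config")
}

# ---------------------------------------------------------------------------
# IDL encoding

# Append a family of clauses to an accumulator. li/lj/lc are literal
# vectors; len gives the clause lengths (recycled).
add_clauses <- function(acc, li, lj, lc, len) {
  if (!length(li)) return(acc)
  acc$li <- c(acc$li, as.integer(li))
  acc$lj <- c(acc$lj, as.integer(lj))
  acc$lc <- c(acc$lc, as.integer(lc))
  nlit <- length(li)
  ncl <- nlit / len
  acc$lens <- c(acc$lens, rep.int(as.integer(len), ncl))
  acc
}

#' Encode the Wheeler recognition problem as an IDL formula
#'
#' One integer variable per node (its rank). All atoms have the form
#' `x_i - x_j <= c`; strict inequalities use `c = -1`. In pure mode
#' (`state = NULL`) the formula carries the full definition: range clauses
#' `1 <= v <= n`, root-first clauses placing every 0-indegree node before
#' every other node, condition (i) clauses `v - v' <= -1` for every edge
#' pair with ordered distinct labels, condition (ii) clauses
#' `(u' - u <= 0) | (v - v' <= 0)` for every ordered pair of same-label
#' edges, and pairwise all-different clauses over all nodes. In range mode
#' (`state` from [renaming_heuristic()]) the per-node ranges come from the
#' heuristic, condition (i) and root-first clauses are implied by the
#' ranges and omitted, and all-different is restricted to tie groups.
#'
#' @param g a [wg_graph()].
#' @param state optional `wg_heuristic` state for range mode.
#' @return An object of class `wg_smt` with the literal arrays, clause
#'   offsets, the node-variable map, and clause counts per family in
#'   `$meta`.
#' @export
encode_smt <- function(g, state = NULL) {
  stopifnot(inherits(g, "wg_graph"))
  gi <- graph_int(g)
  n <- gi$n
  acc <- list(li = integer(), lj = integer(), lc = integer(),
              lens = integer())
  meta <- list(range = 0L, root_first = 0L, cond1 = 0L, cond2 = 0L,
               alldiff = 0L)

  if (is.null(state)) {
    lo <- rep.int(1L, n); hi <- rep.int(n, n)
  } else {
    stopifnot(inherits(state, "wg_heuristic"),
              identical(state$ranges$node, g$nodes))
    lo <- state$ranges$lo; hi <- state$ranges$hi
  }
  # range clauses: v - x0 <= hi ; x0 - v <= -lo
  if (n) {
    acc <- add_clauses(acc, seq_len(n), rep.int(0L, n), hi, 1L)
    acc <- add_clauses(acc, rep.int(0L, n), seq_len(n), -lo, 1L)
    meta$range <- 2L * n
  }

  if (is.null(state)) {
    # root-first: every 0-indegree node strictly before every other node
    indeg <- tabulate(gi$to, nbins = n)
    roots <- which(indeg == 0L); others <- which(indeg > 0L)
    if (length(roots) && length(others)) {
      ri <- rep(roots, each = length(others))
      oi <- rep(others, times = length(roots))
      acc <- add_clauses(acc, ri, oi, rep.int(-1L, length(ri)), 1L)
      meta$root_first <- length(ri)
    }
    # condition (i): for every edge pair with labels a < a': v - v' <= -1
    if (gi$e && gi$sigma > 1L) {
      by_lab <- split(seq_len(gi$e), gi$lab)
      labs <- as.integer(names(by_lab))
      for (a in seq_along(labs)) for (b in seq_along(labs)) {
        if (labs[a] >= labs[b]) next
        ea <- by_lab[[a]]; eb <- by_lab[[b]]
        va <- rep(gi$to[ea], each = length(eb))
        vb <- rep(gi$to[eb], times = length(ea))
        acc <- add_clauses(acc, va, vb, rep.int(-1L, length(va)), 1L)
        meta$cond1 <- meta$cond1 + length(va)
      }
    }
  }

  # condition (ii): for every ordered pair (p, q) of distinct same-label
  # edges: (u_q - u_p <= 0) | (v_p - v_q <= 0)
  if (gi$e > 1L) {
    for (idx in split(seq_len(gi$e), gi$lab)) {
      m <- length(idx)
      if (m < 2L) next
      p <- rep(idx, each = m); q <- rep(idx, times = m)
      keep <- p != q
      p <- p[keep]; q <- q[keep]
      li <- as.vector(rbind(gi$from[q], gi$to[p]))
      lj <- as.vector(rbind(gi$from[p], gi$to[q]))
      acc <- add_clauses(acc, li, lj, rep.int(0L, length(li)), 2L)
      meta$cond2 <- meta$cond2 + length(p)
    }
  }

  # all-different, pairwise: (x - y <= -1) | (y - x <= -1)
  pair_groups <- if (is.null(state)) {
    if (n > 1L) list(seq_len(n)) else list()
  } else {
    Filter(function(gr) length(gr) > 1L, unname(tie_groups(state)))
  }
  for (gr in pair_groups) {
    m <- length(gr)
    # pairs (x, y), x < y in index order
    xi <- rep(gr[-m], times = (m - 1L):1L)
    yi <- unlist(lapply(seq_len(m - 1L), function(a) gr[(a + 1L):m]))
    li <- as.vector(rbind(xi, yi))
    lj <- as.vector(rbind(yi, xi))
    acc <- add_clauses(acc, li, lj, rep.int(-1L, length(li)), 2L)
    meta$alldiff <- meta$alldiff + length(xi)
  }

  cl_start <- c(0L, cumsum(acc$lens))
  # starting assignment hint for the solver: any bijection is legal; one
  # that satisfies the unit clause families (roots first, destination
  # blocks in label order; in range mode, the heuristic ranges) leaves
  # only genuine ordering decisions to the search
  init <- integer(n)
  if (n) {
    if (is.null(state)) {
      in_lab <- rep.int(0L, n)
      if (gi$e) in_lab[gi$to] <- gi$lab
      init[order(in_lab, seq_len(n))] <- seq_len(n)
    } else {
      init[order(lo, seq_len(n))] <- seq_len(n)
    }
  }
  structure(list(
    vars = g$nodes, n = n,
    cl_start = cl_start, li = acc$li, lj = acc$lj, lc = acc$lc,
    lo = lo, hi = hi, init = init,
    mode = if (is.null(state)) "pure" else "range",
    meta = c(meta, list(total = length(acc$lens)))
  ), class = "wg_smt")
}

#' @export
print.wg_smt <- function(x, ...) {
  cat(sprintf("IDL formula (%s mode): %d variables, %d clauses\n",
              x$mode, x$n, x$meta$total))
  cat(sprintf(
    "  range %d | root-first %d | condition-(i) %d | condition-(ii) %d | all-different %d\n",
    x$meta$range, x$meta$root_first, x$meta$cond1, x$meta$cond2,
    x$meta$alldiff))
  invisible(x)
}

#' Solve an IDL formula
#'
#' Discharges the formula with the package's built-in model-guided DPLL
#' solver for integer difference logic and, on satisfiability, decodes the
#' integer model into a node ordering (model values are pinned to `1..n` by
#' the range and all-different clauses).
#'
#' @param f a `wg_smt` formula from [encode_smt()].
#' @param cfg a [wg_config()]; only the `timeout` is used.
#' @return A list with `sat` (`TRUE`, `FALSE`, or `NA` for timeout),
#'   `model` (a node ordering, or `NULL`), and solver `stats`.
#' @export
solve_smt <- function(f, cfg = wg_config()) {
  stopifnot(inherits(f, "wg_smt"))
  n <- f$n
  if (n == 0L)
    return(list(sat = TRUE, model = integer(), stats = list(decisions = 0)))
  res <- .idl_solve_cpp(n, f$cl_start, f$li, f$lj, f$lc,
                        c(0L, f$init), as.double(cfg$timeout))
  if (res$status == "sat") {
    vals <- as.integer(res$model)
    if (!setequal(vals, seq_len(n)))
      stop("internal error: IDL model is not a rank bijection")
    ord <- stats::setNames(vals, f$vars)
    st <- list(decisions = res$decisions, probes = res$probes,
               assertions = res$assertions)
    list(sat = TRUE, model = ord, stats = st)
  } else {
    st <- list(decisions = res$decisions, probes = res$probes,
               assertions = res$assertions)
    list(sat = if (res$status == "unsat") FALSE else NA, model = NULL,
         stats = st)
  }
}

#' Export an IDL formula as SMT-LIB 2 text
#'
#' Writes the formula in the `QF_IDL` logic so it can be cross-checked with
#' any SMT-LIB 2 compliant solver. Variable `x0` is the fixed reference
#' point of the difference constraints.
#'
#' @param f a `wg_smt` formula.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_smt2 <- function(f, path) {
  stopifnot(inherits(f, "wg_smt"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("(set-logic QF_IDL)", con)
  writeLines("(declare-const x0 Int)", con)
  writeLines("(assert (= x0 0))", con)
  if (f$n)
    writeLines(c(sprintf("(declare-const x%d Int)", seq_len(f$n)),
                 sprintf("; x%d := node %s", seq_len(f$n), f$vars)), con)
  K <- length(f$cl_start) - 1L
  lit <- sprintf("(<= (- x%d x%d) %d)", f$li, f$lj, f$lc)
  cls <- vapply(seq_len(K), function(k) {
    rng <- (f$cl_start[k] + 1L):f$cl_start[k + 1L]
    if (length(rng) == 1L) lit[rng]
    else paste0("(or ", paste(lit[rng], collapse = " "), ")")
  }, character(1))
  if (K) writeLines(sprintf("(assert %s)", cls), con)
  writeLines(c("(check-sat)", "(get-model)"), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Recognition results

wg_recognition <- function(verdict, ordering = NULL, violation = NULL,
                           stats = list(), index = NULL) {
  structure(list(verdict = verdict, ordering = ordering,
                 violation = violation, stats = stats, index = index),
            class = "wg_recognition")
}

#' @export
print.wg_recognition <- function(x, ...) {
  cat("Wheeler graph recognition\n")
  cat("  verdict:", x$verdict, "\n")
  if (!is.null(x$stats$solver)) cat("  solver:", x$stats$solver, "\n")
  if (!is.null(x$ordering)) {
    o <- x$ordering[order(x$ordering)]
    shown <- utils::head(o, 12L)
    cat("  ordering:", paste(names(shown), shown, sep = "=", collapse = " "),
        if (length(o) > 12L) "..." else "", "\n")
  }
  if (!is.null(x$violation)) cat("  violation:", x$violation, "\n")
  if (!is.null(x$stats$heuristic_iterations))
    cat(sprintf("  heuristic: %d iterations, %d tie groups (largest %d)\n",
                x$stats$heuristic_iterations, x$stats$tie_groups,
                x$stats$largest_tie_group))
  invisible(x)
}

#' @export
summary.wg_recognition <- function(object, ...) {
  print(object)
  if (!is.null(object$index)) print(object$index)
  invisible(object)
}

heuristic_stats <- function(state, solver) {
  tg <- if (is.null(state$conflict)) lengths(tie_groups(state)) else integer()
  list(solver = solver,
       heuristic_iterations = state$iteration,
       tie_groups = length(tg),
       largest_tie_group = if (length(tg)) max(tg) else 0L)
}

# ---------------------------------------------------------------------------
# Wheelie-Pr: exhaustive permutations within tie groups

# lexicographic successor of a permutation, or NULL when exhausted
next_perm <- function(p) {
  n <- length(p)
  if (n < 2L) return(NULL)
  i <- n - 1L
  while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
  if (i < 1L) return(NULL)
  j <- n
  while (p[j] <= p[i]) j <- j - 1L
  tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
  p[(i + 1L):n] <- rev(p[(i + 1L):n])
  p
}

#' Wheelie-Pr: resolve tie groups by exhaustive permutation search
#'
#' Enumerates the Cartesian product of permutations within each tie group
#' (groups in rank order, permutations in lexicographic order of node
#' identifiers), pruning assignments as soon as a same-label order
#' violation appears among the already-determined nodes. Root-placement and
#' label-block order are fixed by the heuristic ranges and need no search.
#'
#' @param g a [wg_graph()].
#' @param state a `wg_heuristic` state from [renaming_heuristic()].
#' @param cfg a [wg_config()]; `timeout` caps the search, `exhaustive`
#'   disables early stopping.
#' @return A `wg_recognition` result.
#' @export
wheelie_pr <- function(g, state = renaming_heuristic(g), cfg = wg_config("pr")) {
  stopifnot(inherits(g, "wg_graph"), inherits(state, "wg_heuristic"))
  stats <- heuristic_stats(state, "pr")
  if (!is.null(state$conflict))
    return(wg_recognition("not_wheeler", violation = state$conflict,
                          stats = stats))
  gi <- graph_int(g)
  groups <- unname(tie_groups(state))
  glo <- vapply(groups, function(gr) state$ranges$lo[gr[1L]], integer(1))

  rank <- rep(NA_integer_, gi$n)
  # per-label determined edge ranks, grown as groups are assigned
  det_u <- vector("list", gi$sigma); det_v <- vector("list", gi$sigma)
  for (l in seq_len(gi$sigma)) { det_u[[l]] <- integer(); det_v[[l]] <- integer() }
  # edges indexed by the group at which they become determined
  t_start <- Sys.time()
  env <- new.env(parent = emptyenv())
  env$found <- NULL; env$timeout <- FALSE; env$assignments <- 0

  ends_det <- function(edge_idx) !anyNA(rank[c(gi$from[edge_idx], gi$to[edge_idx])])

  search <- function(k) {
    if (env$timeout || (!is.null(env$found) && !cfg$exhaustive)) return()
    if (k > length(groups)) {
      env$assignments <- env$assignments + 1
      chk <- check_wheeler(g, stats::setNames(rank, g$nodes))
      if (chk$valid && is.null(env$found))
        env$found <- stats::setNames(rank, g$nodes)
      return()
    }
    if (as.double(Sys.time() - t_start, units = "secs") > cfg$timeout) {
      env$timeout <- TRUE
      return()
    }
    gr <- groups[[k]]
    m <- length(gr)
    perm <- seq_len(m)
    repeat {
      rank[gr] <<- glo[k] + perm - 1L
      # incremental prune: edges newly determined by this group
      new_e <- which((gi$from %in% gr | gi$to %in% gr) &
                       !is.na(rank[gi$from]) & !is.na(rank[gi$to]))
      ok <- TRUE
      saved <- list()
      for (ei in new_e) {
        l <- gi$lab[ei]
        ru <- rank[gi$from[ei]]; rv <- rank[gi$to[ei]]
        du <- det_u[[l]]; dv <- det_v[[l]]
        if (length(du) &&
            any((du < ru & dv > rv) | (du > ru & dv < rv))) { ok <- FALSE; break }
        det_u[[l]] <<- c(du, ru); det_v[[l]] <<- c(dv, rv)
        saved[[length(saved) + 1L]] <- l
      }
      if (ok) search(k + 1L)
      # undo
      for (l in rev(unlist(saved))) {
        det_u[[l]] <<- det_u[[l]][-length(det_u[[l]])]
        det_v[[l]] <<- det_v[[l]][-length(det_v[[l]])]
      }
      rank[gr] <<- NA_integer_
      if (env$timeout || (!is.null(env$found) && !cfg$exhaustive)) return()
      perm <- next_perm(perm)
      if (is.null(perm)) return()
    }
  }
  search(1L)

  stats$assignments_tested <- env$assignments
  if (env$timeout && is.null(env$found))
    return(wg_recognition("timeout", stats = stats))
  if (!is.null(env$found))
    return(wg_recognition("wheeler", ordering = env$found, stats = stats))
  wg_recognition("not_wheeler",
                 violation = "exhausted all tie-group permutations without finding a valid ordering",
                 stats = stats)
}

# ---------------------------------------------------------------------------
# Wheelie-SMT and pure constraint mode

#' Wheelie-SMT: renaming heuristic plus IDL constraint solving
#'
#' Runs the renaming heuristic; a label conflict is an immediate
#' non-Wheeler verdict, a totally resolved order is verified directly, and
#' anything in between is encoded in range mode and discharged by the IDL
#' solver. Any model is verified with [check_wheeler()] before a Wheeler
#' verdict is reported.
#'
#' @param g a [wg_graph()].
#' @param cfg a [wg_config()].
#' @return A `wg_recognition` result.
#' @export
wheelie_smt <- function(g, cfg = wg_config("smt")) {
  stopifnot(inherits(g, "wg_graph"))
  state <- renaming_heuristic(g)
  stats <- heuristic_stats(state, "smt")
  if (!is.null(state$conflict))
    return(wg_recognition("not_wheeler", violation = state$conflict,
                          stats = stats))
  if (is_totally_resolved(state)) {
    ord <- stats::setNames(state$ranges$lo, g$nodes)
    chk <- check_wheeler(g, ord)
    if (chk$valid)
      return(wg_recognition("wheeler", ordering = ord, stats = stats))
    return(wg_recognition("not_wheeler", violation = chk$violation,
                          stats = stats))
  }
  f <- encode_smt(g, state)
  stats$clauses <- f$meta$total
  res <- solve_smt(f, cfg)
  stats <- c(stats, res$stats)
  if (isTRUE(res$sat)) {
    chk <- check_wheeler(g, res$model)
    if (!chk$valid)
      stop("internal error: IDL model failed Wheeler verification: ",
           chk$violation)
    wg_recognition("wheeler", ordering = res$model, stats = stats)
  } else if (identical(res$sat, FALSE)) {
    wg_recognition("not_wheeler",
                   violation = "no ordering within the heuristic ranges satisfies the Wheeler constraints",
                   stats = stats)
  } else {
    wg_recognition("timeout", stats = stats)
  }
}

#' Pure constraint-mode recognition (no renaming heuristic)
#'
#' Encodes the complete Wheeler definition as an IDL formula over all nodes
#' (ranges `1..n`, root-first, conditions (i) and (ii), global
#' all-different) and solves it from scratch. Exists mainly to quantify how
#' much the renaming heuristic prunes; semantics are identical to
#' [wheelie_smt()].
#'
#' @inheritParams wheelie_smt
#' @return A `wg_recognition` result.
#' @export
pure_smt <- function(g, cfg = wg_config("pure-smt")) {
  stopifnot(inherits(g, "wg_graph"))
  f <- encode_smt(g, state = NULL)
  stats <- list(solver = "pure-smt", clauses = f$meta$total)
  res <- solve_smt(f, cfg)
  stats <- c(stats, res$stats)
  if (isTRUE(res$sat)) {
    chk <- check_wheeler(g, res$model)
    if (!chk$valid)
      stop("internal error: IDL model failed Wheeler verification: ",
           chk$violation)
    wg_recognition("wheeler", ordering = res$model, stats = stats)
  } else if (identical(res$sat, FALSE)) {
    wg_recognition("not_wheeler",
                   violation = "the Wheeler constraint system is unsatisfiable",
                   stats = stats)
  } else {
    wg_recognition("timeout", stats = stats)
  }
}

#' Recognize whether a graph is a Wheeler graph
#'
#' The top-level entry point: dispatches to the configured solver and, on a
#' Wheeler verdict, attaches the witness ordering and the O/I/L index built
#' from it.
#'
#' @param g a [wg_graph()].
#' @param cfg a [wg_config()] choosing the solver, timeout and search mode.
#' @return A `wg_recognition` result: `verdict` (`"wheeler"`,
#'   `"not_wheeler"` or `"timeout"`), `ordering` (witness, if Wheeler),
#'   `violation` (certificate, if not), `stats`, and `index` (a `wg_index`,
#'   if Wheeler).
#' @examples
#' g <- parse_dot('digraph { r -> x [label="A"]; r -> y [label="A"]; }')
#' recognize(g)
#' @export
recognize <- function(g, cfg = wg_config()) {
  stopifnot(inherits(g, "wg_graph"))
  if (!inherits(cfg, "wg_config"))
    stop("usage error: cfg must be a wg_config()")
  res <- switch(cfg$solver,
    "pr" = wheelie_pr(g, renaming_heuristic(g), cfg),
    "smt" = wheelie_smt(g, cfg),
    "pure-smt" = pure_smt(g, cfg),
    "brute" = brute_force_recognize(g),
    stop("usage error: unknown solver '", cfg$solver, "'"))
  if (res$verdict == "wheeler" && is.null(res$index))
    res$index <- build_index(g, res$ordering)
  res
}
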