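# Ground-truth recognizers and search-space arithmetic: a factorial
# brute-force recognizer, the O/I/L enumeration baseline (the reduced
# variant without the isomorphism inner loop), and the exact comparison of
# the two algorithms' search-space sizes.

#' Brute-force Wheeler graph recognition
#'
#' Tries every bijection node -> 1..n in identifier-lexicographic
#' permutation order and returns the first ordering that satisfies the
#' Wheeler conditions. The reference oracle for all solver-equivalence
#' checks; refuses graphs with more than 9 nodes.
#'
#' @param g a [wg_graph()] with `n <= 9`.
#' @return A `wg_recognition` result (never a timeout).
#' @export
brute_force_recognize <- function(g) {
  stopifnot(inherits(g, "wg_graph"))
  gi <- graph_int(g)
  if (gi$n > 9L)
    stop("brute-force recognition refuses graphs with n > 9 (factorial search); n = ",
         gi$n)
  if (gi$n == 0L)
    return(wg_recognition("wheeler", ordering = integer(),
                          stats = list(solver = "brute", orderings_tried = 0)))
  res <- .brute_force_cpp(gi$n, gi$from, gi$to, gi$lab)
  stats <- list(solver = "brute", orderings_tried = res$tried)
  if (isTRUE(res$found)) {
    ord <- stats::setNames(as.integer(res$rank), g$nodes)
    wg_recognition("wheeler", ordering = ord, stats = stats)
  } else {
    wg_recognition("not_wheeler",
                   violation = "exhausted all node permutations without finding a valid ordering",
                   stats = stats)
  }
}

# ---------------------------------------------------------------------------
# Exact big-integer arithmetic (factorials up to a few hundred fit easily;
# numbers are little-endian digit vectors in base 2^26, held in doubles).

BIGBASE <- 2^26

big_from_int <- function(x) {
  d <- numeric(0)
  while (x > 0) { d <- c(d, x %% BIGBASE); x <- x %/% BIGBASE }
  if (!length(d)) d <- 0
  d
}

big_mul_small <- function(d, m) {
  carry <- 0
  for (i in seq_along(d)) {
    v <- d[i] * m + carry
    d[i] <- v %% BIGBASE
    carry <- v %/% BIGBASE
  }
  while (carry > 0) { d <- c(d, carry %% BIGBASE); carry <- carry %/% BIGBASE }
  d
}

big_factorial <- function(n) {
  d <- big_from_int(1)
  for (m in seq_len(n)) d <- big_mul_small(d, m)
  d
}

# number of binary digits of a big number (0 for value 0)
big_bits <- function(d) {
  top <- max(which(d != 0), 1L)
  if (d[top] == 0) return(0L)
  as.integer((top - 1L) * 26L + floor(log2(d[top])) + 1L)
}

# compare 2^k with the big number d: -1, 0, 1
big_cmp_pow2 <- function(k, d) {
  bits <- big_bits(d)
  if (k + 1L < bits) return(-1L)
  if (k + 1L > bits) return(1L)
  # same bit length: 2^k <= d always; equal iff d is exactly a power of two
  pos <- k %% 26L; word <- k %/% 26L + 1L
  exact <- d[word] == 2^pos && all(d[-word] == 0)
  if (exact) 0L else -1L
}

#' Largest C with 2^(2n + C) <= n!
#'
#' The crossover constant between the exponential O/I/L-enumeration search
#' space, of size 2^(2(n+e) + e log2 sigma) = 2^(2n + C) with
#' C = e(2 + log2 sigma), and the factorial permutation search space n!.
#' Computed exactly: `C = floor(log2 n!) - 2n`, with the floor taken from
#' the bit length of the exact factorial.
#'
#' @param n number of nodes (>= 1).
#' @return Integer `C`.
#' @examples
#' search_space_C(100)  # 324
#' @export
search_space_C <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("n must be a single integer >= 1")
  n <- as.integer(n)
  big_bits(big_factorial(n)) - 1L - 2L * n
}

#' Compare the enumeration and permutation search spaces
#'
#' Reports, in log2 units, the worst-case search-space sizes of the
#' O/I/L-array enumeration (`2^(2(n+e) + e log2 sigma)`) and of the node
#' permutation search (`n!`), together with the exact crossover constant
#' from [search_space_C()].
#'
#' @param n,e node and edge counts (`n, e >= 0`).
#' @param sigma alphabet size (`>= 1`).
#' @return An object of class `wg_space_report` with fields `n`, `e`,
#'   `sigma`, `gt_log2`, `wheelie_log2`, `C`, `C_actual` (= `e (2 + log2
#'   sigma)`), and `smaller` (which side has the smaller space).
#' @export
compare_search_spaces <- function(n, e, sigma) {
  if (n < 0 || e < 0 || sigma < 1) stop("need n, e >= 0 and sigma >= 1")
  gt_log2 <- 2 * (n + e) + e * log2(sigma)
  wheelie_log2 <- if (n > 1) sum(log2(seq_len(n))) else 0
  rep <- list(n = n, e = e, sigma = sigma,
              gt_log2 = gt_log2,
              wheelie_log2 = wheelie_log2,
              C = if (n >= 1) search_space_C(n) else NA_integer_,
              C_actual = e * (2 + log2(sigma)),
              smaller = if (gt_log2 < wheelie_log2) "enumeration"
                        else if (gt_log2 > wheelie_log2) "permutation"
                        else "equal")
  class(rep) <- "wg_space_report"
  rep
}

#' @export
print.wg_space_report <- function(x, ...) {
  cat("Search-space comparison (log2 scale)\n")
  cat(sprintf("  n=%d  e=%d  sigma=%d\n", x$n, x$e, x$sigma))
  cat(sprintf("  enumeration (O/I/L): 2(n+e) + e*log2(sigma) = %.2f bits\n",
              x$gt_log2))
  cat(sprintf("  permutation (n!):    log2(n!)              = %.2f bits\n",
              x$wheelie_log2))
  cat(sprintf("  crossover constant C (largest with 2^(2n+C) <= n!): %d\n",
              x$C))
  cat(sprintf("  actual C = e(2 + log2 sigma) = %.2f -> %s side smaller\n",
              x$C_actual, x$smaller))
  invisible(x)
}

# ---------------------------------------------------------------------------
# O/I/L enumeration baseline

# all compositions of e into n non-negative parts (list of integer vectors)
compositions <- function(e, n) {
  if (n == 0L) return(if (e == 0L) list(integer()) else list())
  if (n == 1L) return(list(e))
  out <- list()
  for (first in 0:e) {
    rest <- compositions(e - first, n - 1L)
    out <- c(out, lapply(rest, function(r) c(first, r)))
  }
  out
}

# all distinct permutations of a label multiset (character vector)
multiset_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    out <- c(out, lapply(multiset_perms(rest), function(r) c(v, r)))
  }
  out
}

#' Enumerate O/I/L array candidates (reduced baseline)
#'
#' The enumeration core of the exponential recognition algorithm that
#' searches over all O, I bitstrings of length `n + e` with `n` ones and
#' all label strings `L` with the graph's label multiset, counting the
#' triples that pass cheap consistency screens (well-formed unary codes, a
#' zero-indegree prefix, per-label indegree block sums, within-source
#' non-decreasing labels). The expensive graph-isomorphism inner loop is
#' deliberately omitted, so this baseline never decides Wheelerness: the
#' verdict is always `"unknown"`. It exists to ground the search-space
#' comparison, not to recognize graphs.
#'
#' @param g a tiny [wg_graph()].
#' @param work_bound refuse if the enumeration space
#'   `C(n+e, n)^2 * perms(L)` exceeds this (default `1e6`).
#' @return list with `count` (consistent candidate triples), `verdict`
#'   (always `"unknown"`), and `space` (the enumeration-space size).
#' @export
gt_enumeration <- function(g, work_bound = 1e6) {
  stopifnot(inherits(g, "wg_graph"))
  gi <- graph_int(g)
  n <- gi$n; e <- gi$e
  if (n == 0L) return(list(count = 0, verdict = "unknown", space = 0))
  lab_counts <- table(factor(g$edges$label, levels = g$alphabet))
  n_L <- if (e) exp(lfactorial(e) - sum(lfactorial(lab_counts))) else 1
  space <- choose(n + e, n)^2 * n_L
  if (space > work_bound)
    stop("enumeration space ", format(space), " exceeds work bound ",
         format(work_bound))

  os <- compositions(e, n)   # candidate outdegree sequences (well-formed O)
  is_ <- compositions(e, n)  # candidate indegree sequences (well-formed I)
  cnt <- as.integer(lab_counts)

  # I consistency: zero-indegree prefix, then label blocks whose sums hit
  # the label counts exactly at node boundaries
  i_ok <- vapply(is_, function(iv) {
    pos <- iv > 0L
    if (any(!pos & cumsum(pos) > 0L)) return(FALSE)  # zero after positive
    cs <- cumsum(iv[pos])
    all(cumsum(cnt) %in% cs) || !length(cnt)
  }, logical(1))
  n_i_ok <- sum(i_ok)

  # L x O consistency: within each source block of O, labels non-decreasing
  Ls <- multiset_perms(sort_cp(g$edges$label))
  count <- 0
  for (ov in os) {
    ends <- cumsum(ov); starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (lv in Ls) {
      ok <- TRUE
      for (b in seq_len(n)) {
        if (ov[b] < 2L) next
        blk <- match(lv[starts[b]:ends[b]], g$alphabet)
        if (any(diff(blk) < 0L)) { ok <- FALSE; break }
      }
      if (ok) count <- count + n_i_ok
    }
  }
  list(count = count, verdict = "unknown", space = space)
}
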