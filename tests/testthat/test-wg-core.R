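# Graph data model, DOT round trips, Wheeler-property checking and O/I/L
# index construction.

test_that("parse_dot reads labeled digraphs and rejects bad input", {
  g <- parse_dot('digraph{a->b[label="A"]}')
  expect_equal(length(g$nodes), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$alphabet, "A")

  g2 <- parse_dot('digraph{a->b[label="A"]; a->c[label="A"]; b->d[label="C"]}')
  expect_equal(length(g2$nodes), 4L)
  expect_equal(nrow(g2$edges), 3L)
  expect_equal(length(g2$alphabet), 2L)

  expect_error(parse_dot("digraph{a->b}"), "edge a->b has no label")
  expect_error(parse_dot('graph{a--b[label="A"]}'), "undirected")
  expect_warning(parse_dot('digraph{a->b[label="A"]; a->b[label="A"]}'),
                 "duplicate")
  g3 <- parse_dot('digraph{ a -> b [label="A"]; lonely; }')
  expect_true("lonely" %in% g3$nodes)
  expect_equal(nrow(g3$edges), 1L)
})

test_that("write_dot is deterministic and round-trips", {
  expect_identical(write_dot(wg_graph()), "digraph {\n}")
  g <- mk_g("a", "b", "A")
  expect_identical(write_dot(parse_dot(write_dot(g))), write_dot(g))
  # generator outputs round-trip with equal node/edge/label sets
  for (s in 1:3) {
    for (g in list(gen_complete_wg(8, 2, 1, seed = s)$graph,
                   gen_dnfa_wg(12, 18, 2, 2, seed = s),
                   gen_trie(random_msa(2, 10, seed = s)))) {
      h <- parse_dot(write_dot(g))
      expect_identical(h$nodes, g$nodes)
      expect_identical(h$alphabet, g$alphabet)
      expect_setequal(paste(h$edges$from, h$edges$to, h$edges$label),
                      paste(g$edges$from, g$edges$to, g$edges$label))
    }
  }
})

test_that("find_roots returns 0-indegree nodes sorted by identifier", {
  expect_identical(find_roots(mk_g("a", "b", "A")), "a")
  expect_identical(find_roots(mk_g(c("a", "b"), c("b", "a"), c("A", "A"))),
                   character())
  tr <- gen_trie(msa_from_rows(c("AC", "AG")))
  expect_length(find_roots(tr), 1L)
})

test_that("check_wheeler matches the definition on worked examples", {
  g <- mk_g("a", "b", "A")
  expect_true(check_wheeler(g, c(a = 1, b = 2))$valid)

  cyc <- mk_g(c("a", "b"), c("b", "a"), c("A", "A"))
  for (ord in list(c(a = 1, b = 2), c(a = 2, b = 1))) {
    res <- check_wheeler(cyc, ord)
    expect_false(res$valid)
    expect_match(res$violation, "condition \\(c\\)")
  }

  # two distinct incoming labels at one node: condition (b) with v = v'
  two <- mk_g(c("a", "b"), c("c", "c"), c("A", "B"))
  for (p in list(c(a=1,b=2,c=3), c(a=2,b=1,c=3), c(a=1,b=3,c=2))) {
    res <- check_wheeler(two, p)
    expect_false(res$valid)
  }

  expect_error(check_wheeler(g, c(a = 1, b = 1)), "bijection")
  expect_error(check_wheeler(g, c(a = 1, z = 2)), "nodes")
})

test_that("check_wheeler agrees with a naive triple-loop checker", {
  for (s in 1:60) {
    g <- rand_graph(sample(2:6, 1), sample(2:9, 1), sample(1:3, 1), seed = s)
    set.seed(1000 + s)
    ord <- stats::setNames(sample(length(g$nodes)), g$nodes)
    expect_identical(check_wheeler(g, ord)$valid, naive_check_wheeler(g, ord),
                     info = paste("seed", s))
  }
})

test_that("build_index produces the unary-coded O/I/L triple", {
  idx <- build_index(mk_g("a", "b", "A"), c(a = 1, b = 2))
  expect_identical(idx$O, "011")
  expect_identical(idx$I, "101")
  expect_identical(idx$L, "A")

  lone <- wg_graph(nodes = "x")
  idx2 <- build_index(lone, c(x = 1))
  expect_identical(idx2$O, "1")
  expect_identical(idx2$I, "1")
  expect_identical(idx2$L, "")

  expect_error(build_index(mk_g(c("a","b"), c("b","a"), c("A","A")),
                           c(a = 1, b = 2)), "not a valid")
})

test_that("index invariants hold on recognized generator outputs", {
  for (s in 1:4) {
    g <- gen_dnfa_wg(15, 24, 2, 2, seed = s)
    res <- recognize(g)
    expect_identical(res$verdict, "wheeler")
    n <- length(g$nodes); e <- nrow(g$edges)
    idx <- res$index
    expect_equal(nchar(idx$O), n + e)
    expect_equal(nchar(idx$I), n + e)
    zero_one <- function(x) sum(strsplit(x, "")[[1]] == "1")
    expect_equal(zero_one(idx$O), n)
    expect_equal(zero_one(idx$I), n)
    expect_equal(nchar(idx$L), e)
    expect_identical(sort(strsplit(idx$L, "")[[1]]), sort(g$edges$label))
  }
})

test_that("max_same_label_outdegree counts and is monotone under deletion", {
  expect_equal(max_same_label_outdegree(wg_graph(nodes = "a")), 0L)
  g <- mk_g(c("a", "a", "a"), c("b", "c", "d"), c("A", "A", "B"))
  expect_equal(max_same_label_outdegree(g), 2L)
  for (s in 1:10) {
    h <- rand_graph(5, 12, 2, seed = s)
    d0 <- max_same_label_outdegree(h)
    ed <- h$edges[-sample(nrow(h$edges), 1), ]
    h2 <- wg_graph(ed$from, ed$to, ed$label, nodes = h$nodes)
    expect_lte(max_same_label_outdegree(h2), d0)
  }
})

test_that("ordering and index files use the documented formats", {
  g <- mk_g("a", "b", "A")
  ordf <- tempfile(); idxf <- tempfile()
  write_ordering(c(b = 2, a = 1), ordf)
  expect_identical(readLines(ordf), c("a\t1", "b\t2"))
  write_index(build_index(g, c(a = 1, b = 2)), idxf)
  expect_identical(readLines(idxf), c("O:011", "I:101", "L:A"))
})
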