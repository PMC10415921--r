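# Tie-group solvers: exhaustive permutations, the IDL encodings, the
# built-in solver, and the recognize() orchestrator.

test_that("wheelie_pr resolves tie groups and reports the first witness", {
  tie <- mk_g(c("r", "r"), c("x", "y"), c("A", "A"))
  res <- wheelie_pr(tie)
  expect_identical(res$verdict, "wheeler")
  expect_identical(res$ordering[c("r", "x", "y")],
                   c(r = 1L, x = 2L, y = 3L))  # lexicographically first

  cyc <- mk_g(c("a", "b"), c("b", "a"), c("A", "A"))
  expect_identical(wheelie_pr(cyc)$verdict, "not_wheeler")

  # fully resolved state: single assignment tested
  p <- mk_g(c("v1", "v2"), c("v2", "v3"), c("A", "A"))
  res2 <- wheelie_pr(p)
  expect_identical(res2$verdict, "wheeler")
  expect_equal(res2$stats$assignments_tested, 1)
})

test_that("exhaustive Wheelie-Pr matches early-stopping verdicts", {
  for (s in 1:25) {
    g <- rand_graph(sample(3:6, 1), sample(3:8, 1), sample(1:2, 1), seed = s)
    st <- renaming_heuristic(g)
    v1 <- wheelie_pr(g, st)$verdict
    v2 <- wheelie_pr(g, st, wg_config("pr", exhaustive = TRUE))$verdict
    expect_identical(v1, v2, info = paste("seed", s))
  }
})

test_that("encode_smt emits the documented clause families", {
  lone <- wg_graph(nodes = "x")
  f <- encode_smt(lone)
  expect_identical(f$mode, "pure")
  expect_equal(f$meta$range, 2L)
  expect_equal(f$meta$cond1 + f$meta$cond2 + f$meta$alldiff + f$meta$root_first, 0L)
  expect_true(isTRUE(solve_smt(f)$sat))

  tie <- mk_g(c("r", "r"), c("x", "y"), c("A", "A"))
  st <- renaming_heuristic(tie)
  fr <- encode_smt(tie, st)
  expect_identical(fr$mode, "range")
  expect_equal(fr$meta$cond1, 0L)       # implied by ranges, omitted
  expect_equal(fr$meta$root_first, 0L)
  expect_equal(fr$meta$cond2, 2L)       # both orientations, shared source
  expect_equal(fr$meta$alldiff, 1L)     # single within-group pair (x, y)

  conflict <- mk_g(c("a", "b"), c("c", "c"), c("A", "B"))
  expect_identical(solve_smt(encode_smt(conflict))$sat, FALSE)
})

test_that("pure-mode formulas include the 0-indegree-first clauses", {
  # one edge plus an isolated node: without root-first clauses a model
  # could rank the edge head first even though the graph is Wheeler
  g <- mk_g("b", "a", "A", nodes = c("a", "b", "c"))
  f <- encode_smt(g)
  expect_gt(f$meta$root_first, 0L)
  res <- pure_smt(g)
  expect_identical(res$verdict, "wheeler")
  expect_true(check_wheeler(g, res$ordering)$valid)
})

test_that("solve_smt decodes models into rank bijections", {
  tie <- mk_g(c("r", "r"), c("x", "y"), c("A", "A"))
  res <- solve_smt(encode_smt(tie, renaming_heuristic(tie)))
  expect_true(isTRUE(res$sat))
  expect_setequal(unname(res$model[c("x", "y")]), 2:3)
  expect_equal(unname(res$model["r"]), 1L)
})

test_that("range-mode formulas are smaller than pure-mode ones", {
  for (s in 1:5) {
    g <- gen_dnfa_wg(30, 50, 2, 2, seed = s)
    st <- renaming_heuristic(g)
    expect_lt(encode_smt(g, st)$meta$total, encode_smt(g)$meta$total)
  }
})

test_that("SMT-LIB 2 export is well-formed QF_IDL", {
  tie <- mk_g(c("r", "r"), c("x", "y"), c("A", "A"))
  f <- encode_smt(tie, renaming_heuristic(tie))
  path <- tempfile(fileext = ".smt2")
  write_smt2(f, path)
  txt <- readLines(path)
  expect_identical(txt[1], "(set-logic QF_IDL)")
  expect_equal(sum(grepl("^\\(assert ", txt)), f$meta$total + 1L)  # + x0 pin
  expect_true(any(grepl("check-sat", txt)))
  expect_equal(sum(grepl("^\\(declare-const", txt)), length(tie$nodes) + 1L)
})

test_that("all recognition routes agree on mixed small graphs", {
  for (s in 1:60) {
    g <- switch(s %% 3 + 1,
                rand_graph(sample(3:8, 1), sample(3:10, 1), sample(1:3, 1), seed = s),
                perturb_graph(gen_random_wg(6, 8, 2, seed = s), seed = s),
                gen_complete_wg(sample(4:7, 1), 2, 1, seed = s)$graph)
    v <- verdicts_all(g)
    expect_length(unique(v), 1L)
  }
})

test_that("recognize dispatches, attaches the index and validates config", {
  g <- mk_g(c("r", "r"), c("x", "y"), c("A", "A"))
  for (solver in c("pr", "smt", "pure-smt", "brute")) {
    res <- recognize(g, wg_config(solver))
    expect_identical(res$verdict, "wheeler")
    expect_true(check_wheeler(g, res$ordering)$valid)
    expect_s3_class(res$index, "wg_index")
    expect_equal(count_same_label_crossings(g, res$ordering), 0L,
                 ignore_attr = TRUE)
  }
  nw <- recognize(mk_g(c("a", "b"), c("b", "a"), c("A", "A")))
  expect_identical(nw$verdict, "not_wheeler")
  expect_true(!is.null(nw$violation))
  expect_error(wg_config("bogus"))
  expect_error(recognize(g, cfg = list(solver = "smt")), "usage error")
  expect_error(wg_config("smt", timeout = 0), "timeout")
})
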