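# The renaming heuristic: rough rank ranges, conflict detection, iterative
# refinement and its soundness against exhaustive ground truth.

path3 <- function() mk_g(c("v1", "v2"), c("v2", "v3"), c("A", "A"))

test_that("group_edges_by_label iterates keys in alphabet order", {
  g <- mk_g(c("a", "b"), c("b", "c"), c("A", "B"))
  grp <- group_edges_by_label(g)
  expect_identical(names(grp), c("A", "B"))
  expect_equal(nrow(grp$A), 1L)
  expect_identical(group_edges_by_label(wg_graph(nodes = "x")),
                   stats::setNames(list(), character()))
  tr <- gen_trie(msa_from_rows(c("AC", "AG")))
  expect_identical(names(group_edges_by_label(tr)), c("A", "C", "G"))
})

test_that("detect_label_conflict finds multi-label in-edges", {
  expect_identical(detect_label_conflict(
    mk_g(c("a", "b"), c("c", "c"), c("A", "B"))), "c")
  expect_null(detect_label_conflict(wg_graph(nodes = c("a", "b"))))
  for (s in 1:3)
    expect_null(detect_label_conflict(gen_debruijn(random_msa(2, 30, seed = s), 4)))
})

test_that("initialize_rough_order builds root and label blocks", {
  st <- initialize_rough_order(path3())
  expect_identical(st$ranges$lo, c(1L, 2L, 2L))
  expect_identical(st$ranges$hi, c(1L, 3L, 3L))

  b <- mk_g(c("r", "r"), c("x", "y"), c("A", "B"))
  st2 <- initialize_rough_order(b)
  expect_identical(st2$ranges[st2$ranges$node == "x", c("lo", "hi")],
                   data.frame(lo = 2L, hi = 2L, row.names = 2L))
  expect_identical(unname(unlist(st2$ranges[st2$ranges$node == "y", 2:3])),
                   c(3L, 3L))

  iso <- wg_graph(nodes = c("a", "b", "c"))
  st3 <- initialize_rough_order(iso)
  expect_true(all(st3$ranges$lo == 1L & st3$ranges$hi == 3L))

  expect_error(initialize_rough_order(
    mk_g(c("a", "b"), c("c", "c"), c("A", "B"))), "distinct labels")
})

test_that("get_innodelist lists sorted distinct predecessor orders", {
  g <- path3()
  st <- initialize_rough_order(g)
  expect_identical(get_innodelist(g, st, "v2"), 1L)
  expect_identical(get_innodelist(g, st, "v3"), 3L)
  expect_identical(get_innodelist(g, st, "v1"), integer())
  loop <- mk_g("a", "a", "A")
  stl <- initialize_rough_order(loop)
  expect_identical(get_innodelist(loop, stl, "a"),
                   unname(stl$temp_order["a"]))
})

test_that("renaming_heuristic refines to the documented fixpoints", {
  st <- renaming_heuristic(path3())
  expect_true(st$converged)
  expect_true(is_totally_resolved(st))
  expect_identical(st$ranges$lo, 1:3)

  tie <- mk_g(c("r", "r"), c("x", "y"), c("A", "A"))
  st2 <- renaming_heuristic(tie)
  expect_false(is_totally_resolved(st2))
  xy <- st2$ranges[st2$ranges$node %in% c("x", "y"), ]
  expect_true(all(xy$lo == 2L & xy$hi == 3L))

  conf <- renaming_heuristic(mk_g(c("a", "b"), c("c", "c"), c("A", "B")))
  expect_match(conf$conflict, "distinct labels")

  expect_true(is_totally_resolved(renaming_heuristic(wg_graph(nodes = "z"))))
})

test_that("refinement only splits tie groups and terminates within n", {
  for (s in 1:25) {
    g <- rand_graph(sample(3:8, 1), sample(3:12, 1), sample(1:3, 1), seed = s)
    if (!is.null(detect_label_conflict(g))) next
    st0 <- initialize_rough_order(g)
    st <- renaming_heuristic(g)
    expect_lte(st$iteration, length(g$nodes))
    # every final tie group is contained in an initial one
    key0 <- stats::setNames(paste(st0$ranges$lo, st0$ranges$hi), st0$ranges$node)
    key1 <- stats::setNames(paste(st$ranges$lo, st$ranges$hi), st$ranges$node)
    split1 <- split(names(key1), key1)
    for (grp in split1)
      expect_length(unique(key0[grp]), 1L)
    expect_gte(length(unique(key1)), length(unique(key0)))
  }
})

test_that("heuristic ranges are sound: valid orderings stay inside them", {
  checked <- 0
  for (s in 1:40) {
    g <- rand_graph(sample(3:5, 1), sample(2:7, 1), sample(1:2, 1), seed = s)
    if (!is.null(detect_label_conflict(g))) next
    valid <- all_valid_orderings(g)
    if (!length(valid)) next
    st <- renaming_heuristic(g)
    lo <- stats::setNames(st$ranges$lo, st$ranges$node)
    hi <- stats::setNames(st$ranges$hi, st$ranges$node)
    for (ord in valid) {
      checked <- checked + 1
      expect_true(all(ord >= lo[names(ord)] & ord <= hi[names(ord)]),
                  info = paste("seed", s))
    }
  }
  expect_gt(checked, 20)
})

test_that("heuristic conflicts are confirmed non-Wheeler by the oracle", {
  found <- 0
  for (s in 1:40) {
    g <- rand_graph(sample(3:6, 1), sample(4:9, 1), 2, seed = s)
    st <- renaming_heuristic(g)
    if (!is.null(st$conflict)) {
      found <- found + 1
      expect_identical(brute_force_recognize(g)$verdict, "not_wheeler")
    } else if (is_totally_resolved(st)) {
      # a resolved heuristic-only order, when valid, matches the oracle
      ord <- stats::setNames(st$ranges$lo, st$ranges$node)
      if (check_wheeler(g, ord)$valid)
        expect_identical(brute_force_recognize(g)$verdict, "wheeler")
    }
  }
  expect_gt(found, 0)
})

test_that("range dumps use the node<TAB>lo<TAB>hi format", {
  st <- renaming_heuristic(path3())
  f <- tempfile()
  write_ranges(st, f)
  expect_identical(readLines(f), c("v1\t1\t1", "v2\t2\t2", "v3\t3\t3"))
})
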