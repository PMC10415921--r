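# Graph generators: MSA-derived structures and random Wheeler graphs.

test_that("read_msa parses gapped FASTA and validates shape", {
  m <- read_msa(">a\nAC-GT\n>b\nACCGT\n")
  expect_length(m$seqs, 2L)
  expect_equal(nchar(m$seqs[[1]]), 5L)
  expect_error(read_msa(">a\nACGTA\n>b\nACGTAA\n"), "unequal")
  expect_error(read_msa(">a\n\n"), "empty|unequal|record")
  m2 <- read_msa(">a\nacgt\n")
  expect_identical(unname(m2$seqs), "ACGT")
})

test_that("truncate_columns slices before gap removal", {
  m <- read_msa(paste0(">a\n", strrep("ACGTA", 20), "\n"))
  expect_identical(truncate_columns(m, 1, 100)$seqs, m$seqs)
  expect_equal(nchar(truncate_columns(m, 2, 41)$seqs[[1]]), 40L)
  expect_error(truncate_columns(m, 50, 10), "invalid")
  expect_error(truncate_columns(m, 0, 10), "invalid")
})

test_that("random_msa is reproducible and respects its alphabet", {
  a <- random_msa(3, 50, seed = 9)
  b <- random_msa(3, 50, seed = 9)
  expect_identical(a$seqs, b$seqs)
  expect_true(all(strsplit(paste(a$seqs, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  g <- random_msa(2, 40, gap_rate = 0.3, seed = 1)
  expect_true(any(grepl("-", g$seqs)))
})

test_that("gen_trie builds prefix trees that are Wheeler 1-NFAs", {
  t1 <- gen_trie(msa_from_rows("A"))
  expect_length(t1$nodes, 2L)
  expect_equal(nrow(t1$edges), 1L)

  t2 <- gen_trie(msa_from_rows(c("AC", "AG")))
  expect_length(t2$nodes, 4L)
  expect_equal(nrow(t2$edges), 3L)
  expect_identical(t2$alphabet, c("A", "C", "G"))

  for (s in 1:4) {
    tr <- gen_trie(random_msa(3, 12, seed = s))
    expect_equal(max_same_label_outdegree(tr), 1L)
    expect_identical(recognize(tr)$verdict, "wheeler")
  }
})

test_that("gen_debruijn slides (k-1)-mers with the last-character labels", {
  g <- gen_debruijn(msa_from_rows("ACGT"), 3)
  expect_setequal(g$nodes, c("AC", "CG", "GT"))
  expect_identical(g$edges$label[g$edges$from == "AC"], "G")
  expect_identical(g$edges$label[g$edges$from == "CG"], "T")

  loop <- gen_debruijn(msa_from_rows("AAAA"), 3)
  expect_length(loop$nodes, 1L)
  expect_identical(loop$edges$from, loop$edges$to)
  expect_identical(loop$edges$label, "A")

  expect_error(gen_debruijn(msa_from_rows("AC"), 5), "shorter")
  first <- gen_debruijn(msa_from_rows("ACGT"), 3, "first")
  expect_identical(first$edges$label[first$edges$from == "AC"], "C")
})

test_that("De Bruijn outputs are 1-NFAs and padded ones are Wheeler", {
  for (s in 1:4) {
    m <- random_msa(3, 40, seed = s)
    g <- gen_debruijn(m, 4)
    expect_equal(max_same_label_outdegree(g), 1L)
    gp <- gen_debruijn(m, 4, pad_start = TRUE)
    expect_equal(max_same_label_outdegree(gp), 1L)
    expect_identical(recognize(gp)$verdict, "wheeler")
  }
})

test_that("gen_pseudo_debruijn never merges repeated (k-1)-mers", {
  p <- gen_pseudo_debruijn(msa_from_rows("ACGT"), 3)
  expect_length(p$nodes, 3L)
  expect_equal(nrow(p$edges), 2L)

  q <- gen_pseudo_debruijn(msa_from_rows("AAAA"), 3)
  expect_length(q$nodes, 3L)       # one node per occurrence
  expect_false(any(q$edges$from == q$edges$to))  # no self-loop

  d <- gen_debruijn(msa_from_rows("AAAA"), 3)
  expect_false(identical(length(d$nodes), length(q$nodes)))
})

test_that("gen_revdet walks columns right to left with dedup", {
  r1 <- gen_revdet(msa_from_rows("AC"))
  expect_length(r1$nodes, 2L)
  expect_identical(r1$edges$label, "C")

  expect_identical(write_dot(gen_revdet(msa_from_rows(c("AC", "AC")))),
                   write_dot(r1))

  r2 <- gen_revdet(msa_from_rows(c("AC", "GC")))
  expect_length(r2$nodes, 3L)
  expect_equal(nrow(r2$edges), 2L)
  expect_null(detect_label_conflict(r2))
  expect_identical(brute_force_recognize(r2)$verdict, "wheeler")

  gap <- gen_revdet(msa_from_rows(c("A-C", "AGC")))
  expect_equal(nrow(gap$edges), 3L)  # A->C skips the gap in row 1
})

test_that("e_max evaluates the closed form and its printed identity", {
  expect_identical(e_max(7, 2, 1), 18L)
  expect_identical(e_max(2, 1, 1), 2L)
  set.seed(3)
  for (i in 1:20) {
    n <- sample(1:50, 1); s <- sample(1:6, 1); r <- sample(0:n, 1)
    expect_identical(e_max(n, s, r), as.integer((n - 1) * (s + 1) - r + 1))
  }
  expect_error(e_max(3, 1, 4), "<= n")
})

test_that("gen_complete_wg attains e_max with a valid witness ordering", {
  cw <- gen_complete_wg(3, 1, 1, seed = 5)
  expect_equal(nrow(cw$graph$edges), 4L)
  expect_true(check_wheeler(cw$graph, cw$ordering)$valid)

  cw7 <- gen_complete_wg(7, 2, 1, seed = 11)
  expect_equal(nrow(cw7$graph$edges), 18L)
  expect_identical(recognize(cw7$graph)$verdict, "wheeler")

  expect_identical(write_dot(gen_complete_wg(9, 2, 1, seed = 3)$graph),
                   write_dot(gen_complete_wg(9, 2, 1, seed = 3)$graph))
  expect_error(gen_complete_wg(3, 4, 1), "infeasible")
})

test_that("gen_random_wg samples edges but keeps every in-edge skeleton", {
  g <- gen_random_wg(10, 9, 2, seed = 2)       # e = n - 1: skeleton only
  expect_equal(nrow(g$edges), 9L)
  expect_length(find_roots(g), 1L)
  expect_identical(recognize(g)$verdict, "wheeler")

  g2 <- gen_random_wg(10, e_max(10, 2, 1) - 1L, 2, seed = 2)
  expect_identical(recognize(g2)$verdict, "wheeler")

  expect_identical(write_dot(gen_random_wg(12, 20, 3, seed = 7)),
                   write_dot(gen_random_wg(12, 20, 3, seed = 7)))
  expect_error(gen_random_wg(10, 5, 2), "e_max")
})

test_that("solve_dnfa_profile follows the equal-x_k rule exactly", {
  p <- solve_dnfa_profile(7, 6, 1, 3)   # e_i = 6, d = 3
  expect_identical(p$x[1, ], c(1L, 1L, 1L))
  p2 <- solve_dnfa_profile(8, 7, 1, 3)  # residual 1 goes to x_1
  expect_identical(p2$x[1, ], c(2L, 1L, 1L))
  p3 <- solve_dnfa_profile(6, 5, 1, 1)
  expect_identical(p3$x[1, 1], 5L)
  expect_error(solve_dnfa_profile(6, 9, 1, 1), "source nodes")
  expect_error(solve_dnfa_profile(1000, 3000, 4, 2), "n_min")
})

test_that("gen_dnfa_wg hits d exactly, covers every block node, conserves e_i", {
  for (p in list(c(20, 30, 2, 2), c(40, 80, 3, 3), c(15, 20, 1, 2))) {
    g <- gen_dnfa_wg(p[1], p[2], p[3], p[4], seed = p[1])
    expect_equal(max_same_label_outdegree(g), as.integer(p[4]))
    expect_equal(nrow(g$edges), as.integer(p[2]))
    expect_length(find_roots(g), 1L)
    expect_identical(recognize(g)$verdict, "wheeler")
    prof <- solve_dnfa_profile(p[1], p[2], p[3], p[4])
    cnt <- table(factor(g$edges$label, levels = g$alphabet))
    expect_identical(as.integer(cnt), prof$e_i)
  }
})

test_that("gap-only columns do not change k-mer or trie structure", {
  plain <- msa_from_rows(c("ACGTAC", "ACGGAC"))
  gappy <- msa_from_rows(c("AC--GTAC", "AC--GGAC"))
  expect_identical(write_dot(gen_debruijn(plain, 3)),
                   write_dot(gen_debruijn(gappy, 3)))
  expect_identical(write_dot(gen_trie(plain)), write_dot(gen_trie(gappy)))
})
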