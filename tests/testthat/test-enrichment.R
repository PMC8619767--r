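test_that("hypergeometric tail matches direct enumeration anchors", {
  expect_equal(hypergeom_tail(0, 5, 5, 20), 1)
  # all C(20,5) draws enumerated: 1126 of 15504 have >= 3 of the 5 marked
  expect_equal(hypergeom_tail(3, 5, 5, 20), 1126 / 15504, tolerance = 1e-12)
  expect_equal(hypergeom_tail(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  expect_error(hypergeom_tail(3, 2, 5, 20), "k <= min")
  expect_error(hypergeom_tail(1, 21, 5, 20), "n <= N")
})

test_that("hypergeometric tail matches the distribution oracle over a dense grid", {
  for (N in c(5, 9, 14, 20, 25)) {
    for (K in seq(0, N, by = 2)) {
      for (n in seq(1, N, by = 2)) {
        for (k in 0:min(n, K)) {
          want <- sum(dhyper(k:min(n, K), K, N - K, n))
          expect_equal(hypergeom_tail(k, n, K, N), min(want, 1),
                       tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("BH adjustment reproduces hand-computed step-up vectors", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.5, 0.9)), c(0.9, 0.9))
  # order-invariance up to the induced permutation, q >= p elementwise
  p <- c(0.04, 0.001, 0.3, 0.012, 0.9)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_error(bh_fdr(c(0.1, 1.4)), "\\[0, 1\\]")
})

test_that("ORA arithmetic: fold, ratio and p on exact configurations", {
  genes <- sprintf("G%03d", 1:10)
  coll <- gene_set_collection(
    list(list(term_id = "T5", description = "five", genes = genes[1:5])),
    universe_size = 10)
  res <- ora(genes[1:5], coll, min_overlap = 3)
  expect_equal(res$k_overlap, 5)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$fold, (5 / 5) / (5 / 10))
  expect_equal(res$fold * res$ratio, res$k_overlap / res$n_query)  # identity

  # query = whole universe makes every fold exactly 1
  coll2 <- gene_set_collection(
    list(list(term_id = "A", description = "", genes = genes[1:4]),
         list(term_id = "B", description = "", genes = genes[3:10])),
    universe_size = 10, universe_genes = genes)
  res2 <- ora(genes, coll2, min_overlap = 3)
  expect_equal(res2$fold, rep(1, 2))
  expect_equal(res2$strength, rep(0, 2))
})

test_that("ORA drops query genes outside a declared universe and orders rows by p", {
  genes <- sprintf("G%03d", 1:50)
  coll <- gene_set_collection(
    list(list(term_id = "TIGHT", description = "", genes = genes[1:5]),
         list(term_id = "BROAD", description = "", genes = genes[1:30])),
    universe_size = 50, universe_genes = genes)
  expect_warning(res <- ora(c(genes[1:6], "NOT_A_GENE"), coll, min_overlap = 3),
                 "outside the declared universe")
  expect_equal(unique(res$n_query), 6)
  expect_false(is.unsorted(res$p))
  expect_true(all(res$fdr >= res$p))
})

test_that("enlarging the universe at fixed counts never increases p", {
  genes <- sprintf("G%03d", 1:20)
  term <- list(list(term_id = "T", description = "", genes = genes[1:8]))
  p_small <- ora(genes[1:10],
                 gene_set_collection(term, universe_size = 100))$p
  p_large <- ora(genes[1:10],
                 gene_set_collection(term, universe_size = 1000))$p
  expect_lte(p_large, p_small)
})

test_that("kappa agreement and term clustering follow the stated rules", {
  expect_equal(cohen_kappa(c(TRUE, TRUE, FALSE, FALSE),
                           c(FALSE, FALSE, TRUE, TRUE)), -1)
  expect_equal(cohen_kappa(c(TRUE, FALSE), c(TRUE, FALSE)), 1)
  expect_equal(cohen_kappa(rep(TRUE, 4), rep(TRUE, 4)), 1)

  genes <- sprintf("G%03d", 1:40)
  coll <- gene_set_collection(
    list(list(term_id = "T1", description = "", genes = genes[1:6]),
         list(term_id = "T2", description = "", genes = genes[1:6]),   # identical
         list(term_id = "T3", description = "", genes = genes[21:30])),
    universe_size = 40, universe_genes = genes)
  res <- ora(genes[1:25], coll, min_overlap = 3)
  cls <- kappa_term_clusters(res, genes[1:25], threshold = 0.3)
  grp <- lapply(cls, `[[`, "member_terms")
  expect_true(any(vapply(grp, function(g) setequal(g, c("T1", "T2")), logical(1))))
  expect_true(any(vapply(grp, function(g) identical(g, "T3"), logical(1))))
  # representative is the lowest-p member (T1/T2 tie -> smaller id)
  big <- cls[[which(vapply(grp, length, integer(1)) == 2)]]
  expect_equal(big$representative, "T1")
})

test_that("kappa threshold is a strict >= boundary", {
  # construct two membership vectors with kappa just below 0.3
  x <- c(rep(TRUE, 5), rep(FALSE, 5))
  y <- c(rep(TRUE, 3), rep(FALSE, 4), rep(TRUE, 3))
  k <- cohen_kappa(x, y)
  expect_lt(k, 0.3)
  genes <- sprintf("G%02d", 1:10)
  coll <- gene_set_collection(
    list(list(term_id = "TX", description = "", genes = genes[x]),
         list(term_id = "TY", description = "", genes = genes[y])),
    universe_size = 10, universe_genes = genes)
  res <- ora(genes, coll, min_overlap = 3)
  cls <- kappa_term_clusters(res, genes, threshold = 0.3)
  expect_length(cls, 2)
  cls2 <- kappa_term_clusters(res, genes, threshold = k)  # at kappa: linked
  expect_length(cls2, 1)
})
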