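two_triangles <- function(bridge_conf = 0.4) {
  pn(rbind(c("A", "B"), c("A", "C"), c("B", "C"),
           c("D", "E"), c("D", "F"), c("E", "F"), c("C", "D")),
     c(rep(0.9, 6), bridge_conf))
}

test_that("MCL keeps cliques whole and splits weakly bridged triangles", {
  cl <- mcl(pn_complete(LETTERS[1:4], conf = 0.8))
  expect_equal(cl$n_clusters, 1L)
  expect_true(cl$converged)

  cl <- mcl(two_triangles(), mcl_params(inflation = 3))
  expect_equal(cl$n_clusters, 2L)
  expect_true(same_partition(cl$assignment,
                             list(c("A", "B", "C"), c("D", "E", "F"))))
})

test_that("MCL agrees with the direct fixed-point oracle on small graphs", {
  set.seed(31)
  for (i in 1:8) {
    net <- random_net(sample(4:9, 1), p = runif(1, 0.35, 0.8))
    for (inf in c(2, 3)) {
      cl <- suppressWarnings(mcl(net, mcl_params(inflation = inf)))
      expect_true(same_partition(cl$assignment, mcl_oracle(net, inf)),
                  info = sprintf("graph %d inflation %g", i, inf))
    }
  }
})

test_that("disconnected components are never merged", {
  net <- pn(rbind(c("A", "B"), c("B", "C"), c("X", "Y"), c("Y", "Z")), 0.9)
  cl <- mcl(net)
  expect_gte(cl$n_clusters, 2L)
  expect_false(cl$assignment["A"] == cl$assignment["X"])
})

test_that("cluster ids are ordered by size then smallest member", {
  net <- pn(rbind(c("P", "Q"), c("P", "R"), c("Q", "R"), c("X", "Y")), 0.9)
  cl <- mcl(net)
  expect_equal(unname(cl$assignment[c("P", "Q", "R")]), rep(1L, 3))
  expect_equal(unname(cl$assignment[c("X", "Y")]), rep(2L, 2))
})

test_that("median cluster count does not decrease with inflation on the synthetic family", {
  counts <- sapply(1:5, function(s) {
    net <- filter_by_confidence(generate_network(synthetic_spec(rng_seed = s))$network, 0.4)
    vapply(c(1.5, 2, 3, 4), function(inf) {
      suppressWarnings(mcl(net, mcl_params(inflation = inf))$n_clusters)
    }, numeric(1))
  })
  med <- apply(counts, 1, median)
  expect_false(is.unsorted(med))
})

test_that("switch scores implement min over per-cluster seed connections with strict tau", {
  # V: 3 links into cluster-A seeds, 2 into cluster-B; W: 2 and 2
  ed <- rbind(c("V", "A1"), c("V", "A2"), c("V", "A3"), c("V", "B1"), c("V", "B2"),
              c("W", "A1"), c("W", "A2"), c("W", "B1"), c("W", "B2"))
  net <- pn(ed, 0.8)
  cl <- make_clustering(c(A1 = 1L, A2 = 1L, A3 = 1L, B1 = 2L, B2 = 2L,
                          V = 1L, W = 2L))
  seeds <- seed_set(c("A1", "A2", "A3", "B1", "B2"))
  sw <- find_switches(net, cl, seeds, 1L, 2L, tau = 0.4, top_k = 1)
  expect_equal(sw$top_switches, "V")  # equal score 2, total 5 beats 4
  tab <- sw$table
  expect_equal(tab$switch_score[tab$node == "V"], 2)
  expect_equal(tab$switch_score[tab$node == "W"], 2)

  # one-sided nodes score zero
  expect_equal(tab$switch_score[tab$node == "A1"][1] >= 0, TRUE)
  one_sided <- pn(rbind(c("U", "A1"), c("U", "A2")), 0.9,
                  nodes = c("U", "A1", "A2", "B1"))
  cl2 <- make_clustering(c(A1 = 1L, A2 = 1L, B1 = 2L, U = 1L))
  sw2 <- find_switches(one_sided, cl2, seed_set(c("A1", "A2", "B1")), 1L, 2L)
  expect_equal(sw2$table$switch_score[sw2$table$node == "U"], 0)
})

test_that("switch detection respects the strict threshold and cluster symmetry", {
  net <- two_triangles(bridge_conf = 0.4)
  cl <- mcl(net, mcl_params(inflation = 3))
  seeds <- seed_set(c("A", "B", "C", "D", "E", "F"))
  # strict > 0.4: the 0.4 bridge edge itself must NOT count
  sw <- find_switches(net, cl, seeds, 1L, 2L, tau = 0.4, top_k = 2)
  expect_equal(max(sw$table$switch_score), 0)

  # tau = 1 yields all-zero scores when no edge has confidence 1
  set.seed(11)
  rnet <- random_net(10, 0.5, conf = NULL)
  rcl <- make_clustering(setNames(rep(c(1L, 2L), each = 5), rnet$nodes))
  rs <- seed_set(rnet$nodes)
  sw1 <- find_switches(rnet, rcl, rs, 1L, 2L, tau = 1)
  expect_true(all(sw1$table$switch_score == 0))

  # min() makes the score symmetric in cluster order
  swa <- find_switches(rnet, rcl, rs, 1L, 2L, tau = 0.3)
  swb <- find_switches(rnet, rcl, rs, 2L, 1L, tau = 0.3)
  sa <- setNames(swa$table$switch_score, swa$table$node)
  sb <- setNames(swb$table$switch_score, swb$table$node)
  expect_equal(sa[sort(names(sa))], sb[sort(names(sb))])

  expect_error(find_switches(rnet, rcl, rs, 1L, 1L), "must differ")
  expect_error(find_switches(rnet, rcl, rs, 1L, 9L), "unknown cluster")
})

test_that("planted bridges occupy the top switch slots", {
  sim <- generate_network(synthetic_spec(rng_seed = 3))
  net <- filter_by_confidence(sim$network, 0.4)
  truth <- sim$truth
  cl <- truth_clustering(truth)
  seeds <- seed_set(c(truth$seed_sets[[1]]$members,
                      truth$seed_sets[[2]]$members))
  sw <- find_switches(net, cl, seeds, 1L, 2L, tau = 0.4,
                      top_k = length(truth$bridges))
  expect_setequal(sw$top_switches, truth$bridges)
})
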