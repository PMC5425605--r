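test_that("modularity_q matches closed forms and the brute-force double sum", {
  w <- two_cliques(5)
  expect_equal(modularity_q(w, rep(1:2, each = 5)), 0.5)

  set.seed(21)
  for (rep in 1:20) {
    g <- random_weight_graph(sample(4:8, 1))
    labels <- sample(1:3, nrow(g), replace = TRUE)
    expect_equal(modularity_q(g, labels, gamma = 1),
                 oracle_q_slow(g, labels, 1), tolerance = 1e-12)
    expect_equal(modularity_q(g, labels, gamma = 1.7),
                 oracle_q_slow(g, labels, 1.7), tolerance = 1e-12)
    # all-in-one partition has Q = 0 at gamma 1 for every graph
    expect_lt(abs(modularity_q(g, rep(1, nrow(g)))), 1e-12)
  }

  expect_warning(q0 <- modularity_q(matrix(0, 4, 4), rep(1, 4)), "all-zero")
  expect_equal(q0, 0)
})

test_that("louvain recovers planted structure on canonical small graphs", {
  w <- two_cliques(5, bridge = 0.05)
  p <- louvain(w, gamma = 1, seed = 3)
  expect_true(same_partition(p, rep(1:2, each = 5)))
  expect_equal(p$q_value, oracle_best_q(w), tolerance = 1e-10)

  ring <- ring_of_cliques(4, 5)
  p4 <- best_partition(ring, gamma = 1, n_runs = 10, seed = 1)
  expect_equal(p4$n_modules, 4)
  expect_true(same_partition(p4, rep(1:4, each = 5)))

  uniform <- clique_block(8)
  expect_equal(louvain(uniform, gamma = 1, seed = 2)$n_modules, 1)
})

test_that("louvain is deterministic and self-consistent in Q", {
  set.seed(22)
  w <- random_weight_graph(15, density = 0.5)
  p1 <- louvain(w, gamma = 1.3, seed = 77)
  p2 <- louvain(w, gamma = 1.3, seed = 77)
  expect_identical(p1$labels, p2$labels)
  expect_equal(p1$q_value, modularity_q(w, p1$labels, 1.3))
})

test_that("louvain agrees with igraph on partition quality", {
  skip_if_not_installed("igraph")
  set.seed(23)
  w <- ring_of_cliques(3, 4)
  p <- best_partition(w, gamma = 1, n_runs = 10, seed = 5)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  expect_equal(igraph::modularity(g, p$labels,
                                  weights = igraph::E(g)$weight),
               p$q_value, tolerance = 1e-10)
  ref <- igraph::cluster_louvain(g)
  expect_gte(p$q_value + 1e-10, max(ref$modularity))
})

test_that("best_partition honors the max contract and n_runs = 1 reduction", {
  set.seed(24)
  w <- random_weight_graph(12, density = 0.4)
  single <- best_partition(w, gamma = 1, n_runs = 1, seed = 9)
  expect_identical(single$labels,
                   louvain(w, gamma = 1, seed = dynfc:::derive_seed(9, 1))$labels)
  best <- best_partition(w, gamma = 1, n_runs = 25, seed = 9)
  runs <- vapply(1:25, function(r) {
    louvain(w, gamma = 1, seed = dynfc:::derive_seed(9, r))$q_value
  }, numeric(1))
  expect_gte(best$q_value + 1e-12, max(runs))
})

test_that("rand_z_score is symmetric, label-invariant, and positive on identity", {
  l1 <- c(1, 1, 2, 2, 3, 3, 1, 2)
  z_self <- rand_z_score(l1, l1)
  expect_gt(z_self, 0)
  permuted <- c(3, 3, 1, 1, 2, 2, 3, 1)   # same grouping, relabeled
  expect_equal(rand_z_score(l1, permuted), z_self)
  set.seed(25)
  a <- sample(1:3, 20, replace = TRUE)
  b <- sample(1:4, 20, replace = TRUE)
  expect_equal(rand_z_score(a, b), rand_z_score(b, a))
  expect_warning(z0 <- rand_z_score(seq_len(6), rep(1, 6)), "degenerate")
  expect_equal(z0, 0)
})

test_that("analytic rand_z_score tracks a permutation-null estimate", {
  set.seed(26)
  for (rep in 1:4) {
    l1 <- sample(1:3, 20, replace = TRUE)
    l2 <- sample(1:4, 20, replace = TRUE)
    mc <- mc_rand_z(l1, l2, n_perm = 2e4)
    expect_lt(abs(rand_z_score(l1, l2) - mc$z), 4 * max(mc$se, 0.02))
  }
})

test_that("agreement counts co-assignments exactly", {
  p1 <- c(1, 1, 2, 2)
  p2 <- c(1, 1, 1, 2)
  A <- agreement(list(p1, p1))
  expect_true(all(A %in% c(0, 1)))
  expect_equal(A[1, 2], 1)
  expect_equal(A[2, 3], 0)
  A2 <- agreement(list(p1, p2))
  expect_equal(A2[2, 3], 0.5)
  set.seed(27)
  stack <- lapply(1:7, function(i) sample(1:3, 10, replace = TRUE))
  A3 <- agreement(stack)
  for (i in 1:10) {
    for (j in 1:10) {
      if (i == j) next
      frac <- mean(vapply(stack, function(l) l[i] == l[j], logical(1)))
      expect_equal(A3[i, j], frac)
    }
  }
})

test_that("gamma_sweep reports stable similarity and module counts", {
  w <- two_cliques(6, bridge = 0.05)
  sw <- gamma_sweep(w, gammas = c(1, 1.5), n_runs = 2, seed = 1)
  expect_equal(nrow(sw), 2)
  # with n_runs = 2 the mean similarity is the single pair's z-Rand
  parts <- lapply(1:2, function(r) louvain(w, 1, dynfc:::derive_seed(1, 1, r)))
  expect_equal(sw$mean_rand_z[1], rand_z_score(parts[[1]], parts[[2]]))

  sw2 <- gamma_sweep(w, gammas = seq(1, 2, 0.5), n_runs = 20, seed = 2)
  expect_true(all(sw2$median_n_modules == 2))
  expect_true(all(sw2$mean_rand_z > 0))

  # hierarchical 4-within-2 block graph: module count non-decreasing in gamma
  n <- 24
  h <- matrix(0.05, n, n)
  for (b in 0:1) h[b * 12 + 1:12, b * 12 + 1:12] <- 0.3
  for (b in 0:3) h[b * 6 + 1:6, b * 6 + 1:6] <- 1
  diag(h) <- 0
  sw3 <- gamma_sweep(h, gammas = c(0.5, 1, 1.6), n_runs = 15, seed = 3)
  expect_true(all(diff(sw3$median_n_modules) >= 0))
})

test_that("consensus converges to exact structure and beats single runs", {
  w <- two_cliques(5)
  p <- consensus_partition(w, gamma = 1, n_runs = 25, seed = 4)
  expect_true(same_partition(p, rep(1:2, each = 5)))
  expect_equal(p$q_value, 0.5)

  set.seed(28)
  g <- ring_of_cliques(4, 4) + random_weight_graph(16, density = 0.3) * 0.2
  pc <- consensus_partition(g, gamma = 1, n_runs = 50, seed = 5)
  qs <- vapply(1:50, function(r) {
    louvain(g, 1, dynfc:::derive_seed(99, r))$q_value
  }, numeric(1))
  expect_gte(pc$q_value + 1e-10, median(qs))
})
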