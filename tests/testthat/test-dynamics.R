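test_that("window grid follows the floor((T - L)/s) + 1 rule", {
  w <- make_windows(225, window_spec(22, 5))
  expect_equal(nrow(w), 41)
  expect_equal(w$start[1], 1)
  expect_equal(w$start[41], 201)
  expect_equal(w$end[41], 222)

  expect_equal(nrow(make_windows(22, window_spec(22, 5))), 1)
  expect_equal(nrow(make_windows(12, window_spec(4, 2))), 5)
  expect_error(make_windows(10, window_spec(22, 5)), "exceeds")

  for (T_ in c(5, 13, 27, 50)) {
    for (L in c(1, 3, T_ %/% 2, T_)) {
      for (s in c(1, 2, 7, 10)) {
        grid <- make_windows(T_, window_spec(L, s))
        brute <- sum(vapply(seq_len(T_), function(st) {
          (st - 1) %% s == 0 && st + L - 1 <= T_
        }, logical(1)))
        expect_equal(nrow(grid), brute)
        expect_equal(nrow(grid), floor((T_ - L) / s) + 1)
      }
    }
  }
})

test_that("window connectivity reduces to per-window correlation matrices", {
  set.seed(31)
  mat <- matrix(rnorm(60 * 5), 60, 5)
  spec <- window_spec(20, 10)
  wins <- window_connectivity(mat, spec = spec)
  expect_true(all(wins$valid))
  k <- 3
  idx <- wins$windows$start[k]:wins$windows$end[k]
  expect_equal(unclass(wins$matrices[[k]]),
               unclass(correlation_matrix(mat[idx, ])), tolerance = 1e-12)

  # fully censored window flagged invalid, matrix omitted
  mask <- rep(TRUE, 60)
  mask[21:40] <- FALSE
  wins2 <- window_connectivity(mat, mask, spec)
  expect_false(wins2$valid[3])
  expect_null(wins2$matrices[[3]])
})

test_that("across-window mean converges to the static matrix for stationary data", {
  set.seed(32)
  shared <- rnorm(2000)
  mat <- sapply(1:4, function(i) sqrt(0.5) * shared + sqrt(0.5) * rnorm(2000))
  wins <- window_connectivity(mat, spec = window_spec(50, 25))
  avg <- Reduce(`+`, lapply(wins$matrices, unclass)) / sum(wins$valid)
  static <- unclass(correlation_matrix(mat))
  expect_lt(max(abs(avg - static)), 0.1)
})

test_that("window modularity is reproducible and self-consistent", {
  set.seed(33)
  mat <- matrix(rnorm(80 * 12), 80, 12)
  wins <- window_connectivity(mat, spec = window_spec(30, 25))
  q1 <- window_modularity(wins, gamma = 1.2, n_runs = 5, seed = 7)
  q2 <- window_modularity(wins, gamma = 1.2, n_runs = 5, seed = 7)
  expect_identical(q1$value, q2$value)
  # Q equals best_partition's Q recomputed per window
  for (k in which(wins$valid)) {
    g <- make_graph_ready(wins$matrices[[k]])
    p <- best_partition(g, gamma = 1.2, n_runs = 5,
                        seed = dynfc:::derive_seed(7, k))
    expect_equal(q1$value[k], modularity_q(g, p$labels, 1.2))
  }
})

test_that("window modularity anticorrelates with planted coupling state", {
  # between-module coupling alternating strong/weak across 22-TR blocks
  set.seed(34)
  n_blocks <- 20
  state <- rep(c(0.65, 0.1), length.out = n_blocks)
  shared <- rnorm(22 * n_blocks)
  coupling_t <- rep(state, each = 22)
  s1 <- sqrt(1 - coupling_t) * rnorm(22 * n_blocks) + sqrt(coupling_t) * shared
  s2 <- sqrt(1 - coupling_t) * rnorm(22 * n_blocks) + sqrt(coupling_t) * shared
  mat <- cbind(sapply(1:10, function(i) s1 + 0.5 * rnorm(22 * n_blocks)),
               sapply(1:10, function(i) s2 + 0.5 * rnorm(22 * n_blocks)))
  wins <- window_connectivity(mat, spec = window_spec(22, 22))
  q <- window_modularity(wins, gamma = 1, n_runs = 5, seed = 2)
  expect_lt(cor(q$value, state), -0.5)
})

test_that("module-pair series cover K(K-1)/2 pairs and degenerate correctly", {
  set.seed(35)
  mat <- matrix(rnorm(50 * 30), 50, 30)
  labels <- rep(1:10, each = 3)
  mp <- module_pair_fc(mat, labels, spec = window_spec(20, 10))
  expect_equal(ncol(mp$z), 45)
  expect_equal(mp$pairs$label[1], "1-2")
  expect_error(module_pair_fc(mat, c(rep(1, 29), 3)), "empty module")

  # duplicated module time courses give the clipped maximal z
  base <- matrix(rnorm(50 * 3), 50, 3)
  dup <- cbind(base, base)
  mp2 <- module_pair_fc(dup, rep(1:2, each = 3), spec = window_spec(20, 10))
  expect_true(all(mp2$z[, "1-2"] == atanh(1 - 1e-7)))
})

test_that("node-pair series reduces to window connectivity entries", {
  set.seed(36)
  mat <- matrix(rnorm(60 * 6), 60, 6)
  spec <- window_spec(20, 10)
  bn <- node_pair_fc(mat, 2, 5, spec = spec)
  wins <- window_connectivity(mat, spec = spec)
  for (k in seq_len(nrow(bn))) {
    expect_equal(bn$value[k], unclass(wins$matrices[[k]])[2, 5])
  }
  dup <- cbind(mat, mat[, 1])
  z <- node_pair_fc(dup, 1, 7, spec = spec)
  expect_true(all(z$value == atanh(1 - 1e-7)))
  expect_error(node_pair_fc(mat, c(1, 2), c(2, 3)), "overlap")
})

test_that("bi-nodal and network series track the generator's latent coupling", {
  cfg <- cohort_config(n_control = 2, n_assaulted = 1, n_nodes = 40,
                       n_modules = 5, trauma_effect_fc = 0,
                       trauma_effect_tracking = 0, coupling_volatility = 0.35,
                       motion_spike_prob = 0, seed = 21)
  co <- generate_cohort(cfg)
  net_r <- bn_r <- numeric(3)
  for (s in 1:3) {
    ts <- co$subjects[[s]]
    lat <- co$truth$latent_coupling[s, ]
    mp <- module_pair_fc(ts, co$truth$module_labels)
    net_r[s] <- cor(pair_series(mp, 1, 2)$value, lat)
    bn <- node_pair_fc(ts, ts$roles$amygdala, ts$roles$mpfc)
    bn_r[s] <- cor(bn$value, lat)
  }
  # recovered limbic-DMN series tracks the latent state; the bi-nodal series
  # tracks it positively through the shared-gain channel
  expect_true(all(net_r > 0.3))
  expect_gt(mean(net_r), 0.5)
  expect_true(all(bn_r > 0.3))
  expect_gt(mean(bn_r), 0.5)
})

test_that("static bi-nodal FC agrees with the median of its window series", {
  cfg <- cohort_config(n_control = 10, n_assaulted = 10, n_nodes = 24,
                       n_modules = 4, seed = 8)
  co <- generate_cohort(cfg)
  static <- numeric(20)
  med <- numeric(20)
  for (s in 1:20) {
    ts <- co$subjects[[s]]
    static[s] <- fisher_z(cor(ts$mat[, ts$roles$amygdala],
                              ts$mat[, ts$roles$mpfc]))
    med[s] <- series_median(node_pair_fc(ts, ts$roles$amygdala,
                                         ts$roles$mpfc))
  }
  expect_gt(cor(static, med), 0.7)
})
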