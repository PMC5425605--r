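# Independent oracles and graph builders used across the suite. These stay
# deliberately separate from the package's own code paths.

# all set partitions of n items, as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, maxlab) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible(NULL))
    }
    for (l in seq_len(maxlab + 1)) rec(c(labels, l), max(maxlab, l))
  }
  rec(integer(0), 0L)
  out
}

# modularity by the literal double sum (slow, element-wise)
oracle_q_slow <- function(w, labels, gamma = 1) {
  n <- nrow(w)
  m2 <- sum(w)
  k <- rowSums(w)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) {
        q <- q + w[i, j] - gamma * k[i] * k[j] / m2
      }
    }
  }
  q / m2
}

# same quantity, matrix-formulated (for exhaustive search over partitions)
oracle_q <- function(w, labels, gamma = 1) {
  m2 <- sum(w)
  k <- rowSums(w)
  same <- outer(labels, labels, "==")
  sum((w - gamma * outer(k, k) / m2) * same) / m2
}

oracle_best_q <- function(w, gamma = 1) {
  max(vapply(all_partitions(nrow(w)), function(l) oracle_q(w, l, gamma),
             numeric(1)))
}

# random sparse nonnegative symmetric weight matrix
random_weight_graph <- function(n, density = 0.6) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- runif(sum(up)) * (runif(sum(up)) < density)
  w[up] <- vals
  w <- w + t(w)
  w
}

clique_block <- function(n, v = 1) matrix(v, n, n) - diag(rep(v, n))

two_cliques <- function(n_each = 5, bridge = 0) {
  w <- rbind(cbind(clique_block(n_each), matrix(0, n_each, n_each)),
             cbind(matrix(0, n_each, n_each), clique_block(n_each)))
  if (bridge > 0) w[1, n_each + 1] <- w[n_each + 1, 1] <- bridge
  w
}

ring_of_cliques <- function(n_cliques = 4, clique_size = 5) {
  n <- n_cliques * clique_size
  w <- matrix(0, n, n)
  for (b in seq_len(n_cliques) - 1) {
    idx <- b * clique_size + seq_len(clique_size)
    w[idx, idx] <- 1
  }
  diag(w) <- 0
  for (b in seq_len(n_cliques) - 1) {
    i <- b * clique_size + clique_size
    j <- ((b + 1) %% n_cliques) * clique_size + 1
    w[i, j] <- w[j, i] <- 1
  }
  w
}

# permutation-null estimate of the z-scored Rand statistic, with a
# batch-means standard error for the estimate itself
mc_rand_z <- function(l1, l2, n_perm = 1e5, n_batch = 20) {
  n <- length(l1)
  K1 <- max(l1)
  K2 <- max(l2)
  base <- (l1 - 1L) * K2
  wstat <- function(lab2) {
    nij <- tabulate(base + lab2, K1 * K2)
    sum(nij * (nij - 1)) / 2
  }
  w_obs <- wstat(l2)
  ws <- vapply(seq_len(n_perm), function(i) wstat(l2[sample.int(n)]),
               numeric(1))
  z_est <- (w_obs - mean(ws)) / sd(ws)
  batch <- split(ws, rep(seq_len(n_batch), length.out = n_perm))
  bz <- vapply(batch, function(b) (w_obs - mean(b)) / sd(b), numeric(1))
  list(z = z_est, se = sd(bz) / sqrt(n_batch))
}

# small, fast cohort for unit tests
tiny_cohort_config <- function(...) {
  cohort_config(n_control = 4, n_assaulted = 4, n_nodes = 24, n_modules = 4,
                n_timepoints = 80, ...)
}
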