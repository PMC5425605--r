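#' Partition object
#'
#' Node-to-module labels (integers `1..n_modules`, every label used) together
#' with the resolution and modularity that produced them.
#'
#' @param labels integer vector of module labels.
#' @param gamma resolution parameter.
#' @param q_value modularity of the partition.
#' @return object of class `partition`.
#' @export
partition <- function(labels, gamma = NA_real_, q_value = NA_real_) {
  labels <- compact_labels(labels)
  structure(list(labels = labels, n_modules = max(labels),
                 gamma = gamma, q_value = q_value),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition: %d nodes, %d modules, gamma = %s, Q = %s>\n",
              length(x$labels), x$n_modules, format(x$gamma),
              format(x$q_value, digits = 4)))
  invisible(x)
}

compact_labels <- function(labels) {
  labels <- as.integer(labels)
  match(labels, unique(labels))
}

part_labels <- function(p) {
  if (inherits(p, "partition")) p$labels else as.integer(p)
}

#' Modularity Q of a partition
#'
#' For nonnegative symmetric weights `w`,
#' \deqn{Q = \frac{1}{2m}\sum_{ij}\left[w_{ij} -
#'   \gamma \frac{k_i k_j}{2m}\right]\delta(c_i, c_j)}
#' with \eqn{k_i} the weighted degree and \eqn{2m} the total weight. An
#' all-zero matrix yields Q = 0 with a warning.
#'
#' @param w graph-ready weight matrix.
#' @param p a [partition()] or label vector.
#' @param gamma resolution parameter (default 1).
#' @return modularity value.
#' @export
modularity_q <- function(w, p, gamma = 1) {
  w <- unclass(w)
  labels <- part_labels(p)
  stopifnot(length(labels) == nrow(w))
  if (any(w < 0)) stop("modularity requires nonnegative weights", call. = FALSE)
  m2 <- sum(w)
  if (m2 <= 0) {
    warning("all-zero weight matrix; Q defined as 0")
    return(0)
  }
  k <- rowSums(w)
  q <- 0
  for (c in unique(labels)) {
    idx <- labels == c
    q <- q + sum(w[idx, idx]) - gamma * sum(k[idx])^2 / m2
  }
  q / m2
}

#' Louvain community detection with resolution parameter
#'
#' Two-phase greedy modularity maximization on a dense nonnegative weight
#' matrix: local node moves to convergence (shuffled visit order, strictly
#' positive gain, first-best tie-breaking), then module aggregation, repeated
#' until no move improves Q. Deterministic for a fixed seed.
#'
#' @param w graph-ready weight matrix.
#' @param gamma resolution parameter.
#' @param seed integer seed for the node-visit shuffles.
#' @return a [partition()] with its Q on `w`.
#' @export
louvain <- function(w, gamma = 1, seed = 1) {
  wm <- unclass(w)
  if (any(wm < 0)) stop("louvain requires nonnegative weights", call. = FALSE)
  labels <- .louvain_cpp(wm, gamma, as.double(seed)) + 1L
  if (sum(wm) <= 0) {
    return(partition(labels, gamma = gamma, q_value = 0))
  }
  partition(labels, gamma = gamma,
            q_value = modularity_q(wm, labels, gamma))
}

#' Best-of-n Louvain restarts
#'
#' Runs [louvain()] `n_runs` times with distinct sub-seeds and returns the
#' partition with maximal Q; ties are broken by fewest modules, then lowest
#' run index.
#'
#' @inheritParams louvain
#' @param n_runs number of restarts (>= 1).
#' @return a [partition()].
#' @export
best_partition <- function(w, gamma = 1, n_runs = 25, seed = 1) {
  stopifnot(n_runs >= 1)
  best <- NULL
  for (r in seq_len(n_runs)) {
    p <- louvain(w, gamma, seed = derive_seed(seed, r))
    if (is.null(best) ||
        p$q_value > best$q_value + 1e-12 ||
        (abs(p$q_value - best$q_value) <= 1e-12 &&
         p$n_modules < best$n_modules)) {
      best <- p
    }
  }
  best
}

#' z-scored Rand similarity of two partitions
#'
#' Pair-counting similarity standardized under the permutation null:
#' \eqn{z = (w - M_1 M_2 / M) / \sigma_w}, where `M` is the total number of
#' node pairs, `M1`/`M2` the within-module pairs of each partition, `w` the
#' pairs co-assigned in both, and \eqn{\sigma_w} the analytic standard
#' deviation of `w` when one partition's labels are randomly permuted.
#' Degenerate cases with \eqn{\sigma_w = 0} return 0 with a warning.
#'
#' @param p1,p2 [partition()]s or label vectors on the same node set.
#' @return similarity z value.
#' @export
rand_z_score <- function(p1, p2) {
  l1 <- part_labels(p1)
  l2 <- part_labels(p2)
  stopifnot(length(l1) == length(l2))
  n <- length(l1)
  nij <- table(l1, l2)
  ni <- rowSums(nij)
  nj <- colSums(nij)
  M <- n * (n - 1) / 2
  M1 <- sum(ni * (ni - 1)) / 2
  M2 <- sum(nj * (nj - 1)) / 2
  w <- sum(nij * (nij - 1)) / 2

  C1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M1 + 4 * sum(ni^3)
  C2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M2 + 4 * sum(nj^3)
  a <- 4 * M1 - 2 * M
  b <- 4 * M2 - 2 * M
  sigw2 <- M / 16 - a^2 * b^2 / (256 * M^2) +
    C1 * C2 / (16 * n * (n - 1) * (n - 2)) +
    (a^2 - 4 * C1 - 4 * M) * (b^2 - 4 * C2 - 4 * M) /
      (64 * n * (n - 1) * (n - 2) * (n - 3))
  if (!is.finite(sigw2) || sigw2 <= 0) {
    warning("degenerate partition pair (sigma_w = 0); returning 0")
    return(0)
  }
  (w - M1 * M2 / M) / sqrt(sigw2)
}

#' Agreement matrix of a set of partitions
#'
#' Entry (i, j) is the fraction of partitions assigning nodes i and j to the
#' same module; the diagonal is 1.
#'
#' @param partitions list of [partition()]s or label vectors on one node set.
#' @return symmetric matrix with values in `[0, 1]`.
#' @export
agreement <- function(partitions) {
  stopifnot(length(partitions) >= 2)
  labs <- lapply(partitions, part_labels)
  n <- length(labs[[1]])
  A <- matrix(0, n, n)
  for (l in labs) {
    # indicator of co-assignment via module membership dummies
    D <- outer(l, l, "==")
    A <- A + D
  }
  A <- A / length(labs)
  diag(A) <- 1
  A
}

#' Resolution-parameter sweep
#'
#' For each gamma, runs `n_runs` Louvain partitions and reports the mean
#' pairwise z-scored Rand similarity (over at most `max_pairs` unordered
#' pairs, subsampled for tractability) and the median module count.
#'
#' @inheritParams louvain
#' @param gammas resolutions to test (default 1.0 to 2.0, step 0.1).
#' @param n_runs Louvain runs per gamma (default 250).
#' @param max_pairs maximum partition pairs entering the similarity mean.
#' @return data.frame with columns `gamma`, `mean_rand_z`,
#'   `median_n_modules`.
#' @export
gamma_sweep <- function(w, gammas = seq(1, 2, by = 0.1), n_runs = 250,
                        seed = 1, max_pairs = 1000) {
  stopifnot(length(gammas) >= 2)
  res <- lapply(seq_along(gammas), function(gi) {
    g <- gammas[gi]
    parts <- lapply(seq_len(n_runs), function(r) {
      louvain(w, g, seed = derive_seed(seed, gi, r))
    })
    prs <- combn(n_runs, 2)
    if (ncol(prs) > max_pairs) {
      old <- get_rng_state()
      set.seed(derive_seed(seed, gi, 0))
      prs <- prs[, sample(ncol(prs), max_pairs), drop = FALSE]
      restore_rng_state(old)
    }
    sims <- apply(prs, 2, function(ij) {
      rand_z_score(parts[[ij[1]]], parts[[ij[2]]])
    })
    data.frame(gamma = g, mean_rand_z = mean(sims),
               median_n_modules = median(vapply(parts, function(p)
                 p$n_modules, numeric(1))))
  })
  do.call(rbind, res)
}

#' Consensus partition via iterative agreement-matrix re-clustering
#'
#' Runs Louvain `n_runs` times on the graph, computes the agreement matrix,
#' re-clusters the agreement matrix (diagonal zeroed) with `n_runs` further
#' runs, and repeats until the partitions are unanimous or the mean
#' off-diagonal agreement stops improving (cap `max_iter` rounds, warning on
#' non-convergence). The first round uses `gamma`; later rounds cluster the
#' near-binary agreement weights at `consensus_gamma` (default 1). The
#' returned partition carries its Q on the original matrix at `gamma`.
#'
#' @inheritParams louvain
#' @param n_runs Louvain runs per round (default 300).
#' @param consensus_gamma resolution for agreement-matrix rounds.
#' @param max_iter round cap.
#' @return a [partition()].
#' @export
consensus_partition <- function(w, gamma = 1, n_runs = 300, seed = 1,
                                consensus_gamma = 1, max_iter = 50) {
  w0 <- unclass(w)
  cur <- w0
  g <- gamma
  best_agree <- -Inf
  best_part <- NULL
  for (iter in seq_len(max_iter)) {
    parts <- lapply(seq_len(n_runs), function(r) {
      louvain(cur, g, seed = derive_seed(seed, iter, r))
    })
    canon <- vapply(parts, function(p) paste(p$labels, collapse = ","),
                    character(1))
    if (length(unique(canon)) == 1) {
      p <- parts[[1]]
      return(partition(p$labels, gamma = gamma,
                       q_value = modularity_q(w0, p$labels, gamma)))
    }
    A <- agreement(parts)
    mean_agree <- mean(A[upper.tri(A)])
    if (mean_agree <= best_agree) {
      warning("consensus agreement stopped improving; returning best so far")
      p <- best_part
      return(partition(p$labels, gamma = gamma,
                       q_value = modularity_q(w0, p$labels, gamma)))
    }
    best_agree <- mean_agree
    qs <- vapply(parts, function(p) modularity_q(cur, p$labels, g), numeric(1))
    best_part <- parts[[which.max(qs)]]
    diag(A) <- 0
    cur <- A
    g <- consensus_gamma
  }
  warning("consensus did not converge within ", max_iter, " iterations")
  partition(best_part$labels, gamma = gamma,
            q_value = modularity_q(w0, best_part$labels, gamma))
}

#' Test whether two partitions are identical up to label permutation
#'
#' @param p1,p2 [partition()]s or label vectors.
#' @return logical.
#' @export
same_partition <- function(p1, p2) {
  identical(compact_labels(part_labels(p1)), compact_labels(part_labels(p2)))
}
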