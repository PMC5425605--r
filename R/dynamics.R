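#' Sliding-window specification
#'
#' @param length_trs window length in TRs (default 22, i.e. 44 s at TR 2 s).
#' @param step_trs step between window starts (default 5 TRs).
#' @param min_valid_fraction minimum fraction of retained (uncensored) TRs
#'   for a window to count as valid (default 2/3).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(length_trs = 22, step_trs = 5,
                        min_valid_fraction = 2 / 3) {
  stopifnot(length_trs >= 1, step_trs >= 1,
            min_valid_fraction >= 0, min_valid_fraction <= 1)
  structure(list(length_trs = as.integer(length_trs),
                 step_trs = as.integer(step_trs),
                 min_valid_fraction = min_valid_fraction),
            class = "window_spec")
}

#' Sliding-window index grid
#'
#' Window k starts at TR `1 + (k-1) * step` and spans `length_trs` TRs; a
#' window is included iff it fits entirely inside the series, giving
#' `floor((T - L) / s) + 1` windows.
#'
#' @param n_timepoints series length in TRs.
#' @param spec a [window_spec()].
#' @return data.frame with columns `window`, `start`, `end` (1-based,
#'   inclusive).
#' @export
make_windows <- function(n_timepoints, spec = window_spec()) {
  L <- spec$length_trs
  s <- spec$step_trs
  if (L > n_timepoints) {
    stop("window length exceeds series length", call. = FALSE)
  }
  starts <- seq(1L, n_timepoints - L + 1L, by = s)
  data.frame(window = seq_along(starts), start = starts,
             end = starts + L - 1L)
}

#' Per-window connectivity matrices
#'
#' Pearson correlation (Fisher-z) over each window's retained TRs. A window
#' is invalid when its retained fraction falls below
#' `spec$min_valid_fraction` (or fewer than 3 TRs remain); its matrix is
#' omitted.
#'
#' @param ts a [roi_ts()] or time-by-node matrix.
#' @param mask optional [censor_mask()] or logical keep vector.
#' @param spec a [window_spec()].
#' @return object of class `window_matrices`: list with `windows` (the
#'   grid), `valid` (logical), and `matrices` (list; `NULL` where invalid).
#' @export
window_connectivity <- function(ts, mask = NULL, spec = window_spec()) {
  mat <- if (inherits(ts, "roi_ts")) ts$mat else as.matrix(ts)
  keep <- as_keep(mask, nrow(mat))
  win <- make_windows(nrow(mat), spec)
  valid <- logical(nrow(win))
  mats <- vector("list", nrow(win))
  for (k in seq_len(nrow(win))) {
    idx <- win$start[k]:win$end[k]
    kept <- keep[idx]
    if (mean(kept) < spec$min_valid_fraction || sum(kept) < 3) next
    valid[k] <- TRUE
    mats[[k]] <- suppressWarnings(
      correlation_matrix(mat[idx[kept], , drop = FALSE]))
  }
  structure(list(windows = win, valid = valid, matrices = mats),
            class = "window_matrices")
}

new_window_series <- function(windows, value, valid, name) {
  structure(data.frame(window = windows$window, start = windows$start,
                       value = value, valid = valid),
            class = c("window_series", "data.frame"), series_name = name)
}

#' Per-window modularity Q
#'
#' For each valid window, makes the matrix graph-ready and runs
#' [best_partition()] at the given resolution; stores the resulting Q.
#' Restart seeds are derived deterministically from `seed` and the window
#' index so reruns reproduce the series exactly.
#'
#' @param wins a [window_connectivity()] result.
#' @param gamma resolution (default 1.7).
#' @param n_runs Louvain restarts per window (default 25).
#' @param seed integer seed.
#' @return a `window_series` data.frame of Q values.
#' @export
window_modularity <- function(wins, gamma = 1.7, n_runs = 25, seed = 1) {
  stopifnot(inherits(wins, "window_matrices"))
  q <- rep(NA_real_, nrow(wins$windows))
  for (k in which(wins$valid)) {
    g <- make_graph_ready(wins$matrices[[k]])
    q[k] <- best_partition(g, gamma = gamma, n_runs = n_runs,
                           seed = derive_seed(seed, k))$q_value
  }
  new_window_series(wins$windows, q, wins$valid, "modularity_q")
}

#' Between-module FC window series
#'
#' Each module's time course is the mean series of its nodes; per window the
#' module-pair Pearson correlations over retained TRs are Fisher-z
#' transformed. K modules yield K(K-1)/2 pair series.
#'
#' @param ts a [roi_ts()] or matrix.
#' @param part a [partition()] or label vector covering the node set.
#' @param mask optional censor mask.
#' @param spec a [window_spec()].
#' @return object of class `module_pair_series`: list with `windows`,
#'   `valid`, `z` (window-by-pair matrix), and `pairs` (data.frame with
#'   module indices and labels `mi-mj`).
#' @export
module_pair_fc <- function(ts, part, mask = NULL, spec = window_spec()) {
  mat <- if (inherits(ts, "roi_ts")) ts$mat else as.matrix(ts)
  labels <- part_labels(part)
  stopifnot(length(labels) == ncol(mat))
  K <- max(labels)
  sizes <- tabulate(labels, K)
  if (any(sizes == 0)) stop("empty module in partition", call. = FALSE)
  mod_tc <- vapply(seq_len(K), function(m) {
    rowMeans(mat[, labels == m, drop = FALSE])
  }, numeric(nrow(mat)))

  keep <- as_keep(mask, nrow(mat))
  win <- make_windows(nrow(mat), spec)
  pairs <- t(combn(K, 2))
  pair_labels <- paste0(pairs[, 1], "-", pairs[, 2])
  z <- matrix(NA_real_, nrow(win), nrow(pairs),
              dimnames = list(NULL, pair_labels))
  valid <- logical(nrow(win))
  for (k in seq_len(nrow(win))) {
    idx <- win$start[k]:win$end[k]
    kept <- keep[idx]
    if (mean(kept) < spec$min_valid_fraction || sum(kept) < 3) next
    valid[k] <- TRUE
    r <- cor(mod_tc[idx[kept], , drop = FALSE])
    z[k, ] <- fisher_z(r[pairs])
  }
  structure(list(windows = win, valid = valid, z = z,
                 pairs = data.frame(module_a = pairs[, 1],
                                    module_b = pairs[, 2],
                                    label = pair_labels)),
            class = "module_pair_series")
}

#' Extract one module pair's window series
#'
#' @param mp a [module_pair_fc()] result.
#' @param module_a,module_b module indices.
#' @return a `window_series` data.frame.
#' @export
pair_series <- function(mp, module_a, module_b) {
  lab <- paste0(min(module_a, module_b), "-", max(module_a, module_b))
  stopifnot(lab %in% colnames(mp$z))
  new_window_series(mp$windows, mp$z[, lab], mp$valid,
                    paste0("module_fc_", lab))
}

#' Node-pair (bi-nodal) FC window series
#'
#' Each node set is reduced to its mean time course (singletons pass
#' through); per window the Pearson correlation over retained TRs is
#' Fisher-z transformed. Supports singleton sets (amygdala-mPFC) and
#' multi-node sets (bilateral caudate collapsed to a mean course).
#'
#' @param ts a [roi_ts()] or matrix.
#' @param node_set_a,node_set_b disjoint, nonempty node index vectors.
#' @param mask optional censor mask.
#' @param spec a [window_spec()].
#' @return a `window_series` data.frame.
#' @export
node_pair_fc <- function(ts, node_set_a, node_set_b, mask = NULL,
                         spec = window_spec()) {
  mat <- if (inherits(ts, "roi_ts")) ts$mat else as.matrix(ts)
  stopifnot(length(node_set_a) >= 1, length(node_set_b) >= 1)
  if (length(intersect(node_set_a, node_set_b)) > 0) {
    stop("node sets overlap", call. = FALSE)
  }
  a <- rowMeans(mat[, node_set_a, drop = FALSE])
  b <- rowMeans(mat[, node_set_b, drop = FALSE])
  keep <- as_keep(mask, nrow(mat))
  win <- make_windows(nrow(mat), spec)
  z <- rep(NA_real_, nrow(win))
  valid <- logical(nrow(win))
  for (k in seq_len(nrow(win))) {
    idx <- win$start[k]:win$end[k]
    kept <- keep[idx]
    if (mean(kept) < spec$min_valid_fraction || sum(kept) < 3) next
    valid[k] <- TRUE
    z[k] <- fisher_z(cor(a[idx[kept]], b[idx[kept]]))
  }
  new_window_series(win, z, valid, "node_pair_fc")
}
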