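#' Within-subject cross-level correlation of two window series
#'
#' Pearson correlation over the jointly valid windows, Fisher r-to-z
#' transformed. Fewer than `min_windows` joint windows yields `NA` with a
#' warning (the subject is flagged missing rather than estimated from too
#' little data).
#'
#' @param a,b `window_series` data.frames on aligned window grids.
#' @param min_windows minimum number of jointly valid windows (default 10).
#' @return Fisher-z correlation (scalar, possibly `NA`).
#' @export
cross_level_correlate <- function(a, b, min_windows = 10) {
  stopifnot(nrow(a) == nrow(b))
  ok <- a$valid & b$valid & is.finite(a$value) & is.finite(b$value)
  if (sum(ok) < min_windows) {
    warning("fewer than ", min_windows, " jointly valid windows; returning NA")
    return(NA_real_)
  }
  fisher_z(cor(a$value[ok], b$value[ok]))
}

#' Median of a window series over its valid windows
#'
#' @param a a `window_series` data.frame.
#' @return median value, or `NA` if no window is valid.
#' @export
series_median <- function(a) {
  ok <- a$valid & is.finite(a$value)
  if (!any(ok)) return(NA_real_)
  median(a$value[ok])
}

#' Per-subject cross-level summary
#'
#' Bundles the three within-subject cross-level correlations (bi-nodal vs.
#' limbic-DMN, bi-nodal vs. Q, limbic-DMN vs. Q) and the per-series medians.
#'
#' @param binodal,network,q_series `window_series` for the bi-nodal FC, the
#'   limbic-DMN module-pair FC, and modularity Q.
#' @param min_windows passed to [cross_level_correlate()].
#' @return one-row data.frame: `z_binodal_network`, `z_binodal_q`,
#'   `z_network_q`, `median_binodal`, `median_network`, `median_q`,
#'   `n_valid_windows`.
#' @export
cross_level_summary <- function(binodal, network, q_series, min_windows = 10) {
  data.frame(
    z_binodal_network = cross_level_correlate(binodal, network, min_windows),
    z_binodal_q = cross_level_correlate(binodal, q_series, min_windows),
    z_network_q = cross_level_correlate(network, q_series, min_windows),
    median_binodal = series_median(binodal),
    median_network = series_median(network),
    median_q = series_median(q_series),
    n_valid_windows = sum(binodal$valid & network$valid & q_series$valid)
  )
}
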