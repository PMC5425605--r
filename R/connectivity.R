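#' Fisher r-to-z transform
#'
#' `atanh(r)` with `|r|` clipped to `1 - 1e-7` so perfectly correlated series
#' map to a large finite value rather than infinity.
#'
#' @param r correlation value(s), `|r| <= 1`.
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("|r| > 1 is not a correlation", call. = FALSE)
  }
  atanh(sign(r) * pmin(abs(r), 1 - 1e-7))
}

new_connectivity_matrix <- function(z, variant, n_valid) {
  structure(z, class = c("connectivity_matrix", "matrix", "array"),
            variant = variant, n_valid_timepoints = n_valid)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix %dx%d, %s, %d valid TRs>\n",
              nrow(x), ncol(x), attr(x, "variant"),
              attr(x, "n_valid_timepoints")))
  invisible(x)
}

#' Fisher-z connectivity matrix of one time-series matrix
#'
#' Pairwise Pearson correlation over retained TRs, Fisher r-to-z transformed;
#' diagonal set to zero. Nodes with zero variance over the retained TRs get
#' zero rows/columns with a warning.
#'
#' @param ts a [roi_ts()] or plain time-by-node matrix.
#' @param mask optional [censor_mask()] or logical keep vector.
#' @return a signed `connectivity_matrix`.
#' @export
correlation_matrix <- function(ts, mask = NULL) {
  mat <- if (inherits(ts, "roi_ts")) ts$mat else as.matrix(ts)
  keep <- as_keep(mask, nrow(mat))
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 3) stop("need >= 3 retained TRs", call. = FALSE)
  sds <- apply(mat, 2, sd)
  flat <- sds == 0 | !is.finite(sds)
  r <- matrix(0, ncol(mat), ncol(mat),
              dimnames = list(colnames(mat), colnames(mat)))
  ok <- !flat
  if (any(flat)) {
    warning(sum(flat), " node(s) with zero variance over retained TRs; ",
            "rows/columns set to 0")
  }
  if (sum(ok) >= 2) r[ok, ok] <- cor(mat[, ok, drop = FALSE])
  z <- fisher_z(r)
  diag(z) <- 0
  new_connectivity_matrix(z, "signed", nrow(mat))
}

#' Graph-ready variant of a connectivity matrix
#'
#' Zeroes the diagonal and all negative entries, leaving positive weights
#' unchanged — the form used for community detection and modularity.
#'
#' @param cm a signed `connectivity_matrix` (or plain matrix).
#' @return a `graph_ready` `connectivity_matrix`.
#' @export
make_graph_ready <- function(cm) {
  z <- unclass(cm)
  attr_valid <- attr(cm, "n_valid_timepoints") %||% NA_integer_
  z <- pmax(z, 0)
  diag(z) <- 0
  new_connectivity_matrix(z, "graph_ready", attr_valid)
}

#' Group-level connectivity matrix from concatenated subjects
#'
#' Each subject's retained TRs are z-scored per node (so between-subject
#' mean/variance differences cannot inflate group correlations), concatenated
#' in time, correlated once, Fisher-z transformed, and made graph-ready.
#'
#' @param cohort list of [roi_ts()] (or matrices) sharing one node set.
#' @param masks optional list of [censor_mask()]s, one per subject; subjects
#'   whose mask is flagged unusable are excluded.
#' @return a `graph_ready` `connectivity_matrix`.
#' @export
group_matrix <- function(cohort, masks = NULL) {
  mats <- lapply(cohort, function(ts) {
    if (inherits(ts, "roi_ts")) ts$mat else as.matrix(ts)
  })
  ncols <- vapply(mats, ncol, integer(1))
  if (length(unique(ncols)) != 1) {
    stop("node-set mismatch across subjects: ",
         paste(which(ncols != ncols[1]), collapse = ", "), call. = FALSE)
  }
  pieces <- vector("list", length(mats))
  for (s in seq_along(mats)) {
    m <- masks[[s]] %||% NULL
    if (inherits(m, "censor_mask") && !m$usable) next
    keep <- as_keep(m, nrow(mats[[s]]))
    piece <- mats[[s]][keep, , drop = FALSE]
    pieces[[s]] <- scale(piece)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) stop("no usable subjects", call. = FALSE)
  big <- do.call(rbind, pieces)
  make_graph_ready(correlation_matrix(big))
}
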