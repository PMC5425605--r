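#' Framewise displacement from a six-parameter motion trace
#'
#' FD at TR t is the sum over the six rigid-body parameters of the absolute
#' temporal difference from TR t-1; the first TR is 0 by convention.
#' Rotations are treated in the units supplied.
#'
#' @param motion numeric matrix, one row per TR, six columns.
#' @return nonnegative numeric vector, one value per TR.
#' @export
framewise_displacement <- function(motion) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) stop("need at least 2 TRs", call. = FALSE)
  if (ncol(motion) != 6) stop("motion trace must have 6 columns", call. = FALSE)
  if (!all(is.finite(motion))) {
    stop("non-finite values in motion trace", call. = FALSE)
  }
  c(0, rowSums(abs(diff(motion))))
}

#' Motion censoring mask
#'
#' Applies three censoring rules to a framewise-displacement series:
#' \enumerate{
#'   \item any TR with FD above `threshold` is censored together with the
#'     immediately following TR (delayed motion artifact);
#'   \item a retained TR whose preceding and following TRs are both censored
#'     is censored as well (isolated TRs), iterated to a fixed point;
#'   \item if the censored fraction of the run exceeds `run_fraction`, the
#'     whole run is flagged unusable.
#' }
#'
#' @param fd nonnegative FD series.
#' @param threshold FD censoring threshold (default 0.5).
#' @param run_fraction maximum tolerated censored fraction (default 0.5).
#' @return an object of class `censor_mask`: list with `keep` (logical,
#'   `TRUE` = retained), `retained_fraction`, and `usable`.
#' @export
censor_mask <- function(fd, threshold = 0.5, run_fraction = 0.5) {
  if (any(fd < 0)) stop("FD must be nonnegative", call. = FALSE)
  n <- length(fd)
  keep <- rep(TRUE, n)
  over <- which(fd > threshold)
  keep[over] <- FALSE
  keep[pmin(over + 1L, n)] <- FALSE
  repeat {
    idx <- which(keep)
    iso <- idx[idx > 1 & idx < n]
    iso <- iso[!keep[iso - 1L] & !keep[iso + 1L]]
    if (length(iso) == 0) break
    keep[iso] <- FALSE
  }
  frac <- mean(keep)
  structure(list(keep = keep, retained_fraction = frac,
                 usable = (1 - frac) <= run_fraction),
            class = "censor_mask")
}

#' @export
print.censor_mask <- function(x, ...) {
  cat(sprintf("<censor_mask: %d/%d TRs retained (%.1f%%), %s>\n",
              sum(x$keep), length(x$keep), 100 * x$retained_fraction,
              if (x$usable) "usable" else "UNUSABLE"))
  invisible(x)
}

as_keep <- function(mask, n) {
  if (is.null(mask)) return(rep(TRUE, n))
  if (inherits(mask, "censor_mask")) mask <- mask$keep
  stopifnot(is.logical(mask), length(mask) == n)
  mask
}

volterra_design <- function(motion) {
  motion <- as.matrix(motion)
  lag1 <- rbind(motion[1, , drop = FALSE], motion[-nrow(motion), , drop = FALSE])
  X <- cbind(motion, motion^2, lag1, lag1^2)
  colnames(X) <- c(paste0("R", 1:6), paste0("R", 1:6, "_sq"),
                   paste0("R", 1:6, "_lag"), paste0("R", 1:6, "_lagsq"))
  X
}

#' Nuisance regression of node time series
#'
#' Regresses each node's series on an intercept, 24 Volterra motion
#' regressors (the six parameters, their squares, and lag-1 copies of both;
#' the lag row is padded by repeating the first sample), and mean CSF and WM
#' signals; returns the residual series. Collinear design columns are dropped
#' with a warning.
#'
#' @param ts a [roi_ts()] (or plain matrix).
#' @param motion six-column motion trace matching the series length.
#' @param csf,wm nuisance signal vectors; if `NULL`, taken from
#'   `ts$nuisance`.
#' @return object of the same type as `ts` with residual signals.
#' @export
nuisance_regress <- function(ts, motion, csf = NULL, wm = NULL) {
  mat <- if (inherits(ts, "roi_ts")) ts$mat else as.matrix(ts)
  if (inherits(ts, "roi_ts")) {
    csf <- csf %||% ts$nuisance$csf
    wm <- wm %||% ts$nuisance$wm
  }
  n <- nrow(mat)
  X <- cbind(intercept = 1, volterra_design(motion), csf = csf, wm = wm)
  if (nrow(X) != n) stop("regressor length does not match series", call. = FALSE)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("dropping collinear nuisance columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  resid <- mat - X %*% qr.coef(qrX, mat)
  if (inherits(ts, "roi_ts")) {
    ts$mat <- resid
    ts
  } else {
    resid
  }
}

#' Zero-phase bandpass filter
#'
#' Butterworth bandpass (default 0.01-0.1 Hz) applied forward and backward
#' (`signal::filtfilt`) to each node's series, so no phase distortion is
#' introduced into windowed correlations.
#'
#' @param ts a [roi_ts()] (uses its TR) or plain matrix (supply
#'   `tr_seconds`).
#' @param low_hz,high_hz passband edges in Hz.
#' @param tr_seconds sampling interval, required for plain matrices.
#' @param order Butterworth order per direction (default 4).
#' @return filtered object of the same type.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1, tr_seconds = NULL,
                     order = 4) {
  mat <- if (inherits(ts, "roi_ts")) ts$mat else as.matrix(ts)
  tr <- if (inherits(ts, "roi_ts")) ts$tr_seconds else tr_seconds
  if (is.null(tr)) stop("`tr_seconds` required for plain matrices", call. = FALSE)
  nyq <- 1 / (2 * tr)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("passband must satisfy 0 < low < high < Nyquist (", nyq, " Hz)",
         call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- apply(mat, 2, function(x) signal::filtfilt(bf, x))
  if (inherits(ts, "roi_ts")) {
    ts$mat <- out
    ts
  } else {
    out
  }
}

#' Preprocess one subject
#'
#' Convenience wrapper running the node-level preprocessing sequence:
#' framewise displacement, censor mask, nuisance regression, bandpass.
#' Censoring is only recorded here; censored TRs are excluded at correlation
#' time, never interpolated, so the temporal grid stays intact for windowing.
#'
#' @param ts a [roi_ts()].
#' @param motion six-column motion trace.
#' @param fd_threshold,run_fraction censoring parameters.
#' @param filter run the bandpass step (default `TRUE`).
#' @return list with `ts` (processed [roi_ts()]), `mask` ([censor_mask()]),
#'   and `mean_fd`.
#' @export
prep_subject <- function(ts, motion, fd_threshold = 0.5, run_fraction = 0.5,
                         filter = TRUE) {
  fd <- framewise_displacement(motion)
  mask <- censor_mask(fd, threshold = fd_threshold, run_fraction = run_fraction)
  out <- nuisance_regress(ts, motion)
  if (filter) out <- bandpass(out)
  list(ts = out, mask = mask, mean_fd = mean(fd))
}
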