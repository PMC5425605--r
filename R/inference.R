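#' Build a group-level regression design
#'
#' Two models over subject records:
#' \describe{
#'   \item{`"ctq"`}{intercept + the five CTQ subscales, each log-transformed
#'     (raw scores are >= 5, so the log is defined) and z-scored, entered
#'     simultaneously, + z-scored age, verbal IQ, and mean FD (9 columns).}
#'   \item{`"group"`}{intercept + 0/1 assault dummy + the same three z-scored
#'     covariates (5 columns).}
#' }
#'
#' @param records data.frame with columns `group`, `age`, `verbal_iq`,
#'   `ctq_emotional_abuse`, `ctq_emotional_neglect`, `ctq_physical_abuse`,
#'   `ctq_physical_neglect`, `ctq_sexual_abuse`, `mean_fd`.
#' @param model `"ctq"` or `"group"`.
#' @param log_ctq log-transform CTQ subscales before z-scoring (default
#'   `TRUE`).
#' @return numeric design matrix with named columns, rows aligned to
#'   `records`.
#' @export
build_design <- function(records, model = c("ctq", "group"), log_ctq = TRUE) {
  model <- match.arg(model)
  zs <- function(x, name) {
    if (sd(x) == 0) {
      stop("constant column after transform: ", name, call. = FALSE)
    }
    as.numeric(scale(x))
  }
  covs <- cbind(age = zs(records$age, "age"),
                verbal_iq = zs(records$verbal_iq, "verbal_iq"),
                mean_fd = zs(records$mean_fd, "mean_fd"))
  if (model == "ctq") {
    ctq_cols <- c("ctq_emotional_abuse", "ctq_emotional_neglect",
                  "ctq_physical_abuse", "ctq_physical_neglect",
                  "ctq_sexual_abuse")
    ctq <- vapply(ctq_cols, function(cn) {
      x <- records[[cn]]
      if (log_ctq) x <- log(x)
      zs(x, cn)
    }, numeric(nrow(records)))
    X <- cbind(intercept = 1, ctq, covs)
  } else {
    dummy <- as.numeric(records$group == "assaulted")
    if (sd(dummy) == 0) {
      stop("constant column after transform: assault dummy", call. = FALSE)
    }
    X <- cbind(intercept = 1, assaulted = dummy, covs)
  }
  if (nrow(X) < ncol(X) + 2) {
    stop("too few complete cases for the design", call. = FALSE)
  }
  X
}

#' Ordinary least-squares fit with per-predictor inference
#'
#' Least-squares coefficients with classical standard errors, t = B/se, and
#' two-sided p from the t distribution on n - p degrees of freedom.
#'
#' @param y outcome vector.
#' @param X full-rank design matrix (include the intercept column).
#' @param outcome optional outcome name carried into the result.
#' @return data.frame with one row per predictor: `term`, `estimate`, `se`,
#'   `t`, `p`, plus attributes `df` and `outcome`.
#' @export
ols_fit <- function(y, X, outcome = "y") {
  ok <- is.finite(y)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(X)
  p <- ncol(X)
  fit <- lm.fit(X, y)
  df <- n - p
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  # diag(XtXinv) follows the QR pivot order; map back to column order
  se <- se[match(seq_len(p), qrX$pivot)]
  b <- fit$coefficients
  tval <- b / se
  res <- data.frame(term = colnames(X), estimate = unname(b),
                    se = unname(se), t = unname(tval),
                    p = 2 * pt(abs(tval), df, lower.tail = FALSE),
                    row.names = NULL)
  attr(res, "df") <- df
  attr(res, "outcome") <- outcome
  res
}

#' One-sample t-test against zero
#'
#' @param values numeric vector (>= 3 finite values).
#' @return list with `t`, `df`, `p`, `mean`, and `zero_variance` flag (the t
#'   statistic is infinite and flagged when the values have no spread).
#' @export
one_sample_t <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need >= 3 finite values", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  s <- sd(values)
  if (s == 0) {
    return(list(t = Inf * sign(m), df = n - 1, p = if (m == 0) 1 else 0,
                mean = m, zero_variance = TRUE))
  }
  tt <- t.test(values)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = m, zero_variance = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals p values in `[0, 1]`.
#' @return adjusted p values (step-up, monotone).
#' @export
fdr_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH")
}
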