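#' Within-subject linear support vector regression
#'
#' Fits epsilon-insensitive linear SVR (via `e1071::svm`, cost defaulting to
#' 1) predicting a target window series from the module-pair window series.
#' Columns are z-scored before fitting; the returned weights are the signed
#' contribution of each feature to the decision function, labeled by module
#' pair.
#'
#' @param features window-by-pair numeric matrix (valid windows only, or use
#'   `valid` to subset).
#' @param target window vector aligned with `features`.
#' @param cost SVR penalty parameter C (default 1).
#' @param epsilon tube width (default 0.1).
#' @param valid optional logical subset of rows to use.
#' @return list with `weights` (named numeric), `intercept`, `cost`,
#'   `epsilon`, and the fitted `model`.
#' @export
fit_linear_svr <- function(features, target, cost = 1, epsilon = 0.1,
                           valid = NULL) {
  if (!is.null(valid)) {
    features <- features[valid, , drop = FALSE]
    target <- target[valid]
  }
  ok <- is.finite(target) & apply(is.finite(features), 1, all)
  features <- features[ok, , drop = FALSE]
  target <- target[ok]
  if (nrow(features) < 10) {
    stop("fewer than 10 valid windows for SVR", call. = FALSE)
  }
  Xz <- scale(features)
  Xz[, attr(Xz, "scaled:scale") == 0] <- 0
  yz <- as.numeric(scale(target))
  fit <- e1071::svm(x = Xz, y = yz, type = "eps-regression",
                    kernel = "linear", cost = cost, epsilon = epsilon,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  names(w) <- colnames(features)
  list(weights = w, intercept = -fit$rho, cost = cost, epsilon = epsilon,
       model = fit)
}

#' Leave-one-window-out SVR performance
#'
#' For each valid window, refits the SVR on the remaining windows
#' (re-estimating the z-scoring on the training windows only, so no
#' information leaks into the held-out window) and predicts it; performance
#' is the Pearson correlation between held-out predictions and observations.
#' Constant predictions yield 0 with a warning.
#'
#' @inheritParams fit_linear_svr
#' @return performance r in `[-1, 1]`.
#' @export
loocv_performance <- function(features, target, cost = 1, epsilon = 0.1,
                              valid = NULL) {
  if (!is.null(valid)) {
    features <- features[valid, , drop = FALSE]
    target <- target[valid]
  }
  ok <- is.finite(target) & apply(is.finite(features), 1, all)
  features <- features[ok, , drop = FALSE]
  target <- target[ok]
  n <- nrow(features)
  if (n < 10) stop("fewer than 10 valid windows for SVR", call. = FALSE)
  preds <- numeric(n)
  for (k in seq_len(n)) {
    Xtr <- features[-k, , drop = FALSE]
    ytr <- target[-k]
    mu <- colMeans(Xtr)
    sdev <- apply(Xtr, 2, sd)
    sdev[sdev == 0] <- 1
    Xtrz <- sweep(sweep(Xtr, 2, mu), 2, sdev, "/")
    ymu <- mean(ytr)
    ysd <- sd(ytr)
    if (ysd == 0) ysd <- 1
    fit <- e1071::svm(x = Xtrz, y = (ytr - ymu) / ysd,
                      type = "eps-regression", kernel = "linear",
                      cost = cost, epsilon = epsilon, scale = FALSE)
    xte <- (features[k, ] - mu) / sdev
    preds[k] <- predict(fit, matrix(xte, nrow = 1)) * ysd + ymu
  }
  if (sd(preds) == 0) {
    warning("constant LOOCV predictions; performance defined as 0")
    return(0)
  }
  cor(preds, target)
}

#' Group-level one-sample t-tests on SVR feature weights
#'
#' Per module pair, a one-sample t-test of the subjects' weights against
#' zero, with flags at uncorrected p < `alpha` and at Benjamini-Hochberg
#' FDR `fdr_alpha`.
#'
#' @param per_subject_weights subject-by-pair numeric matrix (columns labeled
#'   by module pair).
#' @param alpha uncorrected screening threshold (default 0.01).
#' @param fdr_alpha FDR threshold (default 0.05).
#' @return data.frame with one row per pair: `pair`, `mean_weight`, `t`,
#'   `p`, `p_fdr`, `sig_uncorrected`, `sig_fdr`.
#' @export
group_weight_tests <- function(per_subject_weights, alpha = 0.01,
                               fdr_alpha = 0.05) {
  W <- as.matrix(per_subject_weights)
  if (nrow(W) < 3) stop("need >= 3 subjects", call. = FALSE)
  res <- lapply(seq_len(ncol(W)), function(j) {
    tt <- one_sample_t(W[, j])
    data.frame(pair = colnames(W)[j] %||% as.character(j),
               mean_weight = tt$mean, t = tt$t, p = tt$p)
  })
  res <- do.call(rbind, res)
  res$p_fdr <- fdr_adjust(res$p)
  res$sig_uncorrected <- res$p < alpha
  res$sig_fdr <- res$p_fdr < fdr_alpha
  res
}
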