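#!/usr/bin/env Rscript
# Within-subject linear SVR (cost 1): the 45 network-network window series
# predict the bi-nodal amygdala-mPFC series; leave-one-window-out
# performance per subject; group one-sample t-tests on the feature weights
# (screen p < 0.01, BH-FDR flags alongside).
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "_common.R"))

ws_file <- file.path("results", "window_series.tsv")
if (!file.exists(ws_file)) stop("run 04_dynamics.R first")
ws <- read.table(ws_file, header = TRUE, sep = "\t")
net_cols <- sort(unique(grep("^net_", ws$series, value = TRUE)))

subjects <- unique(ws$subject)
weights <- matrix(NA_real_, length(subjects), length(net_cols),
                  dimnames = list(subjects, sub("^net_", "", net_cols)))
perf <- numeric(length(subjects))
for (i in seq_along(subjects)) {
  d <- ws[ws$subject == subjects[i], ]
  target <- d[d$series == "binodal_fc", ]
  feats <- sapply(net_cols, function(nm) d$value[d$series == nm])
  valid <- target$valid & apply(sapply(net_cols, function(nm)
    d$valid[d$series == nm]), 1, all)
  colnames(feats) <- sub("^net_", "", net_cols)
  fit <- fit_linear_svr(feats, target$value, valid = valid)
  weights[i, ] <- fit$weights
  perf[i] <- loocv_performance(feats, target$value, valid = valid)
}

gt <- group_weight_tests(weights)
write_tsv(gt, file.path(results_dir(), "svr_group_tests.tsv"))
write_tsv(cbind(data.frame(subject = subjects, performance = perf),
                as.data.frame(weights)),
          file.path(results_dir(), "svr_subjects.tsv"))

message(sprintf("median LOOCV performance r = %.3f", median(perf)))
flagged <- gt[gt$sig_uncorrected, c("pair", "mean_weight", "t", "p")]
message("network pairs flagged at p < 0.01:")
print(flagged, row.names = FALSE)
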