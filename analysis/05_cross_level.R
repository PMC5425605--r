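#!/usr/bin/env Rscript
# Within-subject cross-level correlations: bi-nodal FC vs limbic-DMN FC,
# bi-nodal FC vs modularity Q, limbic-DMN FC vs Q (Fisher-z per subject),
# plus per-series medians; caudate-mPFC control analyses alongside.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "_common.R"))

ws_file <- file.path("results", "window_series.tsv")
part_file <- file.path("results", "group_partition.tsv")
if (!file.exists(ws_file) || !file.exists(part_file)) {
  stop("run 03_group_partition.R and 04_dynamics.R first")
}
ws <- read.table(ws_file, header = TRUE, sep = "\t")
gpart <- read.table(part_file, header = TRUE, sep = "\t")$module

cohort <- generate_cohort(study_config())
roles <- cohort$subjects[[1]]$roles
limbic <- gpart[roles$amygdala]
dmn <- gpart[roles$mpfc]
netpair <- paste0("net_", min(limbic, dmn), "-", max(limbic, dmn))

as_series <- function(df) {
  structure(data.frame(window = df$window, start = df$window,
                       value = df$value, valid = df$valid),
            class = c("window_series", "data.frame"))
}

rows <- lapply(split(ws, ws$subject), function(d) {
  pick <- function(nm) as_series(d[d$series == nm, ])
  out <- cross_level_summary(pick("binodal_fc"), pick(netpair),
                             pick("modularity_q"))
  out$z_caudate_network <- cross_level_correlate(pick("caudate_fc"),
                                                 pick(netpair))
  out$z_caudate_q <- cross_level_correlate(pick("caudate_fc"),
                                           pick("modularity_q"))
  cbind(data.frame(subject = d$subject[1]), out)
})
cross <- do.call(rbind, rows)

# covariate table with mean FD for the group models
prep <- mapply(prep_subject, cohort$subjects, cohort$motion,
               SIMPLIFY = FALSE)
cov <- cohort$covariates
cov$mean_fd <- vapply(prep, `[[`, numeric(1), "mean_fd")
cross <- merge(cov, cross, by = "subject", sort = FALSE)
write_tsv(cross, file.path(results_dir(), "cross_level.tsv"))
message(sprintf("mean within-subject z: bi-nodal~network %.3f, bi-nodal~Q %.3f, network~Q %.3f",
                mean(cross$z_binodal_network), mean(cross$z_binodal_q),
                mean(cross$z_network_q)))
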