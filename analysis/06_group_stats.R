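#!/usr/bin/env Rscript
# Group-level inference: one-sample t-tests on the three cross-level
# distributions; regressions of median bi-nodal FC and median Q on the five
# CTQ subscales (log-transformed, z-scored, entered simultaneously) plus
# age, verbal IQ, and mean FD; assault-group models on the cross-level z's.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "_common.R"))

cl_file <- file.path("results", "cross_level.tsv")
if (!file.exists(cl_file)) stop("run 05_cross_level.R first")
cross <- read.table(cl_file, header = TRUE, sep = "\t")

tt <- lapply(list(binodal_network = cross$z_binodal_network,
                  binodal_q = cross$z_binodal_q,
                  network_q = cross$z_network_q,
                  caudate_network = cross$z_caudate_network,
                  caudate_q = cross$z_caudate_q), one_sample_t)
ttab <- data.frame(contrast = names(tt),
                   mean_z = vapply(tt, `[[`, numeric(1), "mean"),
                   t = vapply(tt, `[[`, numeric(1), "t"),
                   df = vapply(tt, `[[`, numeric(1), "df"),
                   p = vapply(tt, `[[`, numeric(1), "p"))
write_tsv(ttab, file.path(results_dir(), "cross_level_ttests.tsv"))

X_ctq <- build_design(cross, "ctq")
X_grp <- build_design(cross, "group")
fits <- list(ctq_on_median_binodal = ols_fit(cross$median_binodal, X_ctq),
             ctq_on_median_q = ols_fit(cross$median_q, X_ctq),
             group_on_z_binodal_network = ols_fit(cross$z_binodal_network,
                                                  X_grp),
             group_on_z_binodal_q = ols_fit(cross$z_binodal_q, X_grp),
             group_on_z_network_q = ols_fit(cross$z_network_q, X_grp))
reg <- do.call(rbind, lapply(names(fits), function(nm) {
  cbind(model = nm, fits[[nm]])
}))
write_tsv(reg, file.path(results_dir(), "group_regressions.tsv"))

ea <- fits$ctq_on_median_binodal$term == "ctq_emotional_abuse"
message(sprintf("emotional abuse -> median bi-nodal FC: B = %.3f (p = %.2g)",
                fits$ctq_on_median_binodal$estimate[ea],
                fits$ctq_on_median_binodal$p[ea]))
message(sprintf("emotional abuse -> median Q: B = %.4f (p = %.2g)",
                fits$ctq_on_median_q$estimate[ea],
                fits$ctq_on_median_q$p[ea]))
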