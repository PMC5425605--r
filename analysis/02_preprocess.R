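#!/usr/bin/env Rscript
# Motion preprocessing: framewise displacement, the three censoring rules
# (FD > 0.5 plus successor, isolated TRs, >50% censored runs), 24 Volterra
# motion regressors + CSF/WM, and 0.01-0.1 Hz zero-phase bandpass.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "_common.R"))

cohort <- generate_cohort(study_config())
prep <- mapply(prep_subject, cohort$subjects, cohort$motion, SIMPLIFY = FALSE)

tab <- data.frame(
  subject = cohort$covariates$subject,
  mean_fd = vapply(prep, `[[`, numeric(1), "mean_fd"),
  retained_fraction = vapply(prep, function(p) p$mask$retained_fraction,
                             numeric(1)),
  usable = vapply(prep, function(p) p$mask$usable, logical(1))
)
write_tsv(tab, file.path(results_dir(), "censoring_summary.tsv"))
message(sprintf("mean FD %.3f; %d/%d subjects usable",
                mean(tab$mean_fd), sum(tab$usable), nrow(tab)))
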