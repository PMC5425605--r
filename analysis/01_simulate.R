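#!/usr/bin/env Rscript
# Simulate the synthetic cohort: 56 adolescent girls (30 control, 26
# assaulted), node-level resting-state series with planted limbic-DMN
# coupling dynamics, trauma-severity effects, and motion spikes.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "_common.R"))

cohort <- generate_cohort(study_config())
dir <- results_dir("cohort")
write_cohort(cohort, dir)

eff <- cohort$truth$subject_effects
message(sprintf("simulated %d subjects, %d nodes, %d TRs",
                length(cohort$subjects), ncol(cohort$subjects[[1]]$mat),
                nrow(cohort$subjects[[1]]$mat)))
message(sprintf("planted mean bi-nodal coupling: control %.3f, assaulted %.3f",
                mean(eff$true_binodal_mean[eff$group == "control"]),
                mean(eff$true_binodal_mean[eff$group == "assaulted"])))
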