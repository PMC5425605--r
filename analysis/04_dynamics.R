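#!/usr/bin/env Rscript
# Sliding-window dynamics: 22-TR windows stepped by 5 TRs (41 windows per
# subject); per-window modularity Q (gamma 1.7, 25 Louvain restarts),
# between-network FC from network mean time courses, and the a-priori
# bi-nodal amygdala-mPFC and caudate-mPFC series.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "_common.R"))

part_file <- file.path("results", "group_partition.tsv")
if (!file.exists(part_file)) stop("run 03_group_partition.R first")
gpart <- read.table(part_file, header = TRUE, sep = "\t")$module

cohort <- generate_cohort(study_config())
prep <- mapply(prep_subject, cohort$subjects, cohort$motion, SIMPLIFY = FALSE)
usable <- vapply(prep, function(p) p$mask$usable, logical(1))

long <- list()
for (s in which(usable)) {
  ts <- prep[[s]]$ts
  mask <- prep[[s]]$mask
  id <- cohort$covariates$subject[s]
  wins <- window_connectivity(ts, mask)
  q <- window_modularity(wins, gamma = 1.7, n_runs = 25,
                         seed = dynfc:::derive_seed(STUDY_SEED, 20, s))
  mp <- module_pair_fc(ts, gpart, mask)
  bn <- node_pair_fc(ts, ts$roles$amygdala, ts$roles$mpfc, mask)
  cd <- node_pair_fc(ts, ts$roles$caudate, ts$roles$mpfc, mask)
  base <- data.frame(subject = id, window = q$window)
  long[[length(long) + 1]] <- rbind(
    cbind(base, series = "modularity_q", value = q$value, valid = q$valid),
    cbind(base, series = "binodal_fc", value = bn$value, valid = bn$valid),
    cbind(base, series = "caudate_fc", value = cd$value, valid = cd$valid),
    do.call(rbind, lapply(seq_len(ncol(mp$z)), function(j) {
      cbind(base, series = paste0("net_", colnames(mp$z)[j]),
            value = mp$z[, j], valid = mp$valid)
    }))
  )
}
out <- do.call(rbind, long)
write_tsv(out, file.path(results_dir(), "window_series.tsv"))
message(sprintf("wrote %d window observations for %d subjects",
                nrow(out), sum(usable)))
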