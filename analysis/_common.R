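# Shared study definition for the numbered analysis scripts.
#
# Every script regenerates what it needs from this config (generation is
# deterministic and takes seconds), so each script can be run on its own;
# tables land under results/.
library(dynfc)

STUDY_SEED <- 20170511
# 56 subjects (30 control / 26 assaulted), 225 TRs at TR 2 s. The node count
# is reduced from the 215-node parcellation to 60 nodes in 10 networks to
# keep per-window community detection fast on a laptop; all structural
# numbers (41 windows, 45 network pairs) are unchanged.
study_config <- function() {
  cohort_config(n_nodes = 60, n_modules = 10, seed = STUDY_SEED)
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  message("wrote ", path)
}
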