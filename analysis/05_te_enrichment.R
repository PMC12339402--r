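#!/usr/bin/env Rscript
# Stage 5 - transposon-family enrichment by modified z-score.
#
# Simulates a ~1,200-family TE signal table with a planted lamina-enriched
# subset, scores every family with the robust modified z statistic
# (0.6745 * (x - median) / MAD) per mark, and flags families exceeding
# z > 2 on H3K9me2 and/or LAP2b. Reports recovery of the planted subset.

library(ladseg)

state1 <- readRDS("results/state_01.rds")
out <- "results/05_te"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config(seed = state1$seed)

te <- simulate_te_table(state1$params, seed = state1$seed)
fl <- flag_enriched(te$table, threshold = cfg$te_z_threshold)
fl$planted <- fl$family %in% te$enriched
write.table(fl, file.path(out, "te_families.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

sens <- mean(fl$enriched[fl$planted])
spec <- mean(!fl$enriched[!fl$planted])
cat(sprintf(paste0(
  "%d of %d TE families flagged at modified z > %g on either mark;\n",
  "planted subset recovered with sensitivity %.3f, specificity %.3f.\n"),
  sum(fl$enriched), nrow(fl), cfg$te_z_threshold, sens, spec))
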