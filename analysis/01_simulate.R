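#!/usr/bin/env Rscript
# Stage 1 - simulate the study system.
#
# Generates the desk-scale ground truth this analysis runs on: a 2 x 50 Mb
# genome carrying megabase-scale lamina-associated domains (LADs; LB1 +
# LAP2b + H3K9me2) and H3K9me2-only domains (KODs), 2,000 genes labeled by
# their true domain class, and three replicates of spike-in controlled
# CUT&RUN-like fragments for the H3K9me2 landscape. Everything downstream
# (02-06) consumes these files.

library(ladseg)

seed <- 20260920L %% 100000L
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

params <- sim_params(seed = seed)
truth <- simulate_genome(params, seed = seed)

for (mk in names(truth$domains))
  write_domains(truth$domains[[mk]], file.path(out, paste0("truth_", mk, ".bed")))
write.table(truth$genes, file.path(out, "genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cutrun <- simulate_cutrun(truth, params, mark = "H3K9me2",
                          contact_loss_factor = 1, seed = seed)
spike <- data.frame(
  replicate = seq_along(cutrun$replicates),
  n_spikein = vapply(cutrun$replicates, `[[`, 0, "n_spikein"),
  M = vapply(cutrun$replicates, `[[`, 0, "M"))
write.table(spike, file.path(out, "spikein_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

saveRDS(list(params = params, truth = truth, cutrun = cutrun, seed = seed),
        file.path("results", "state_01.rds"))

lad_mb <- sum(with(truth$domains$LB1$intervals, end - start)) / 1e6
kod_mb <- sum(with(truth$domains$H3K9me2$intervals, end - start)) / 1e6 - lad_mb
cat(sprintf(paste0(
  "Simulated landscape: %.1f Mb of LADs and %.1f Mb of KODs on a 100 Mb\n",
  "genome; %d genes (%s); 3 replicates, %s fragments each on average.\n"),
  lad_mb, kod_mb, nrow(truth$genes),
  paste(names(table(truth$genes$class)), table(truth$genes$class),
        sep = "=", collapse = ", "),
  format(round(mean(spike$M)), big.mark = ",")))
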