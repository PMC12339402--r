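#!/usr/bin/env Rscript
# Stage 2 - spike-in scale factors and normalized RPKM tracks.
#
# Computes the per-replicate scale factor (antibody constant / spike-in
# reads), bins each replicate's fragments into 10 kb RPKM by fragment
# midpoint, applies the scale factor, and averages the replicates.

library(ladseg)

state <- readRDS("results/state_01.rds")
out <- "results/02_normalize"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config(seed = state$seed)

tracks <- list()
sf <- numeric()
for (r in seq_along(state$cutrun$replicates)) {
  fs <- state$cutrun$replicates[[r]]
  s <- compute_scale_factor("H3K9me2", fs$n_spikein, cfg)
  sf[r] <- s$value
  tracks[[r]] <- normalize_track(bin_rpkm(fs, state$truth$genome, cfg$bin_size),
                                 s)
  write_binned_track(tracks[[r]],
                     file.path(out, sprintf("H3K9me2_rep%d.norm.bedGraph", r)))
}
write.table(data.frame(replicate = seq_along(sf), scale_factor = sf),
            file.path(out, "scale_factors.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
avg <- average_tracks(tracks)
write_binned_track(avg, file.path(out, "H3K9me2_average.norm.bedGraph"))

saveRDS(list(tracks = tracks, avg = avg), "results/state_02.rds")

cat(sprintf(paste0(
  "Scale factors %s place the replicates on one quantitative scale;\n",
  "normalized 10 kb RPKM tracks and their average written to %s.\n"),
  paste(signif(sf, 3), collapse = ", "), out))
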