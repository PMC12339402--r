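#' Run the synthetic end-to-end pipeline
#'
#' Orchestrates the stages in dependency order on fully synthetic data:
#' simulate a ground-truth landscape and CUT&RUN replicates, spike-in
#' normalize binned RPKM tracks, fit and Viterbi-decode a two-state HMM per
#' replicate, intersect replicates into consensus domains, assign gene
#' classes and expression summaries, score TE-family enrichment, and profile
#' synthetic nucleus images. Standard-format outputs (BED, bedGraph, TSV,
#' JSON) are written under `out_dir` and a run manifest (config snapshot,
#' seed, per-stage outputs with md5 digests, package version) is returned
#' and saved as JSON. A single global seed is expanded into per-stage
#' substreams keyed by stage name, so stages draw independent randomness.
#'
#' @param config a [pipeline_config()].
#' @param params a [sim_params()].
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   c("simulate", "normalize", "segment", "annotate", "te", "imaging").
#' @param seed global seed; defaults to `config$seed`.
#' @return list of class `run_manifest` (invisibly); also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), params = sim_params(),
                         out_dir = tempfile("ladseg_run_"),
                         stages = c("simulate", "normalize", "segment",
                                    "annotate", "te", "imaging"),
                         seed = config$seed) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  results <- list()

  put <- function(stage, name, path) {
    outputs[[stage]] <<- c(outputs[[stage]], setNames(path, name))
    path
  }

  ls_log("run_pipeline: seed ", seed, ", stages: ", paste(stages, collapse = ", "))

  truth <- simulate_genome(params, seed = stage_seed(seed, "simulate"),
                           config = config)
  cutrun <- simulate_cutrun(truth, params, mark = "H3K9me2",
                            contact_loss_factor = 1,
                            seed = stage_seed(seed, "cutrun"))
  if ("simulate" %in% stages) {
    for (mk in names(truth$domains))
      put("simulate", paste0("truth_", mk),
          write_domains(truth$domains[[mk]],
                        file.path(out_dir, paste0("truth_", mk, ".bed"))))
    put("simulate", "genes",
        write_intervals(data.frame(chrom = truth$genes$chrom,
                                   start = truth$genes$start,
                                   end = truth$genes$end,
                                   label = truth$genes$gene_id),
                        file.path(out_dir, "genes.bed")))
    results$truth <- truth
  }

  tracks <- list()
  if (any(c("normalize", "segment") %in% stages)) {
    for (r in seq_along(cutrun$replicates)) {
      fs <- cutrun$replicates[[r]]
      s <- compute_scale_factor(cutrun$mark, fs$n_spikein, config)
      trk <- normalize_track(bin_rpkm(fs, truth$genome, config$bin_size), s)
      tracks[[r]] <- trk
      ls_log("normalize: replicate ", r, " scale factor ", signif(s$value, 4),
             " (", fs$n_spikein, " spike-in reads, M = ", fs$M, ")")
      if ("normalize" %in% stages)
        put("normalize", paste0("rep", r),
            write_binned_track(trk, file.path(out_dir,
                                              paste0("norm_rep", r, ".bedGraph"))))
    }
    if ("normalize" %in% stages) {
      avg <- average_tracks(tracks)
      put("normalize", "average",
          write_binned_track(avg, file.path(out_dir, "norm_average.bedGraph")))
      results$tracks <- tracks
    }
  }

  consensus <- NULL
  if ("segment" %in% stages) {
    seqs <- do.call(c, lapply(tracks, track_sequences))
    model <- fit_hmm(seqs, K = 2L, seed = stage_seed(seed, "segment"))
    put("segment", "model",
        write_hmm_model(model, file.path(out_dir, "hmm_model.json")))
    rep_domains <- lapply(seq_along(tracks), function(r) {
      d <- decode(model, tracks[[r]], mark = cutrun$mark,
                  sample = paste0("rep", r))
      put("segment", paste0("domains_rep", r),
          write_domains(d, file.path(out_dir, paste0("domains_rep", r, ".bed"))))
      d
    })
    consensus <- consensus_domains(rep_domains)
    put("segment", "consensus",
        write_domains(consensus, file.path(out_dir, "domains_consensus.bed")))
    results$model <- model
    results$consensus <- consensus
  }

  if ("annotate" %in% stages) {
    expr <- simulate_expression(truth, params,
                                seed = stage_seed(seed, "expression"))
    doms <- truth$domains
    if (!is.null(consensus)) doms$H3K9me2 <- consensus
    tab <- assign_classes(truth$genes, doms, mes_class_scheme(), config)
    tab <- merge(tab, expr$tpm, by = "gene_id")
    tab <- merge(tab, classify_degs(expr$de, config$deg_fc, config$deg_alpha),
                 by = "gene_id")
    write.table(tab, file.path(out_dir, "gene_domain_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    put("annotate", "gene_table", file.path(out_dir, "gene_domain_table.tsv"))
    acct <- overlap_accounting(doms)
    write.table(acct, file.path(out_dir, "overlap_accounting.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    put("annotate", "overlap", file.path(out_dir, "overlap_accounting.tsv"))
    results$gene_table <- tab
    results$overlap <- acct
  }

  if ("te" %in% stages) {
    te <- simulate_te_table(params, seed = stage_seed(seed, "te"))
    flagged <- flag_enriched(te$table, threshold = config$te_z_threshold)
    write.table(flagged, file.path(out_dir, "te_families.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    put("te", "te_table", file.path(out_dir, "te_families.tsv"))
    results$te <- list(flagged = flagged, enriched = te$enriched)
  }

  if ("imaging" %in% stages) {
    profs <- lapply(c(peripheral = "peripheral", uniform = "uniform"),
                    function(mode) {
      img <- simulate_nucleus(params, mode = mode,
                              seed = stage_seed(seed, "imaging"))
      prof <- radial_shell_profile(img, n_shells = config$n_shells)
      f <- file.path(out_dir, paste0("radial_", mode, ".tsv"))
      write.table(prof, f, sep = "\t", quote = FALSE, row.names = FALSE)
      put("imaging", paste0("radial_", mode), f)
      prof
    })
    results$radial <- profs
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ladseg")),
    seed = seed,
    config = unclass(config),
    stages = stages,
    outputs = lapply(outputs, function(paths)
      lapply(as.list(paths), function(p)
        list(path = p, md5 = unname(tools::md5sum(p))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$results <- results
  class(manifest) <- "run_manifest"
  invisible(manifest)
}
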