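#' Pipeline configuration
#'
#' Collects every tunable threshold used across the pipeline into a single
#' validated list. Defaults are the operational constants of the analysis:
#' spike-in scale constants per antibody, the 10 kb analysis bin size, the 90%
#' gene-body overlap rule for domain membership, the TPM > 5 expression cut,
#' the twofold / adjusted-p 0.05 differential-expression thresholds, the
#' modified z > 2 transposon enrichment cut, and the imaging shell/square
#' geometry.
#'
#' @param bin_size analysis bin width in bp.
#' @param antibody_constants named numeric vector: spike-in scale constant per
#'   antibody mark. The scale factor for a sample is constant / spike-in reads.
#' @param gene_overlap_fraction minimum fraction of a gene body covered by a
#'   domain for the gene to be called domain-resident (inclusive).
#' @param tpm_expressed TPM threshold for calling a gene expressed.
#' @param tpm_ge if TRUE the expression cut is `>=` instead of the default
#'   strict `>`.
#' @param deg_fc,deg_alpha fold-change and adjusted-p thresholds for calling
#'   differentially expressed genes (strict `>` on |log2FC| vs log2(deg_fc),
#'   strict `<` on p).
#' @param copy_fc,mirE_te_fc fold-change thresholds used for per-copy TE and
#'   knockdown TE differential calls respectively (consumed via
#'   [classify_degs()] with the matching `fc_threshold`).
#' @param te_z_threshold modified z-score cut for flagging enriched TE
#'   families (strict `>`).
#' @param n_shells number of radial shells for nuclear intensity profiles.
#' @param tem_square_um side of the TEM quantification square in micrometres.
#' @param tem_n_squares number of squares sampled per nuclear region.
#' @param hmm_states_to_try candidate HMM state counts for model selection.
#' @param seed default random seed for stochastic stages.
#'
#' @return a list of class `ladseg_config`.
#' @export
pipeline_config <- function(bin_size = 10000L,
                            antibody_constants = c(H3K9me2 = 3000, H3K9me3 = 7000,
                                                   LAP2b = 8000, LB1 = 8000),
                            gene_overlap_fraction = 0.90,
                            tpm_expressed = 5,
                            tpm_ge = FALSE,
                            deg_fc = 2,
                            deg_alpha = 0.05,
                            copy_fc = 10,
                            mirE_te_fc = 5,
                            te_z_threshold = 2,
                            n_shells = 25L,
                            tem_square_um = 0.2,
                            tem_n_squares = 40L,
                            hmm_states_to_try = 2:5,
                            seed = 1L) {
  cfg <- list(bin_size = as.integer(bin_size),
              antibody_constants = antibody_constants,
              gene_overlap_fraction = gene_overlap_fraction,
              tpm_expressed = tpm_expressed,
              tpm_ge = isTRUE(tpm_ge),
              deg_fc = deg_fc,
              deg_alpha = deg_alpha,
              copy_fc = copy_fc,
              mirE_te_fc = mirE_te_fc,
              te_z_threshold = te_z_threshold,
              n_shells = as.integer(n_shells),
              tem_square_um = tem_square_um,
              tem_n_squares = as.integer(tem_n_squares),
              hmm_states_to_try = as.integer(hmm_states_to_try),
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "ladseg_config"
  cfg
}

validate_config <- function(cfg) {
  num <- c("bin_size", "gene_overlap_fraction", "tpm_expressed", "deg_fc",
           "deg_alpha", "copy_fc", "mirE_te_fc", "te_z_threshold", "n_shells",
           "tem_square_um", "tem_n_squares")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !(cfg[[f]] > 0))
      stop("config field '", f, "' must be a single positive number", call. = FALSE)
  }
  if (cfg$gene_overlap_fraction > 1)
    stop("gene_overlap_fraction must be in (0, 1]", call. = FALSE)
  if (is.null(names(cfg$antibody_constants)) || any(cfg$antibody_constants <= 0))
    stop("antibody_constants must be a named vector of positive constants",
         call. = FALSE)
  invisible(cfg)
}

#' Read / write a configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_config` returns a `ladseg_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$antibody_constants <- unlist(raw$antibody_constants)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param cfg a `ladseg_config`.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$antibody_constants <- as.list(out$antibody_constants)  # keep names
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Lightweight INFO-level logger used by every pipeline stage; silenced via
# options(ladseg.quiet = TRUE) so tests stay readable.
ls_log <- function(...) {
  if (!isTRUE(getOption("ladseg.quiet", FALSE)))
    message("[ladseg] ", ...)
  invisible(NULL)
}
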