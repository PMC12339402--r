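#' Spike-in scale factor
#'
#' The scale factor for a sample is a per-antibody constant divided by the
#' number of properly paired spike-in reads, placing replicate CUT&RUN samples
#' on a common quantitative scale. Defaults use 3,000 for H3K9me2, 7,000 for
#' H3K9me3 and 8,000 for LAP2b/LB1.
#'
#' @param mark antibody name; must be present in `config$antibody_constants`.
#' @param n_spikein properly paired spike-in read count (> 0; no pseudo-count
#'   is applied).
#' @param config a [pipeline_config()].
#' @return list of class `scale_factor` with fields mark, constant, n_spikein,
#'   value.
#' @export
#' @examples
#' compute_scale_factor("H3K9me2", 6000)$value  # 0.5
compute_scale_factor <- function(mark, n_spikein, config = pipeline_config()) {
  if (!mark %in% names(config$antibody_constants))
    stop("unknown mark '", mark, "'; known marks: ",
         paste(names(config$antibody_constants), collapse = ", "), call. = FALSE)
  if (!is.numeric(n_spikein) || length(n_spikein) != 1L || n_spikein <= 0)
    stop("n_spikein must be a single count > 0 (no pseudo-count is applied)",
         call. = FALSE)
  C <- unname(config$antibody_constants[[mark]])
  structure(list(mark = mark, constant = C, n_spikein = n_spikein,
                 value = C / n_spikein),
            class = "scale_factor")
}

#' Fragment sets
#'
#' CUT&RUN fragments on the target genome together with the sample's spike-in
#' read count. The fragment count M is the "per million mapped" denominator of
#' RPKM.
#'
#' @param fragments interval data.frame of fragments.
#' @param n_spikein spike-in read count for the sample.
#' @param genome optional [genome_def()]; when given, fragments are bounds
#'   checked.
#' @return list of class `fragment_set` with fields fragments, n_spikein, M.
#' @export
fragment_set <- function(fragments, n_spikein, genome = NULL) {
  validate_intervals(fragments, "fragment")
  if (!is.null(genome)) {
    if (!all(fragments$chrom %in% names(genome)))
      stop("fragments on chromosomes absent from genome", call. = FALSE)
    if (any(fragments$end > genome[fragments$chrom]))
      stop("fragment beyond chromosome length", call. = FALSE)
  }
  structure(list(fragments = fragments, n_spikein = n_spikein,
                 M = nrow(fragments)),
            class = "fragment_set")
}

#' Bin fragments into RPKM coverage
#'
#' Each fragment is assigned to exactly one bin by its midpoint, so the total
#' assigned count over valid bins equals M minus fragments whose midpoints hit
#' blacklisted bins. RPKM for a bin with count c and actual length L (final
#' bins may be short) is c / ((L/1000) * (M/1e6)). Bins overlapping a
#' blacklist interval at any base are masked invalid rather than zeroed, so
#' they are excluded from normalization and segmentation.
#'
#' @param frags a [fragment_set()].
#' @param genome a [genome_def()].
#' @param bin_size bin width in bp.
#' @param blacklist optional interval data.frame of excluded regions.
#' @return a [binned_track()] of RPKM values.
#' @export
bin_rpkm <- function(frags, genome, bin_size, blacklist = NULL) {
  stopifnot(inherits(frags, "fragment_set"))
  fr <- frags$fragments
  M <- frags$M
  if (M == 0) stop("fragment set is empty (M = 0)", call. = FALSE)
  if (!all(fr$chrom %in% names(genome)))
    stop("fragment on chromosome absent from genome", call. = FALSE)
  if (any(fr$end > genome[fr$chrom]) || any(fr$start < 0))
    stop("fragment outside genome bounds", call. = FALSE)
  nb <- n_bins(genome, bin_size)
  values <- list(); mask <- list()
  for (ch in names(genome)) {
    sel <- fr$chrom == ch
    mid <- floor((fr$start[sel] + fr$end[sel]) / 2)
    bins <- pmin(floor(mid / bin_size) + 1L, nb[[ch]])
    counts <- tabulate(bins, nbins = nb[[ch]])
    L <- bin_lengths(genome[[ch]], bin_size)
    values[[ch]] <- counts / ((L / 1000) * (M / 1e6))
    mask[[ch]] <- rep(TRUE, nb[[ch]])
  }
  trk <- binned_track(genome, bin_size, values, mask)
  if (!is.null(blacklist) && nrow(blacklist)) trk <- mask_blacklist(trk, blacklist)
  trk
}

#' Mask blacklisted bins of a track
#'
#' Any bin overlapping a blacklist interval by at least one base becomes
#' invalid (any-overlap rule).
#'
#' @param trk a [binned_track()].
#' @param blacklist interval data.frame.
#' @return masked [binned_track()].
#' @export
mask_blacklist <- function(trk, blacklist) {
  validate_intervals(blacklist, "blacklist")
  for (i in seq_len(nrow(blacklist))) {
    ch <- blacklist$chrom[i]
    if (!ch %in% names(trk$genome)) next
    b0 <- floor(blacklist$start[i] / trk$bin_size) + 1L
    b1 <- ceiling(min(blacklist$end[i], trk$genome[[ch]]) / trk$bin_size)
    b1 <- min(b1, length(trk$mask[[ch]]))
    if (b0 > b1) next
    trk$mask[[ch]][b0:b1] <- FALSE
    trk$values[[ch]][b0:b1] <- NA_real_
  }
  trk
}

#' Apply a spike-in scale factor to a track
#'
#' Multiplies every valid bin by the scale factor; the validity mask is
#' preserved.
#'
#' @param trk a [binned_track()].
#' @param s a [compute_scale_factor()] result or a single positive number.
#' @return normalized [binned_track()].
#' @export
normalize_track <- function(trk, s) {
  v <- if (inherits(s, "scale_factor")) s$value else as.numeric(s)
  stopifnot(is.finite(v), v > 0)
  trk$values <- lapply(trk$values, function(x) x * v)
  trk
}

#' Average replicate tracks bin-wise
#'
#' Arithmetic mean per bin over tracks sharing a grid; a bin invalid in any
#' replicate is invalid in the average.
#'
#' @param tracks list of [binned_track()]s on an identical genome/bin grid.
#' @return a [binned_track()].
#' @export
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  ref <- tracks[[1L]]
  for (t in tracks[-1L])
    if (!same_grid(ref, t)) stop("tracks are on different grids", call. = FALSE)
  for (ch in names(ref$genome)) {
    vals <- do.call(rbind, lapply(tracks, function(t) t$values[[ch]]))
    msk <- do.call(rbind, lapply(tracks, function(t) t$mask[[ch]]))
    ok <- apply(msk, 2L, all)
    ref$values[[ch]] <- ifelse(ok, colMeans(vals), NA_real_)
    ref$mask[[ch]] <- ok
  }
  ref
}

#' Target-to-spike-in yield ratio
#'
#' Ratio of target-genome fragment count to spike-in read count, a proxy for
#' the quantitative yield of released target DNA relative to the fixed
#' spike-in amount. Under a genome-wide contact-loss perturbation the
#' mutant/wild-type ratio of yields tracks the contact-loss factor.
#'
#' @param M_target target fragment count.
#' @param n_spikein spike-in read count (> 0).
#' @return M_target / n_spikein.
#' @export
yield_ratio <- function(M_target, n_spikein) {
  if (!is.numeric(n_spikein) || n_spikein <= 0)
    stop("n_spikein must be > 0", call. = FALSE)
  M_target / n_spikein
}
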