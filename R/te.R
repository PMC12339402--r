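#' Per-family transposon signal
#'
#' Aggregates per-copy, per-replicate RPKM into one value per family and
#' mark: RPKM is first averaged across replicates within each copy, then
#' across copies within each family (unweighted mean; a length-weighted mean
#' is available via `weight_by_length`).
#'
#' @param copy_rpkm long data.frame with columns family, copy, replicate,
#'   rpkm and optionally length (bp, required for length weighting).
#' @param weight_by_length weight the copy average by copy length.
#' @return data.frame (family, mean_rpkm, n_copies). Families listed with
#'   zero copies (all-NA rpkm) come back with NA and a warning.
#' @export
family_signal <- function(copy_rpkm, weight_by_length = FALSE) {
  need <- c("family", "copy", "replicate", "rpkm")
  if (!all(need %in% names(copy_rpkm)))
    stop("copy_rpkm needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (weight_by_length && !"length" %in% names(copy_rpkm))
    stop("length column required for length weighting", call. = FALSE)
  # replicate average within copy
  per_copy <- aggregate(rpkm ~ family + copy, data = copy_rpkm, FUN = mean,
                        na.action = stats::na.pass)
  if (weight_by_length) {
    len <- copy_rpkm[!duplicated(copy_rpkm[c("family", "copy")]),
                     c("family", "copy", "length")]
    per_copy <- merge(per_copy, len, by = c("family", "copy"))
    fam <- lapply(split(per_copy, per_copy$family), function(d)
      data.frame(family = d$family[1L],
                 mean_rpkm = sum(d$rpkm * d$length) / sum(d$length),
                 n_copies = nrow(d)))
    out <- do.call(rbind, fam)
  } else {
    agg <- aggregate(rpkm ~ family, data = per_copy, FUN = mean,
                     na.action = stats::na.pass)
    nc <- aggregate(copy ~ family, data = per_copy, FUN = length)
    out <- data.frame(family = agg$family, mean_rpkm = agg$rpkm,
                      n_copies = nc$copy[match(agg$family, nc$family)])
  }
  if (anyNA(out$mean_rpkm))
    warning("families with no measured copies flagged NA: ",
            paste(out$family[is.na(out$mean_rpkm)], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Per-family signal from a binned track
#'
#' Alternative aggregation route: each TE copy's RPKM is the mean of the
#' valid track bins it overlaps, and the family value is the unweighted
#' mean over copies with at least one valid bin.
#'
#' @param trk a [binned_track()] of (normalized) RPKM.
#' @param te_annotation interval data.frame with a `family` column (or the
#'   `label` column holding the family name).
#' @return data.frame (family, mean_rpkm, n_copies).
#' @export
family_signal_from_track <- function(trk, te_annotation) {
  fam <- te_annotation$family
  if (is.null(fam)) fam <- te_annotation$label
  if (is.null(fam)) stop("te_annotation needs a family (or label) column",
                         call. = FALSE)
  per_copy <- rep(NA_real_, nrow(te_annotation))
  for (i in seq_len(nrow(te_annotation))) {
    ch <- te_annotation$chrom[i]
    if (!ch %in% names(trk$genome)) stop("TE copy on unknown chromosome ", ch,
                                         call. = FALSE)
    b0 <- floor(te_annotation$start[i] / trk$bin_size) + 1L
    b1 <- min(ceiling(te_annotation$end[i] / trk$bin_size),
              length(trk$values[[ch]]))
    v <- trk$values[[ch]][b0:b1]
    if (any(is.finite(v))) per_copy[i] <- mean(v, na.rm = TRUE)
  }
  agg <- tapply(per_copy, fam, function(v) mean(v[is.finite(v)]))
  nc <- tapply(is.finite(per_copy), fam, sum)
  out <- data.frame(family = names(agg), mean_rpkm = as.numeric(agg),
                    n_copies = as.integer(nc[names(agg)]),
                    stringsAsFactors = FALSE)
  if (any(out$n_copies == 0))
    warning("families with no measured copies flagged NA: ",
            paste(out$family[out$n_copies == 0], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Modified z-score of family signal
#'
#' Robust outlier statistic z_i = 0.6745 * (x_i - median) / MAD, where MAD is
#' the raw (unscaled) median absolute deviation from the median; the 0.6745
#' consistency factor is applied explicitly rather than folded into the MAD.
#' For even n the median is the mean of the central order statistics.
#'
#' @param values numeric vector of per-family replicate-averaged RPKM
#'   (length >= 2).
#' @return numeric vector of modified z-scores.
#' @export
#' @examples
#' modified_z(c(1, 2, 3, 4, 100))[5]  # 0.6745 * 97 = 65.4265
modified_z <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  med <- median(values)
  mad_raw <- median(abs(values - med))
  if (mad_raw == 0)
    stop("degenerate distribution: MAD = 0, modified z undefined", call. = FALSE)
  0.6745 * (values - med) / mad_raw
}

#' Flag enriched transposon families
#'
#' A family is enriched when its modified z-score strictly exceeds the
#' threshold for at least one of the configured marks (and/or rule; exactly
#' z = threshold is not enriched). Families with undefined z are excluded
#' with a warning.
#'
#' @param table data.frame with one RPKM column per mark (plus `family`).
#' @param marks columns to score.
#' @param threshold modified z cut (default 2).
#' @return the table with `z_<mark>` columns and a logical `enriched`
#'   column.
#' @export
flag_enriched <- function(table, marks = c("H3K9me2", "LAP2b"), threshold = 2) {
  missing <- setdiff(marks, names(table))
  if (length(missing))
    stop("table lacks mark column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  zs <- matrix(NA_real_, nrow(table), length(marks),
               dimnames = list(NULL, marks))
  for (mk in marks) {
    zs[, mk] <- modified_z(table[[mk]])
    table[[paste0("z_", mk)]] <- zs[, mk]
  }
  undef <- apply(zs, 1L, function(z) any(!is.finite(z)))
  if (any(undef))
    warning(sum(undef), " families with undefined z excluded from flagging")
  table$enriched <- !undef & apply(zs > threshold, 1L, any)
  table
}
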