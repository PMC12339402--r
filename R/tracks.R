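#' Binned signal tracks
#'
#' A binned signal track holds one value per fixed-width bin per chromosome,
#' plus a validity mask. Invalid bins (blacklisted, or absent from the source
#' file) carry NA and are excluded from normalization and segmentation. For a
#' chromosome of length L and bin size b there are ceiling(L/b) bins; the
#' final bin may be short.
#'
#' @param genome a [genome_def()] object.
#' @param bin_size bin width in bp.
#' @param values optional list (per chromosome) of numeric vectors, one per
#'   bin; default all-NA.
#' @param mask optional list of logical validity flags; default: valid where
#'   `values` is finite.
#' @return object of class `binned_track`.
#' @export
binned_track <- function(genome, bin_size, values = NULL, mask = NULL) {
  stopifnot(inherits(genome, "ladseg_genome"), bin_size >= 1)
  nb <- n_bins(genome, bin_size)
  if (is.null(values))
    values <- lapply(nb, function(n) rep(NA_real_, n))
  values <- values[names(genome)]
  if (is.null(mask))
    mask <- lapply(values, function(v) is.finite(v))
  mask <- mask[names(genome)]
  for (ch in names(genome)) {
    if (length(values[[ch]]) != nb[[ch]] || length(mask[[ch]]) != nb[[ch]])
      stop("chromosome ", ch, ": expected ", nb[[ch]], " bins", call. = FALSE)
    if (any(values[[ch]][mask[[ch]]] < 0, na.rm = TRUE))
      stop("valid bin values must be >= 0", call. = FALSE)
    values[[ch]][!mask[[ch]]] <- NA_real_
  }
  structure(list(genome = genome, bin_size = as.numeric(bin_size),
                 values = values, mask = mask),
            class = "binned_track")
}

#' Bin count per chromosome
#' @param genome a [genome_def()] object.
#' @param bin_size bin width in bp.
#' @return named integer vector, ceiling(length / bin_size) per chromosome.
#' @export
n_bins <- function(genome, bin_size) {
  setNames(as.integer(ceiling(as.numeric(genome) / bin_size)), names(genome))
}

# per-bin lengths for one chromosome (final bin may be short)
bin_lengths <- function(chrom_len, bin_size) {
  nb <- as.integer(ceiling(chrom_len / bin_size))
  len <- rep(bin_size, nb)
  len[nb] <- chrom_len - bin_size * (nb - 1)
  len
}

#' @export
print.binned_track <- function(x, ...) {
  nv <- sum(vapply(x$mask, sum, 0L))
  nt <- sum(vapply(x$mask, length, 0L))
  cat("<binned_track>", length(x$genome), "chromosomes,", x$bin_size,
      "bp bins,", nv, "/", nt, "valid bins\n")
  invisible(x)
}

#' Read a binned track from bedGraph
#'
#' Records must be aligned to the bin grid (start on a bin boundary, end at
#' the next boundary or the chromosome end). Bins not listed in the file are
#' invalid (masked).
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param genome a [genome_def()] object.
#' @param bin_size bin width in bp.
#' @return a [binned_track()].
#' @export
read_binned_track <- function(path, genome, bin_size) {
  trk <- binned_track(genome, bin_size)
  df <- tryCatch(
    read.table(path, sep = "\t", col.names = c("chrom", "start", "end", "value"),
               colClasses = c("character", "numeric", "numeric", "numeric")),
    error = function(e) NULL)
  if (is.null(df)) return(trk)  # empty file -> all bins invalid
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    if (!ch %in% names(genome))
      stop("bedGraph line ", i, ": unknown chromosome ", ch, call. = FALSE)
    L <- genome[[ch]]
    s <- df$start[i]; e <- df$end[i]
    if (e > L)
      stop("bedGraph line ", i, ": record beyond chromosome length", call. = FALSE)
    if (s %% bin_size != 0 || (e != s + bin_size && e != L))
      stop("bedGraph line ", i, ": record not aligned to ", bin_size,
           " bp bin grid", call. = FALSE)
    b <- s %/% bin_size + 1L
    trk$values[[ch]][b] <- df$value[i]
    trk$mask[[ch]][b] <- TRUE
  }
  trk
}

#' Write a binned track as bedGraph
#'
#' Only valid bins are written; invalid bins are omitted so a round trip
#' through [read_binned_track()] reproduces values and mask.
#'
#' @param trk a [binned_track()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_binned_track <- function(trk, path) {
  rows <- lapply(names(trk$genome), function(ch) {
    keep <- which(trk$mask[[ch]])
    if (!length(keep)) return(NULL)
    s <- (keep - 1) * trk$bin_size
    e <- pmin(s + trk$bin_size, trk$genome[[ch]])
    data.frame(chrom = ch, start = s, end = e, value = trk$values[[ch]][keep])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    file.create(path)
    return(invisible(path))
  }
  df$start <- format_coord(df$start)
  df$end <- format_coord(df$end)
  df$value <- format(df$value, digits = 17, scientific = FALSE, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# check two tracks share a grid
same_grid <- function(a, b) {
  identical(names(a$genome), names(b$genome)) &&
    isTRUE(all.equal(as.numeric(a$genome), as.numeric(b$genome))) &&
    a$bin_size == b$bin_size
}
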