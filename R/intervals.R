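#' Genome definition
#'
#' A genome is an ordered, named vector of chromosome lengths in bp. All
#' interval and track coordinates in the package are 0-based half-open (BED
#' convention); 1-based inputs are converted at the reader boundary.
#'
#' @param lengths named numeric vector of chromosome lengths (bp).
#' @return named numeric vector of class `ladseg_genome`.
#' @export
#' @examples
#' genome_def(c(chr1 = 5e6, chr2 = 3e6))
genome_def <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("all chromosomes must be named", call. = FALSE)
  if (anyDuplicated(names(lengths)))
    stop("chromosome names must be unique", call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  structure(setNames(as.numeric(lengths), names(lengths)),
            class = "ladseg_genome")
}

#' Construct a validated interval table
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` and
#' optionally `label`, in 0-based half-open coordinates.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates; `start < end` required.
#' @param label optional state/domain/name tag (recycled).
#' @return data.frame with columns chrom, start, end, label.
#' @export
genomic_intervals <- function(chrom, start, end, label = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   label = rep(as.character(label), length.out = length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(what, " validation: need 0 <= start < end, violated at row(s) ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  if (any(!nzchar(df$chrom)) || anyNA(df$chrom))
    stop(what, " validation: empty chromosome name", call. = FALSE)
  invisible(df)
}

#' Read intervals from BED or 1-based TSV
#'
#' BED input is 0-based half-open with columns chrom/start/end\[/name\].
#' `format = "tsv1"` reads a header-bearing TSV (columns `chrom`, `start`,
#' `end`, optional `name`) with 1-based inclusive coordinates, converted to
#' 0-based half-open on read.
#'
#' @param path input file.
#' @param format `"bed"` or `"tsv1"`.
#' @return interval data.frame (chrom, start, end, label), file order kept.
#' @export
read_intervals <- function(path, format = c("bed", "tsv1")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
      return(genomic_intervals(character(), numeric(), numeric()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    n <- lengths(parts)
    bad <- which(n < 3L)
    if (length(bad))
      stop("malformed BED line ", bad[1L], ": fewer than 3 columns", call. = FALSE)
    chrom <- vapply(parts, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(start) || anyNA(end)) {
      bad <- which(is.na(start) | is.na(end))[1L]
      stop("malformed BED line ", bad, ": non-numeric coordinate", call. = FALSE)
    }
    label <- ifelse(n >= 4L, vapply(parts, function(p) p[min(4L, length(p))], ""),
                    NA_character_)
    df <- data.frame(chrom = chrom, start = start, end = end, label = label,
                     stringsAsFactors = FALSE)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(df)))
      stop("tsv1 input must have columns chrom, start, end", call. = FALSE)
    df <- data.frame(chrom = as.character(df$chrom),
                     start = as.numeric(df$start) - 1,  # 1-based -> 0-based
                     end = as.numeric(df$end),
                     label = if ("name" %in% names(df)) as.character(df$name)
                             else NA_character_,
                     stringsAsFactors = FALSE)
  }
  validate_intervals(df)
  df
}

#' Write intervals as BED
#'
#' Emits BED3 when every label is NA, BED4 otherwise.
#'
#' @param df interval data.frame.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_intervals <- function(df, path) {
  validate_intervals(df)
  out <- df[, c("chrom", "start", "end")]
  out$start <- format_coord(out$start)
  out$end <- format_coord(out$end)
  if (!all(is.na(df$label))) out$label <- df$label
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Domain sets
#'
#' A domain set is a sorted, non-overlapping labeled interval collection for
#' one mark and one sample (or replicate consensus).
#'
#' @param intervals interval data.frame; merged/sorted on construction if
#'   needed (overlapping or bookended intervals are unioned).
#' @param mark antibody/mark name.
#' @param sample sample or condition label.
#' @param label label applied to intervals whose label is NA.
#' @return object of class `domain_set`.
#' @export
domain_set <- function(intervals, mark = "", sample = "", label = "domain") {
  validate_intervals(intervals, "domain")
  if (is.null(intervals$label))
    intervals$label <- rep(NA_character_, nrow(intervals))
  intervals$label[is.na(intervals$label)] <- label
  o <- order(intervals$chrom, intervals$start, intervals$end)
  if (any(o != seq_along(o))) intervals <- intervals[o, , drop = FALSE]
  # enforce non-overlap by merging overlapping/bookended intervals per label
  if (nrow(intervals) > 1L) {
    merged <- lapply(split(intervals, intervals$label), function(d) {
      red <- GenomicRanges::reduce(intervals_to_granges(d), min.gapwidth = 1L)
      if (length(red) != nrow(d)) granges_to_intervals(red, label = d$label[1L])
      else d
    })
    intervals <- do.call(rbind, merged)
    o <- order(intervals$chrom, intervals$start, intervals$end)
    intervals <- intervals[o, , drop = FALSE]
  }
  rownames(intervals) <- NULL
  structure(list(intervals = intervals, mark = mark, sample = sample),
            class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cat("<domain_set>", x$mark, x$sample, "-", nrow(x$intervals),
      "intervals,", sum(x$intervals$end - x$intervals$start) / 1e6, "Mb\n")
  invisible(x)
}

#' Write a domain set as a BED file
#'
#' Output is BED4 (chrom, start, end, label), 0-based half-open, ordered by
#' (chrom, start). Unsorted input is sorted with a logged notice.
#'
#' @param domains a `domain_set` or interval data.frame.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_domains <- function(domains, path) {
  df <- if (inherits(domains, "domain_set")) domains$intervals else domains
  o <- order(df$chrom, df$start)
  if (any(o != seq_len(nrow(df)))) {
    ls_log("write_domains: input unsorted; sorting by (chrom, start)")
    df <- df[o, , drop = FALSE]
  }
  df$label[is.na(df$label)] <- "domain"
  write_intervals(df, path)
}

# --- GRanges bridge (internal): 0-based half-open <-> 1-based closed --------

intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

granges_to_intervals <- function(gr, label = NA_character_) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             label = label, stringsAsFactors = FALSE)
}
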