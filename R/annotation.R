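#' Fraction of a gene body covered by domains
#'
#' Coverage is computed against the union of the (non-overlapping) domain
#' intervals: the summed overlap in bp divided by the gene length. A gene is
#' domain-resident when its coverage meets the configured fraction
#' (inclusive; 0.90 by default, so exactly 90% covered is a member).
#'
#' @param gene a single-row interval data.frame (or list with chrom, start,
#'   end).
#' @param domains a [domain_set()].
#' @return coverage fraction in \[0, 1\].
#' @export
gene_domain_coverage <- function(gene, domains) {
  if (gene$end <= gene$start) stop("zero-length gene", call. = FALSE)
  df <- data.frame(chrom = gene$chrom, start = gene$start, end = gene$end,
                   label = NA_character_)
  gene_domain_coverage_vec(df, domains)
}

# vectorized coverage for a gene table against one domain set
gene_domain_coverage_vec <- function(genes, domains) {
  if (any(genes$end <= genes$start)) stop("zero-length gene", call. = FALSE)
  if (!nrow(genes)) return(numeric())
  if (!nrow(domains$intervals)) return(rep(0, nrow(genes)))
  g <- intervals_to_granges(genes)
  d <- intervals_to_granges(domains$intervals)
  hits <- GenomicRanges::findOverlaps(g, d)
  ov <- GenomicRanges::pintersect(g[S4Vectors::queryHits(hits)],
                                  d[S4Vectors::subjectHits(hits)])
  bp <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
  out <- rep(0, nrow(genes))
  out[as.integer(names(bp))] <- as.numeric(bp)
  out / (genes$end - genes$start)
}

#' Domain class schemes
#'
#' A class scheme names the boolean membership patterns over a mark set. The
#' naive mES scheme over (LB1, LAP2b, H3K9me2) defines LADs (all three),
#' LB1+LAP2b domains (both lamina marks without H3K9me2), KODs (H3K9me2
#' only) and non-LADs (no mark); the remaining patterns keep systematic
#' names built from their marks. The EpiLC scheme uses two marks (LB1,
#' H3K9me2) because the LAP2b signal is not a reliable lamina fiducial in
#' that state: LAD (both), LB1_only, KOD (H3K9me2 only), nonLAD.
#'
#' @return list of class `class_scheme` with fields `marks` and `classify`,
#'   a function from a named logical membership vector to a class label.
#' @export
mes_class_scheme <- function() {
  classify <- function(m) {
    if (m[["LB1"]] && m[["LAP2b"]] && m[["H3K9me2"]]) return("LAD")
    if (m[["LB1"]] && m[["LAP2b"]]) return("LB1_LAP2b")
    if (m[["H3K9me2"]] && !m[["LB1"]] && !m[["LAP2b"]]) return("KOD")
    if (!any(m)) return("nonLAD")
    paste(names(m)[m], collapse = "_")  # residual patterns, systematic names
  }
  structure(list(marks = c("LB1", "LAP2b", "H3K9me2"), classify = classify),
            class = "class_scheme")
}

#' @rdname mes_class_scheme
#' @export
epilc_class_scheme <- function() {
  classify <- function(m) {
    if (m[["LB1"]] && m[["H3K9me2"]]) return("LAD")
    if (m[["LB1"]]) return("LB1_only")
    if (m[["H3K9me2"]]) return("KOD")
    "nonLAD"
  }
  structure(list(marks = c("LB1", "H3K9me2"), classify = classify),
            class = "class_scheme")
}

#' Assign genes to domain classes
#'
#' Computes the per-mark gene-body coverage fraction against each mark's
#' domain set, derives membership with the configured overlap rule, and
#' labels every gene with exactly one class from the scheme (the patterns
#' partition the space, so class counts always sum to the gene total).
#'
#' @param genes gene table (gene_id, chrom, start, end, optional biotype).
#' @param domain_sets named list of [domain_set()]s covering the scheme's
#'   marks.
#' @param scheme a [mes_class_scheme()] / [epilc_class_scheme()].
#' @param config a [pipeline_config()].
#' @return `gene_domain_table`: the gene table plus `cov_<mark>`,
#'   `in_<mark>` and `class` columns.
#' @export
assign_classes <- function(genes, domain_sets, scheme = mes_class_scheme(),
                           config = pipeline_config()) {
  missing_marks <- setdiff(scheme$marks, names(domain_sets))
  if (length(missing_marks))
    stop("missing domain sets for mark(s): ",
         paste(missing_marks, collapse = ", "), call. = FALSE)
  out <- genes
  member <- matrix(FALSE, nrow(genes), length(scheme$marks),
                   dimnames = list(NULL, scheme$marks))
  for (mk in scheme$marks) {
    cov <- gene_domain_coverage_vec(genes, domain_sets[[mk]])
    out[[paste0("cov_", mk)]] <- cov
    member[, mk] <- cov >= config$gene_overlap_fraction
    out[[paste0("in_", mk)]] <- member[, mk]
  }
  out$class <- vapply(seq_len(nrow(genes)), function(i)
    scheme$classify(member[i, ]), "")
  class(out) <- c("gene_domain_table", class(out))
  out
}

#' Genome overlap accounting across marks
#'
#' Partitions the covered genome into the 2^m - 1 boolean membership
#' patterns over the given domain sets (UpSet-style accounting) and reports
#' the Mb in each pattern. Pattern masses sum exactly to the union of all
#' domain sets.
#'
#' @param domain_sets named list of [domain_set()]s.
#' @return data.frame (pattern, one logical column per mark, Mb), sorted by
#'   decreasing Mb.
#' @export
overlap_accounting <- function(domain_sets) {
  marks <- names(domain_sets)
  stopifnot(length(marks) >= 1L)
  grs <- lapply(domain_sets, function(d) intervals_to_granges(d$intervals))
  all_gr <- do.call(c, unname(grs))
  if (!length(all_gr))
    return(data.frame(pattern = character(), Mb = numeric()))
  pieces <- GenomicRanges::disjoin(all_gr)
  member <- vapply(grs, function(g)
    IRanges::overlapsAny(pieces, g), logical(length(pieces)))
  if (length(pieces) == 1L) member <- matrix(member, nrow = 1L,
                                             dimnames = list(NULL, marks))
  key <- apply(member, 1L, function(m) paste(marks[m], collapse = "&"))
  bp <- tapply(GenomicRanges::width(pieces), key, sum)
  pat <- names(bp)
  df <- data.frame(pattern = pat, Mb = as.numeric(bp) / 1e6,
                   stringsAsFactors = FALSE)
  for (mk in marks)
    df[[mk]] <- vapply(strsplit(df$pattern, "&", fixed = TRUE),
                       function(p) mk %in% p, TRUE)
  df[order(-df$Mb), c("pattern", marks, "Mb")]
}

#' Proportion of expressed genes in a class
#'
#' Fraction of the class's genes with TPM strictly above the expression
#' threshold (or `>=` when the config's `tpm_ge` toggle is set). An empty
#' class yields NA with a warning rather than a silent zero.
#'
#' @param table a [assign_classes()] result carrying a `TPM` column (join
#'   your TPM table first) .
#' @param class class label to summarize.
#' @param config a [pipeline_config()].
#' @return fraction in \[0, 1\], or NA for an empty class.
#' @export
expressed_proportion <- function(table, class, config = pipeline_config()) {
  if (!"TPM" %in% names(table))
    stop("table has no TPM column", call. = FALSE)
  sel <- table$class == class
  if (!any(sel)) {
    warning("no genes in class '", class, "'; proportion undefined")
    return(NA_real_)
  }
  tpm <- table$TPM[sel]
  expressed <- if (config$tpm_ge) tpm >= config$tpm_expressed
               else tpm > config$tpm_expressed
  mean(expressed)
}

#' Classify differentially expressed genes
#'
#' A gene is up when log2FC strictly exceeds log2(fc_threshold) with
#' adjusted p strictly below alpha; down symmetrically; otherwise unchanged.
#' A gene at exactly the fold-change boundary is unchanged.
#'
#' @param de_table data.frame with `log2FC` and `padj` columns.
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return `de_table` with a `de_status` factor column
#'   (up/down/unchanged).
#' @export
classify_degs <- function(de_table, fc_threshold = 2, alpha = 0.05) {
  if (!all(c("log2FC", "padj") %in% names(de_table)))
    stop("de_table must have columns log2FC and padj", call. = FALSE)
  lfc <- log2(fc_threshold)
  up <- de_table$log2FC > lfc & de_table$padj < alpha
  down <- de_table$log2FC < -lfc & de_table$padj < alpha
  de_table$de_status <- factor(ifelse(up, "up", ifelse(down, "down", "unchanged")),
                               levels = c("up", "down", "unchanged"))
  de_table
}

#' Two-sided exact enrichment of DEGs in a domain class
#'
#' Builds the 2x2 table (DEG in class / DEG outside / non-DEG in class /
#' non-DEG outside) and computes the sample odds ratio (0 or Inf permitted on
#' zero cells) and the two-sided exact p-value: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's (within a 1e-12 relative tolerance).
#' A zero margin gives p = 1 by convention.
#'
#' @param table a classified gene table with `class` and `de_status`.
#' @param class domain class of interest.
#' @param direction `"up"`, `"down"`, or `"any"` (up or down).
#' @return list of class `enrichment_result`: counts, odds_ratio, p_value.
#' @export
deg_class_enrichment <- function(table, class, direction = c("up", "down", "any")) {
  direction <- match.arg(direction)
  is_deg <- if (direction == "any") table$de_status != "unchanged"
            else table$de_status == direction
  in_class <- table$class == class
  counts <- c(deg_in = sum(is_deg & in_class),
              deg_out = sum(is_deg & !in_class),
              nondeg_in = sum(!is_deg & in_class),
              nondeg_out = sum(!is_deg & !in_class))
  res <- fisher_exact_2x2(counts[["deg_in"]], counts[["deg_out"]],
                          counts[["nondeg_in"]], counts[["nondeg_out"]])
  structure(list(class = class, direction = direction, counts = counts,
                 odds_ratio = res$odds_ratio, p_value = res$p_value),
            class = "enrichment_result")
}

#' Two-sided exact test for a 2x2 table
#'
#' Conditional on both margins, table probabilities follow the
#' hypergeometric distribution; the two-sided p-value sums the probabilities
#' of every table as or less probable than the observed one (relative
#' tolerance factor 1 + 1e-12 guards against ties lost to rounding). The
#' odds ratio is the sample ratio a*d / (b*c), with 0 and Inf permitted.
#'
#' @param a,b,c,d cell counts (a,b = row 1; c,d = row 2).
#' @return list(odds_ratio, p_value).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c)
  m <- a + c; n2 <- b + d; k <- a + b
  if (m == 0 || n2 == 0 || k == 0 || (c + d) == 0) {
    ls_log("fisher_exact_2x2: zero margin, p = 1 by convention")
    return(list(odds_ratio = or, p_value = 1))
  }
  support <- max(0, k - n2):min(k, m)
  dens <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-12)])
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Domain-class transitions between cell states
#'
#' Labels every gene by its path between the naive (mES) and primed (EpiLC)
#' class assignments: cLAD (LAD in both), cKOD (KOD in both), newKOD
#' (non-LAD to KOD), LAD_to_LB1 (LAD to LB1-only), nonLAD (non-LAD in
#' both); everything else is kept in an explicit "other" bucket. The mES
#' side counts LB1+LAP2b+H3K9me2 LADs; the EpiLC side uses the two-mark
#' scheme.
#'
#' @param table_mes [assign_classes()] result for the naive state.
#' @param table_epilc [assign_classes()] result for the primed state (EpiLC
#'   scheme).
#' @return list: `table` (gene_id, class_mes, class_epilc, transition),
#'   `counts` (named table of transition labels).
#' @export
transition_classes <- function(table_mes, table_epilc) {
  missing <- c(setdiff(table_mes$gene_id, table_epilc$gene_id),
               setdiff(table_epilc$gene_id, table_mes$gene_id))
  if (length(missing))
    stop("gene universe mismatch; missing: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  idx <- match(table_mes$gene_id, table_epilc$gene_id)
  cm <- table_mes$class
  ce <- table_epilc$class[idx]
  lab <- ifelse(cm == "LAD" & ce == "LAD", "cLAD",
         ifelse(cm == "KOD" & ce == "KOD", "cKOD",
         ifelse(cm == "nonLAD" & ce == "KOD", "newKOD",
         ifelse(cm == "LAD" & ce == "LB1_only", "LAD_to_LB1",
         ifelse(cm == "nonLAD" & ce == "nonLAD", "nonLAD", "other")))))
  df <- data.frame(gene_id = table_mes$gene_id, class_mes = cm,
                   class_epilc = ce, transition = lab,
                   stringsAsFactors = FALSE)
  list(table = df, counts = table(factor(lab, levels = c("cLAD", "cKOD",
       "newKOD", "LAD_to_LB1", "nonLAD", "other"))))
}
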