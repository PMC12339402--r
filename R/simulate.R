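#' Simulation parameters
#'
#' Parameters of the synthetic-data generator that emulates the statistical
#' structure of spike-in controlled CUT&RUN over a two-state (background /
#' lamina-contact) genome, class-dependent gene expression, transposon-family
#' signal tables and nuclear marker images. Defaults describe a desk-scale
#' study: 2 chromosomes x 50 Mb at 10 kb bins (10,000 bins), 3 replicates per
#' condition, megabase-scale domains (stay probabilities 0.995 give a 2 Mb
#' mean domain length), overdispersed negative-binomial bin counts, and
#' ~1,200 TE families with a small strongly-enriched subset.
#'
#' @param n_chromosomes,chrom_length,bin_size genome geometry (bp).
#' @param n_replicates replicates per condition.
#' @param stay_background,stay_domain Markov-chain stay probabilities; the
#'   mean domain length is bin_size / (1 - stay_domain).
#' @param mu_background,mu_domain,nb_dispersion negative-binomial mean per
#'   background/domain bin and the NB size parameter (Poisson as size -> Inf).
#' @param fragment_length simulated fragment length (bp).
#' @param spikein_expected expected spike-in read count per sample (Poisson).
#' @param n_genes number of genes; lengths uniform on
#'   `gene_length_range` (bp).
#' @param gene_length_range gene length range in bp.
#' @param p_expressed named class-specific probabilities that a gene is
#'   expressed (free parameters of the generator, not measured values).
#' @param derepressed_fraction fraction of LAD genes derepressed in the
#'   mutant genotype DE table.
#' @param n_te_families,te_enriched_fraction,te_shift_mads TE table size, the
#'   fraction of families drawn from the shifted (enriched) distribution, and
#'   the shift in units of the null MAD.
#' @param te_null_mean,te_null_sd,te_mark_cor null RPKM location/scale and
#'   the between-mark correlation of a family's signal.
#' @param image_size,pixel_size,nucleus_radii image geometry (px, um/px, px).
#' @param ring_fraction peripheral ring width as a fraction of the nuclear
#'   depth; amplitude `ring_amplitude`; additive Gaussian noise sd
#'   `image_noise_sd` (clipped at 0).
#' @param ring_amplitude marker amplitude inside the pattern.
#' @param image_noise_sd additive Gaussian noise sd.
#' @param n_foci number of interior foci for the internal pattern.
#' @param seed default generator seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_chromosomes = 2L, chrom_length = 50e6, bin_size = 10000L,
                       n_replicates = 3L,
                       stay_background = 0.995, stay_domain = 0.995,
                       mu_background = 20, mu_domain = 80, nb_dispersion = 20,
                       fragment_length = 150L,
                       spikein_expected = 3000,
                       n_genes = 2000L, gene_length_range = c(2e3, 2e5),
                       p_expressed = c(nonLAD = 0.6, KOD = 0.35,
                                       LB1_LAP2b = 0.35, LAD = 0.1, other = 0.35),
                       derepressed_fraction = 0.1,
                       n_te_families = 1200L, te_enriched_fraction = 0.05,
                       te_shift_mads = 10, te_null_mean = 10, te_null_sd = 1,
                       te_mark_cor = 0.8,
                       image_size = 192L, pixel_size = 0.1,
                       nucleus_radii = c(80, 60), ring_fraction = 0.08,
                       ring_amplitude = 100, image_noise_sd = 0, n_foci = 12L,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_chromosomes >= 1, p$chrom_length >= p$bin_size,
            p$n_replicates >= 1,
            p$stay_background > 0, p$stay_background <= 1,
            p$stay_domain > 0, p$stay_domain <= 1,
            p$mu_background > 0, p$mu_domain > 0, p$nb_dispersion > 0,
            all(p$p_expressed >= 0), all(p$p_expressed <= 1),
            p$te_enriched_fraction >= 0, p$te_enriched_fraction <= 1)
  class(p) <- "sim_params"
  p
}

# derive a per-purpose 32-bit seed from a base seed and a stream name, so each
# stage draws from an independent substream
stage_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Simulate a ground-truth domain landscape
#'
#' Draws, per chromosome, a first-order Markov chain over
#' \{background, domain\} at bin resolution for the LAD landscape (positive
#' for LB1, LAP2b and H3K9me2) and a second, independent chain for
#' H3K9me2-only domains (KODs) placed in the non-LAD background. Genes are
#' placed uniformly and labeled with their true class by applying the
#' gene-overlap rule to the true domains.
#'
#' @param params a [sim_params()].
#' @param seed RNG seed.
#' @param config a [pipeline_config()] supplying the overlap fraction.
#' @return list of class `sim_truth`: genome, per-mark [domain_set()]s
#'   (`domains`), gene table with true class (`genes`), emission/transition
#'   ground truth (`emission`, `stay`).
#' @export
simulate_genome <- function(params = sim_params(), seed = params$seed,
                            config = pipeline_config()) {
  set.seed(stage_seed(seed, "genome"))
  if (params$chrom_length < params$bin_size)
    stop("chromosome shorter than one bin", call. = FALSE)
  genome <- genome_def(setNames(rep(params$chrom_length, params$n_chromosomes),
                                paste0("chr", seq_len(params$n_chromosomes))))
  lad <- markov_intervals(genome, params$bin_size, params$stay_background,
                          params$stay_domain)
  kod_raw <- markov_intervals(genome, params$bin_size, params$stay_background,
                              params$stay_domain)
  # KODs live outside LADs: subtract the LAD landscape
  kod <- setdiff_intervals(kod_raw, lad)

  h3k9me2 <- union_intervals(lad, kod)
  domains <- list(
    LB1 = domain_set(lad, mark = "LB1", sample = "truth"),
    LAP2b = domain_set(lad, mark = "LAP2b", sample = "truth"),
    H3K9me2 = domain_set(h3k9me2, mark = "H3K9me2", sample = "truth"))

  genes <- place_genes(genome, params)
  cov <- vapply(domains, function(d)
    gene_domain_coverage_vec(genes, d), numeric(nrow(genes)))
  member <- cov >= config$gene_overlap_fraction
  genes$class <- apply(member, 1L, function(m) {
    if (all(m)) "LAD"
    else if (m[["LB1"]] && m[["LAP2b"]]) "LB1_LAP2b"
    else if (m[["H3K9me2"]] && !m[["LB1"]] && !m[["LAP2b"]]) "KOD"
    else if (!any(m)) "nonLAD"
    else "other"
  })

  structure(list(genome = genome, domains = domains, genes = genes,
                 emission = c(background = params$mu_background,
                              domain = params$mu_domain),
                 stay = c(background = params$stay_background,
                          domain = params$stay_domain),
                 params = params),
            class = "sim_truth")
}

# one two-state Markov chain per chromosome -> domain-state intervals
markov_intervals <- function(genome, bin_size, stay_bg, stay_dom) {
  out <- list()
  for (ch in names(genome)) {
    nb <- as.integer(ceiling(genome[[ch]] / bin_size))
    # stationary start; degenerate chains resolve to all-background
    leave_bg <- 1 - stay_bg; leave_dom <- 1 - stay_dom
    p_dom <- if (leave_bg + leave_dom == 0) 0 else leave_bg / (leave_bg + leave_dom)
    states <- integer(nb)
    states[1L] <- rbinom(1L, 1L, p_dom)
    u <- runif(nb)
    for (i in seq_len(nb - 1L)) {
      stay <- if (states[i] == 1L) stay_dom else stay_bg
      states[i + 1L] <- if (u[i] < stay) states[i] else 1L - states[i]
    }
    r <- rle(states == 1L)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = (starts[j] - 1) * bin_size,
        end = min(ends[j] * bin_size, genome[[ch]]),
        label = "domain", stringsAsFactors = FALSE)
  }
  if (!length(out)) return(genomic_intervals(character(), numeric(), numeric()))
  do.call(rbind, out)
}

setdiff_intervals <- function(a, b) {
  if (!nrow(a)) return(a)
  if (!nrow(b)) return(a)
  gr <- GenomicRanges::setdiff(intervals_to_granges(a), intervals_to_granges(b))
  if (!length(gr)) return(genomic_intervals(character(), numeric(), numeric()))
  granges_to_intervals(gr, label = "domain")
}

union_intervals <- function(a, b) {
  both <- rbind(a[nrow(a) > 0, ], b[nrow(b) > 0, ])
  if (!nrow(both)) return(genomic_intervals(character(), numeric(), numeric()))
  gr <- GenomicRanges::reduce(intervals_to_granges(both), min.gapwidth = 1L)
  granges_to_intervals(gr, label = "domain")
}

place_genes <- function(genome, params) {
  n <- params$n_genes
  ch <- sample(names(genome), n, replace = TRUE,
               prob = as.numeric(genome) / sum(genome))
  len <- round(runif(n, params$gene_length_range[1L], params$gene_length_range[2L]))
  len <- pmin(len, floor(as.numeric(genome[ch]) / 2))  # fit small test genomes
  start <- floor(runif(n, 0, genome[ch] - len))
  data.frame(gene_id = sprintf("gene%05d", seq_len(n)), chrom = ch,
             start = start, end = start + len,
             biotype = sample(c("protein_coding", "lncRNA", "pseudogene"), n,
                              replace = TRUE, prob = c(0.6, 0.25, 0.15)),
             stringsAsFactors = FALSE)
}

#' Simulate spike-in controlled CUT&RUN replicates
#'
#' Per replicate, draws a negative-binomial fragment count in every bin with
#' a state-dependent mean: background bins at `mu_background`, domain bins at
#' mu_background + factor * (mu_domain - mu_background), where the
#' genotype's contact-loss factor scales the domain signal above background
#' (1 = wild type, 0 = complete contact loss). Fragments are placed uniformly
#' within their bin; each sample draws a Poisson spike-in read count.
#'
#' @param truth a [simulate_genome()] result.
#' @param params a [sim_params()] (genome/bin geometry must match `truth`).
#' @param mark which mark's true domains drive the signal.
#' @param contact_loss_factor genotype multiplier on the above-background
#'   domain signal.
#' @param seed RNG seed.
#' @return list of class `sim_cutrun`: `replicates` (each a
#'   [fragment_set()]), `mark`, `contact_loss_factor`.
#' @export
simulate_cutrun <- function(truth, params = truth$params, mark = "H3K9me2",
                            contact_loss_factor = 1, seed = params$seed) {
  stopifnot(inherits(truth, "sim_truth"), mark %in% names(truth$domains),
            contact_loss_factor >= 0)
  set.seed(stage_seed(seed, paste0("cutrun_", mark, "_", contact_loss_factor)))
  genome <- truth$genome
  bs <- params$bin_size
  dom <- truth$domains[[mark]]$intervals
  mu_dom_eff <- params$mu_background +
    contact_loss_factor * (params$mu_domain - params$mu_background)

  # per-chromosome bin state from the true domain intervals
  state <- lapply(names(genome), function(ch) {
    nb <- as.integer(ceiling(genome[[ch]] / bs))
    s <- logical(nb)
    d <- dom[dom$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      b0 <- floor(d$start[i] / bs) + 1L
      b1 <- ceiling(d$end[i] / bs)
      s[b0:min(b1, nb)] <- TRUE
    }
    s
  })
  names(state) <- names(genome)

  reps <- vector("list", params$n_replicates)
  for (r in seq_len(params$n_replicates)) {
    frs <- list()
    for (ch in names(genome)) {
      s <- state[[ch]]
      nb <- length(s)
      mu <- ifelse(s, mu_dom_eff, params$mu_background)
      counts <- rnbinom(nb, size = params$nb_dispersion, mu = mu)
      tot <- sum(counts)
      if (tot == 0) next
      bin_idx <- rep.int(seq_len(nb), counts)
      L <- bin_lengths(genome[[ch]], bs)[bin_idx]
      offset <- floor(runif(tot) * pmax(L - params$fragment_length, 1))
      start <- (bin_idx - 1) * bs + offset
      end <- pmin(start + params$fragment_length, genome[[ch]])
      frs[[ch]] <- data.frame(chrom = ch, start = start, end = end,
                              label = NA_character_, stringsAsFactors = FALSE)
    }
    fr <- do.call(rbind, frs)
    rownames(fr) <- NULL
    n_spike <- rpois(1L, params$spikein_expected)
    reps[[r]] <- fragment_set(fr, n_spikein = n_spike, genome = genome)
  }
  structure(list(replicates = reps, mark = mark,
                 contact_loss_factor = contact_loss_factor),
            class = "sim_cutrun")
}

#' Simulate expression and differential-expression tables
#'
#' Each gene is expressed with a class-specific probability (defaults:
#' non-LAD 0.6, KOD 0.35, LAD 0.1 - free generator parameters). Expressed
#' genes draw TPM strictly above the expression threshold; silent genes draw
#' below it. A configurable fraction of LAD genes is flagged derepressed in
#' the mutant genotype with log2FC > 1 and adjusted p < 0.05; remaining genes
#' get null fold changes and non-significant p values.
#'
#' @param truth a [simulate_genome()] result.
#' @param params a [sim_params()].
#' @param seed RNG seed.
#' @return list: `tpm` (gene_id, TPM), `de` (gene_id, log2FC, padj),
#'   `derepressed` (gene ids of the planted derepressed subset).
#' @export
simulate_expression <- function(truth, params = truth$params,
                                seed = params$seed) {
  set.seed(stage_seed(seed, "expression"))
  genes <- truth$genes
  known <- names(params$p_expressed)
  bad <- setdiff(unique(genes$class), known)
  if (length(bad))
    stop("unknown gene class: ", paste(bad, collapse = ", "), call. = FALSE)
  p <- params$p_expressed[genes$class]
  expressed <- runif(nrow(genes)) < p
  tpm <- ifelse(expressed,
                5 + rlnorm(nrow(genes), meanlog = 2.5, sdlog = 1),
                runif(nrow(genes), 0, 5))

  lad_genes <- genes$gene_id[genes$class == "LAD"]
  n_dep <- round(params$derepressed_fraction * length(lad_genes))
  dep <- if (n_dep > 0) sample(lad_genes, n_dep) else character()
  is_dep <- genes$gene_id %in% dep
  log2fc <- ifelse(is_dep, 1 + runif(nrow(genes), 0.2, 2.5),
                   rnorm(nrow(genes), 0, 0.2))
  padj <- ifelse(is_dep, runif(nrow(genes), 0, 0.049),
                 runif(nrow(genes), 0.05, 1))
  list(tpm = data.frame(gene_id = genes$gene_id, TPM = tpm,
                        stringsAsFactors = FALSE),
       de = data.frame(gene_id = genes$gene_id, log2FC = log2fc, padj = padj,
                       stringsAsFactors = FALSE),
       derepressed = dep)
}

#' Simulate a transposon-family signal table
#'
#' Most families draw replicate-averaged RPKM for each mark from a correlated
#' null (a shared per-family level plus mark-specific noise, mimicking the
#' fact that lamina-proximal families carry both marks); a designated subset
#' is shifted upward on both marks by `te_shift_mads` null-MAD units so its
#' modified z-score exceeds the enrichment threshold.
#'
#' @param params a [sim_params()].
#' @param seed RNG seed.
#' @param marks mark names for the table columns.
#' @return list: `table` (family, te_class, one RPKM column per mark),
#'   `enriched` (planted enriched family names).
#' @export
simulate_te_table <- function(params = sim_params(), seed = params$seed,
                              marks = c("H3K9me2", "LAP2b")) {
  set.seed(stage_seed(seed, "te"))
  n <- params$n_te_families
  fam <- sprintf("TEfam%04d", seq_len(n))
  te_class <- sample(c("LINE", "LTR", "SINE", "other"), n, replace = TRUE,
                     prob = c(0.35, 0.35, 0.2, 0.1))
  n_enr <- round(params$te_enriched_fraction * n)
  enriched <- if (n_enr > 0) sample(fam, n_enr) else character()
  is_enr <- fam %in% enriched

  sd_shared <- params$te_null_sd * sqrt(params$te_mark_cor)
  sd_noise <- params$te_null_sd * sqrt(1 - params$te_mark_cor)
  base <- rnorm(n, params$te_null_mean, sd_shared)
  shift <- params$te_shift_mads * 0.6745 * params$te_null_sd
  tab <- data.frame(family = fam, te_class = te_class, stringsAsFactors = FALSE)
  for (mk in marks) {
    x <- base + rnorm(n, 0, sd_noise) + ifelse(is_enr, shift, 0)
    tab[[mk]] <- pmax(x, 0)
  }
  list(table = tab, enriched = enriched)
}

#' Simulate a nucleus image
#'
#' Builds an elliptical binary nucleus mask and a marker channel with one of
#' three spatial modes: `peripheral` (a ring of the stated depth fraction at
#' the mask boundary, as in wild-type lamina-tethered heterochromatin),
#' `internal` (interior Gaussian foci, as after tether loss) or `uniform`.
#' Additive Gaussian noise is clipped at zero.
#'
#' @param params a [sim_params()].
#' @param mode `"peripheral"`, `"internal"` or `"uniform"`.
#' @param seed RNG seed.
#' @return a [nucleus_image()].
#' @export
simulate_nucleus <- function(params = sim_params(),
                             mode = c("peripheral", "internal", "uniform"),
                             seed = params$seed) {
  mode <- match.arg(mode)
  set.seed(stage_seed(seed, paste0("nucleus_", mode)))
  n <- params$image_size
  a <- params$nucleus_radii[1L]; b <- params$nucleus_radii[2L]
  cx <- (n + 1) / 2; cy <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  mask <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1

  amp <- params$ring_amplitude
  marker <- matrix(0, n, n)
  if (mode == "uniform") {
    marker[mask] <- amp
  } else {
    depth <- mask_depth(mask)
    if (mode == "peripheral") {
      ring <- mask & depth$r > (1 - params$ring_fraction)
      marker[ring] <- amp
    } else {
      interior <- which(mask & depth$r < 0.6, arr.ind = TRUE)
      idx <- interior[sample(nrow(interior), min(params$n_foci, nrow(interior))), ,
                      drop = FALSE]
      sig <- 3
      for (i in seq_len(nrow(idx))) {
        r0 <- idx[i, 1L]; c0 <- idx[i, 2L]
        rr <- pmax(1L, r0 - 9L):pmin(n, r0 + 9L)
        cc <- pmax(1L, c0 - 9L):pmin(n, c0 + 9L)
        g <- outer(rr - r0, cc - c0, function(dr, dc)
          amp * exp(-(dr^2 + dc^2) / (2 * sig^2)))
        marker[rr, cc] <- marker[rr, cc] + g
      }
      marker[!mask] <- 0
    }
  }
  if (params$image_noise_sd > 0)
    marker <- pmax(marker + matrix(rnorm(n * n, 0, params$image_noise_sd), n, n), 0)
  nucleus_image(channels = list(marker = marker), mask = mask,
                pixel_size = params$pixel_size)
}
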