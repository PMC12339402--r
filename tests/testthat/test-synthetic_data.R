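small_params <- function(...) {
  sim_params(n_chromosomes = 1L, chrom_length = 5e6, n_genes = 200L, ...)
}

test_that("generators are bit-for-bit deterministic given (params, seed)", {
  p <- small_params()
  a <- simulate_genome(p, seed = 9)
  b <- simulate_genome(p, seed = 9)
  expect_identical(a$domains$H3K9me2$intervals, b$domains$H3K9me2$intervals)
  expect_identical(a$genes, b$genes)
  ca <- simulate_cutrun(a, p, seed = 9)
  cb <- simulate_cutrun(b, p, seed = 9)
  expect_identical(ca$replicates[[1]]$fragments, cb$replicates[[1]]$fragments)
  expect_identical(simulate_te_table(p, seed = 9), simulate_te_table(p, seed = 9))
  expect_identical(simulate_nucleus(p, "peripheral", seed = 9),
                   simulate_nucleus(p, "peripheral", seed = 9))
  expect_false(identical(a$domains$H3K9me2$intervals,
                         simulate_genome(p, seed = 10)$domains$H3K9me2$intervals))
})

test_that("domain lengths follow the geometric run-length mean", {
  # stay 0.995 at 10 kb bins -> mean domain length 1/(1-p) bins = 2 Mb
  p <- sim_params(n_chromosomes = 50L, chrom_length = 20e6)
  truth <- simulate_genome(p, seed = 21)
  d <- truth$domains$LB1$intervals
  # drop censored runs touching chromosome ends
  interior <- d[d$start > 0 & d$end < p$chrom_length, ]
  expect_gt(nrow(interior), 100)
  expect_equal(mean(interior$end - interior$start),
               p$bin_size / (1 - p$stay_domain), tolerance = 0.1)
})

test_that("degenerate stay probabilities give an all-background genome", {
  p <- small_params(stay_background = 1.0)
  truth <- simulate_genome(p, seed = 4)
  expect_equal(nrow(truth$domains$LB1$intervals), 0L)
  expect_equal(nrow(truth$domains$H3K9me2$intervals), 0L)
  expect_true(all(truth$genes$class == "nonLAD"))
  expect_error(sim_params(chrom_length = 5e6, bin_size = 6e6))
})

test_that("contact-loss factor scales domain signal down to background", {
  p <- sim_params(n_chromosomes = 1L, chrom_length = 20e6, n_replicates = 1L)
  truth <- simulate_genome(p, seed = 31)
  in_domain <- function(trk, dom) {
    s <- rep(FALSE, length(trk$values$chr1))
    for (i in seq_len(nrow(dom))) {
      b0 <- floor(dom$start[i] / p$bin_size) + 1
      b1 <- ceiling(dom$end[i] / p$bin_size)
      s[b0:b1] <- TRUE
    }
    s
  }
  dom <- truth$domains$H3K9me2$intervals
  counts_for <- function(factor, seed) {
    cr <- simulate_cutrun(truth, p, "H3K9me2", contact_loss_factor = factor,
                          seed = seed)
    fs <- cr$replicates[[1]]
    mids <- floor((fs$fragments$start + fs$fragments$end) / 2)
    tabulate(floor(mids / p$bin_size) + 1, nbins = length(truth$genome) *
               ceiling(p$chrom_length / p$bin_size))
  }
  s <- in_domain(binned_track(truth$genome, p$bin_size), dom)

  # WT: domain-bin mean equals the configured domain mean
  cw <- counts_for(1, 41)
  expect_equal(mean(cw[s]), p$mu_domain, tolerance = 0.05)
  expect_equal(mean(cw[!s]), p$mu_background, tolerance = 0.05)

  # factor 0: domain bins statistically indistinguishable from background
  c0 <- counts_for(0, 42)
  n <- min(1000, sum(s), sum(!s))
  tt <- t.test(c0[which(s)[1:n]], c0[which(!s)[1:n]])
  expect_gt(tt$p.value, 0.01)
})

test_that("the Poisson limit of the count model has unit variance/mean", {
  p <- sim_params(n_chromosomes = 1L, chrom_length = 100e6, n_replicates = 1L,
                  stay_background = 1.0, nb_dispersion = 1e9)
  truth <- simulate_genome(p, seed = 51)
  cr <- simulate_cutrun(truth, p, "H3K9me2", seed = 51)
  fs <- cr$replicates[[1]]
  mids <- floor((fs$fragments$start + fs$fragments$end) / 2)
  counts <- tabulate(floor(mids / p$bin_size) + 1, nbins = 10000)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.1)
})

test_that("expression probabilities act per class and respect the CI check", {
  p <- sim_params(n_chromosomes = 2L, chrom_length = 25e6, n_genes = 2000L,
                  p_expressed = c(nonLAD = 0, KOD = 1, LB1_LAP2b = 0.35,
                                  LAD = 0.1, other = 0.35))
  truth <- simulate_genome(p, seed = 61)
  ex <- simulate_expression(truth, p, seed = 61)
  tpm <- setNames(ex$tpm$TPM, ex$tpm$gene_id)
  non <- truth$genes$gene_id[truth$genes$class == "nonLAD"]
  kod <- truth$genes$gene_id[truth$genes$class == "KOD"]
  expect_true(all(tpm[non] <= 5))       # probability 0: none expressed
  expect_true(all(tpm[kod] > 5))        # probability 1: all expressed
  lad <- truth$genes$gene_id[truth$genes$class == "LAD"]
  phat <- mean(tpm[lad] > 5)
  ci <- qbinom(c(0.005, 0.995), length(lad), 0.1) / length(lad)
  expect_gte(phat, ci[1])
  expect_lte(phat, ci[2])
  # derepressed subset carries the planted DE signature
  de <- ex$de[ex$de$gene_id %in% ex$derepressed, ]
  expect_true(all(de$log2FC > 1 & de$padj < 0.05))
  p_bad <- p; p_bad$p_expressed <- c(nonLAD = 0.5)
  expect_error(simulate_expression(truth, p_bad, seed = 1), "unknown gene class")
})

test_that("TE table plants a recoverable enriched subset", {
  p <- sim_params()
  te <- simulate_te_table(p, seed = 71)
  expect_equal(nrow(te$table), 1200L)
  expect_equal(length(te$enriched), 60L)
  # no enrichment configured: flags almost surely empty
  p0 <- sim_params(te_enriched_fraction = 0)
  hits <- vapply(1:5, function(s) {
    t0 <- simulate_te_table(p0, seed = s)
    sum(flag_enriched(t0$table, threshold = 6)$enriched)
  }, 0)
  expect_true(all(hits == 0))
  # identical values on purpose: MAD degenerates downstream
  t_flat <- te$table
  t_flat$H3K9me2 <- 1
  expect_error(modified_z(t_flat$H3K9me2), "MAD = 0")
})

test_that("nucleus masks and modes have the stated geometry", {
  p <- sim_params(image_size = 220L, nucleus_radii = c(80, 60))
  img <- simulate_nucleus(p, "uniform", seed = 81)
  expect_equal(sum(img$mask), pi * 80 * 60, tolerance = 0.02)
  expect_true(all(img$channels$marker[img$mask] == p$ring_amplitude))
  expect_true(all(img$channels$marker[!img$mask] == 0))

  per <- simulate_nucleus(p, "peripheral", seed = 81)
  int <- simulate_nucleus(p, "internal", seed = 81)
  # peripheral mass sits at high depth, internal mass at low depth
  d <- ladseg:::mask_depth(per$mask)
  r_per <- sum(per$channels$marker * ifelse(is.na(d$r), 0, d$r)) /
    sum(per$channels$marker)
  r_int <- sum(int$channels$marker * ifelse(is.na(d$r), 0, d$r)) /
    sum(int$channels$marker)
  expect_gt(r_per, 0.9)
  expect_lt(r_int, 0.7)
})
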