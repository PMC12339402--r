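mk_domains <- function(df, mark) domain_set(df, mark = mark)

three_mark_sets <- function(lad, kod = NULL) {
  h3 <- if (is.null(kod)) lad else rbind(lad, kod)
  list(LB1 = mk_domains(lad, "LB1"), LAP2b = mk_domains(lad, "LAP2b"),
       H3K9me2 = mk_domains(h3, "H3K9me2"))
}

test_that("gene coverage honours the inclusive 90% boundary", {
  gene <- list(chrom = "chr1", start = 0, end = 1000)
  cfg <- pipeline_config()
  d90 <- mk_domains(genomic_intervals("chr1", 0, 900), "LB1")
  d899 <- mk_domains(genomic_intervals("chr1", 0, 899), "LB1")
  expect_equal(gene_domain_coverage(gene, d90), 0.9)
  expect_true(gene_domain_coverage(gene, d90) >= cfg$gene_overlap_fraction)
  expect_equal(gene_domain_coverage(gene, d899), 0.899)
  expect_false(gene_domain_coverage(gene, d899) >= cfg$gene_overlap_fraction)
  expect_error(gene_domain_coverage(list(chrom = "chr1", start = 5, end = 5),
                                    d90), "zero-length")
})

test_that("coverage is computed against the domain union, per-base oracle", {
  set.seed(201)
  for (i in 1:500) {
    gene <- list(chrom = "chr1", start = 0, end = sample(50:400, 1))
    doms <- random_interval_set(500, n = sample(1:5, 1))
    expect_equal(gene_domain_coverage(gene, mk_domains(doms, "m")),
                 oracle_coverage(gene, doms), tolerance = 1e-12)
  }
})

truthful_genes <- function() {
  set.seed(211)
  st <- sample(0:90000, 60)
  data.frame(gene_id = paste0("g", 1:60), chrom = "chr1", start = st,
             end = st + sample(500:8000, 60), stringsAsFactors = FALSE)
}

truthful_sets <- function() {
  set.seed(212)
  three_mark_sets(random_interval_set(100000, 6), kod = NULL)
}

test_that("class assignment is an exact partition with named patterns", {
  genes <- data.frame(gene_id = paste0("g", 1:5), chrom = "chr1",
                      start = c(0, 2000, 4000, 6000, 8000),
                      end = c(1000, 3000, 5000, 7000, 9000),
                      stringsAsFactors = FALSE)
  lad <- genomic_intervals("chr1", 0, 1000)          # g1 fully covered
  kod <- genomic_intervals("chr1", 4000, 5000)       # g3 H3K9me2 only
  sets <- three_mark_sets(lad, kod)
  # g4 partially (50%) covered by all marks: residual handling
  sets$LB1 <- mk_domains(rbind(lad, genomic_intervals("chr1", 6000, 6500)), "LB1")
  tab <- assign_classes(genes, sets)
  expect_equal(tab$class, c("LAD", "nonLAD", "KOD", "nonLAD", "nonLAD"))
  expect_equal(sum(table(tab$class)), nrow(genes))
  expect_error(assign_classes(genes, sets[c("LB1", "LAP2b")]),
               "H3K9me2")

  # raising the overlap fraction can only shrink memberships
  cfg95 <- pipeline_config(gene_overlap_fraction = 0.95)
  genes2 <- truthful_genes()
  sets2 <- truthful_sets()
  t90 <- assign_classes(genes2, sets2)
  t95 <- assign_classes(genes2, sets2, config = cfg95)
  for (mk in c("LB1", "LAP2b", "H3K9me2"))
    expect_true(all(t90[[paste0("in_", mk)]] | !t95[[paste0("in_", mk)]]))
})

test_that("overlap accounting partitions the union, Mb-exact", {
  a <- mk_domains(genomic_intervals("chr1", 0, 2e6), "A")
  # identical sets: only the joint pattern has mass
  acct <- overlap_accounting(list(A = a, B = mk_domains(a$intervals, "B")))
  expect_equal(nrow(acct), 1L)
  expect_equal(acct$pattern, "A&B")
  expect_equal(acct$Mb, 2)
  # disjoint sets: only the singleton patterns
  b <- mk_domains(genomic_intervals("chr1", 3e6, 4e6), "B")
  acct2 <- overlap_accounting(list(A = a, B = b))
  expect_setequal(acct2$pattern, c("A", "B"))
  expect_equal(sum(acct2$Mb), 3)

  # random sets: pattern masses sum to the union size via independent oracle
  set.seed(221)
  for (i in 1:10) {
    sets <- list(A = mk_domains(random_interval_set(2e5, 8), "A"),
                 B = mk_domains(random_interval_set(2e5, 8), "B"),
                 C = mk_domains(random_interval_set(2e5, 8), "C"))
    acct3 <- overlap_accounting(sets)
    base <- rep(FALSE, 2e5)
    for (s in sets)
      for (j in seq_len(nrow(s$intervals)))
        base[(s$intervals$start[j] + 1):s$intervals$end[j]] <- TRUE
    expect_equal(sum(acct3$Mb) * 1e6, sum(base), tolerance = 1e-12)
  }
})

test_that("expressed proportion uses a strict TPM threshold by default", {
  tab <- data.frame(class = c("LAD", "LAD", "LAD", "nonLAD"),
                    TPM = c(0, 5, 5.01, 80))
  expect_equal(expressed_proportion(tab, "LAD"), 1 / 3)  # 5 is not expressed
  cfg_ge <- pipeline_config(tpm_ge = TRUE)
  expect_equal(expressed_proportion(tab, "LAD", cfg_ge), 2 / 3)
  expect_equal(expressed_proportion(data.frame(class = "x", TPM = 0), "x"), 0)
  expect_warning(p <- expressed_proportion(tab, "KOD"), "undefined")
  expect_true(is.na(p))
  expect_error(expressed_proportion(data.frame(class = "x"), "x"), "TPM")
})

test_that("DEG classification uses strict fold-change and alpha boundaries", {
  de <- data.frame(gene_id = paste0("g", 1:4),
                   log2FC = c(1.0, 3, -2, 0.5),
                   padj = c(0.01, 0.04, 0.001, 0.2))
  got <- classify_degs(de, fc_threshold = 2, alpha = 0.05)
  expect_equal(as.character(got$de_status),
               c("unchanged", "up", "down", "unchanged"))  # log2FC = 1 exactly
  expect_error(classify_degs(data.frame(log2FC = 1)), "padj")

  set.seed(231)
  big <- data.frame(log2FC = rnorm(1000, 0, 2), padj = runif(1000))
  got2 <- classify_degs(big)
  expect_equal(sum(got2$de_status == "up"),
               sum(big$log2FC > 1 & big$padj < 0.05))
  expect_equal(sum(got2$de_status == "down"),
               sum(big$log2FC < -1 & big$padj < 0.05))
})

test_that("two-sided exact p matches enumeration and fisher.test", {
  r <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)

  r2 <- fisher_exact_2x2(10, 0, 0, 10)
  expect_equal(r2$odds_ratio, Inf)
  expect_equal(r2$p_value, oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-12)

  set.seed(241)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    mine <- fisher_exact_2x2(a, b, c, d)$p_value
    expect_equal(mine, oracle_fisher_p(a, b, c, d), tolerance = 1e-12)
    expect_equal(mine, fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
    # transpose symmetry
    expect_equal(mine, fisher_exact_2x2(a, c, b, d)$p_value, tolerance = 1e-12)
  }
  expect_equal(fisher_exact_2x2(0, 0, 3, 4)$p_value, 1)  # zero margin
})

test_that("DEG enrichment builds the 2x2 from class and direction", {
  tab <- data.frame(class = rep(c("LAD", "nonLAD"), each = 10),
                    de_status = factor(c(rep("up", 7), rep("unchanged", 3),
                                         rep("up", 2), rep("unchanged", 8)),
                                       levels = c("up", "down", "unchanged")))
  res <- deg_class_enrichment(tab, "LAD", "up")
  expect_equal(unname(res$counts), c(7, 2, 3, 8))
  expect_equal(res$p_value, oracle_fisher_p(7, 2, 3, 8), tolerance = 1e-12)
  expect_gt(res$odds_ratio, 1)
})

test_that("transition labels partition the gene universe", {
  mes <- data.frame(gene_id = paste0("g", 1:6),
                    class = c("LAD", "KOD", "nonLAD", "LAD", "nonLAD", "KOD"))
  epi <- data.frame(gene_id = paste0("g", 1:6),
                    class = c("LAD", "KOD", "KOD", "LB1_only", "nonLAD", "LAD"))
  tr <- transition_classes(mes, epi)
  expect_equal(tr$table$transition,
               c("cLAD", "cKOD", "newKOD", "LAD_to_LB1", "nonLAD", "other"))
  expect_equal(sum(tr$counts), 6)
  expect_error(transition_classes(mes, epi[1:5, ]), "universe")
})
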