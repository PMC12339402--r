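test_that("family signal averages replicates within copies, then copies", {
  df <- data.frame(family = "L1MdA", copy = c("c1", "c1", "c2", "c2"),
                   replicate = c(1, 2, 1, 2), rpkm = c(2, 4, 10, 10))
  out <- family_signal(df)
  expect_equal(out$mean_rpkm, mean(c(mean(c(2, 4)), 10)))  # (3 + 10)/2
  expect_equal(out$n_copies, 2)

  one <- family_signal(data.frame(family = "f", copy = "c", replicate = 1,
                                  rpkm = 7.5))
  expect_equal(one$mean_rpkm, 7.5)

  # random fixture vs independent nested-mean oracle
  set.seed(301)
  big <- expand.grid(copy = paste0("c", 1:7), replicate = 1:3,
                     stringsAsFactors = FALSE)
  big$family <- rep(c("A", "B", "C", "D", "A", "B", "C"), 3)
  big$rpkm <- rexp(nrow(big), 0.1)
  got <- family_signal(big)
  for (f in unique(big$family)) {
    d <- big[big$family == f, ]
    per_copy <- tapply(d$rpkm, d$copy, mean)
    expect_equal(got$mean_rpkm[got$family == f], mean(per_copy),
                 tolerance = 1e-12)
  }

  # length weighting changes the aggregation as documented
  df$length <- c(100, 100, 300, 300)
  lw <- family_signal(df, weight_by_length = TRUE)
  expect_equal(lw$mean_rpkm, (3 * 100 + 10 * 300) / 400)
  expect_error(family_signal(df[, 1:4], weight_by_length = TRUE), "length")
})

test_that("modified z matches the hand-computed median/MAD form", {
  x <- c(1, 2, 3, 4, 100)
  z <- modified_z(x)
  # med = 3, MAD = median(|x - 3|) = 1, z(100) = 0.6745 * 97
  expect_equal(z[5], 0.6745 * 97, tolerance = 1e-12)
  expect_equal(z[3], 0)
  # brute-force re-computation on random vectors
  set.seed(311)
  for (i in 1:50) {
    v <- rlnorm(sample(5:200, 1))
    med <- sort(v)[ceiling(length(v) / 2)]
    if (length(v) %% 2 == 0) {
      sv <- sort(v)
      med <- (sv[length(v) / 2] + sv[length(v) / 2 + 1]) / 2
    }
    dev <- sort(abs(v - med))
    mad_raw <- if (length(v) %% 2 == 1) dev[ceiling(length(v) / 2)]
               else (dev[length(v) / 2] + dev[length(v) / 2 + 1]) / 2
    expect_equal(modified_z(v), 0.6745 * (v - med) / mad_raw, tolerance = 1e-9)
  }
})

test_that("modified z is location- and positive-scale-invariant", {
  set.seed(321)
  x <- rexp(101)
  z <- modified_z(x)
  expect_equal(median(z), 0)
  expect_equal(modified_z(x + 13.7), z, tolerance = 1e-9)
  expect_equal(modified_z(x * 42), z, tolerance = 1e-9)
  expect_true(all(diff(z[order(x)]) >= 0))  # monotone in x
  expect_error(modified_z(rep(2, 10)), "MAD = 0")
  expect_error(modified_z(3), "at least 2")
})

test_that("enrichment flag uses strict > with and/or across marks", {
  tab <- data.frame(family = c("a", "b", "c"),
                    H3K9me2 = c(10, 10, 10), LAP2b = c(5, 5, 5))
  # engineer exact z values via direct construction
  z_exact <- function(target_z, n = 101) {
    # values with median 0, MAD 1, one value at target_z / 0.6745
    c(rep(c(-1, 0, 1), length.out = n - 1), target_z / 0.6745)
  }
  x <- z_exact(2)
  expect_equal(max(modified_z(x)), 2, tolerance = 1e-12)
  t2 <- data.frame(family = paste0("f", seq_along(x)), H3K9me2 = x,
                   LAP2b = rep(c(0, 1, -1), length.out = length(x)))
  fl <- flag_enriched(t2, threshold = 2)
  expect_false(fl$enriched[length(x)])        # z = 2 exactly: not enriched
  t3 <- t2
  t3$H3K9me2[length(x)] <- 5 / 0.6745
  fl3 <- flag_enriched(t3, threshold = 2)
  expect_true(fl3$enriched[length(x)])        # one mark suffices (and/or)

  # monotone in threshold: higher cut flags a subset
  set.seed(331)
  t4 <- data.frame(family = paste0("f", 1:300), H3K9me2 = rlnorm(300),
                   LAP2b = rlnorm(300))
  lo <- flag_enriched(t4, threshold = 1)$enriched
  hi <- flag_enriched(t4, threshold = 2.5)$enriched
  expect_true(all(lo | !hi))
  expect_error(flag_enriched(t4, marks = c("H3K9me2", "nope")), "nope")
})

test_that("planted enriched families are recovered with high accuracy", {
  p <- sim_params()
  sens <- spec <- numeric(3)
  for (i in 1:3) {
    te <- simulate_te_table(p, seed = 400 + i)
    fl <- flag_enriched(te$table, threshold = pipeline_config()$te_z_threshold)
    truth <- fl$family %in% te$enriched
    sens[i] <- mean(fl$enriched[truth])
    spec[i] <- mean(!fl$enriched[!truth])
  }
  expect_true(all(sens >= 0.95))
  expect_true(all(spec >= 0.95))
})

test_that("bin-track aggregation route matches a direct bin-mean oracle", {
  g <- genome_def(c(chr1 = 50000))
  trk <- binned_track(g, 10000, list(chr1 = c(2, 4, NA, 8, 10)))
  te <- data.frame(chrom = "chr1", start = c(0, 15000, 21000, 40000),
                   end = c(9000, 18000, 29000, 49000),
                   family = c("A", "A", "B", "B"), stringsAsFactors = FALSE)
  out <- family_signal_from_track(trk, te)
  # A: copy1 bin1 (2), copy2 bin2 (4) -> 3. B: copy1 sits entirely in the
  # invalid bin 3, so only copy2 (bin 5, 10) is measured -> 10, one copy
  expect_equal(out$mean_rpkm[out$family == "A"], 3)
  expect_equal(out$n_copies[out$family == "A"], 2L)
  expect_equal(out$mean_rpkm[out$family == "B"], 10)
  expect_equal(out$n_copies[out$family == "B"], 1L)
  # copy spanning an invalid and a valid bin averages the valid one only
  te2 <- data.frame(chrom = "chr1", start = 25000, end = 35000, family = "D")
  expect_equal(family_signal_from_track(trk, te2)$mean_rpkm, 8)
  # family with no measured copies is NA with a warning
  te3 <- rbind(te, data.frame(chrom = "chr1", start = 21000, end = 29000,
                              family = "C"))
  expect_warning(out3 <- family_signal_from_track(trk, te3), "C")
  expect_true(is.na(out3$mean_rpkm[out3$family == "C"]))
})
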