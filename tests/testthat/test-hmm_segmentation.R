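test_that("forward log-likelihood matches closed forms", {
  # K = 1: lnL is the sum of Normal log-densities
  m1 <- hmm_model(means = 2, sds = 1.5, transition = matrix(1, 1, 1),
                  initial = 1)
  x <- c(1.2, -0.4, 3.3, 2.2)
  expect_equal(log_likelihood(m1, x), sum(dnorm(x, 2, 1.5, log = TRUE)),
               tolerance = 1e-10)
  # single observation, K = 2: log of the mixture density
  m2 <- hmm_model(means = c(0, 3), sds = c(1, 2),
                  transition = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                  initial = c(0.6, 0.4))
  expect_equal(log_likelihood(m2, 1.7),
               log(0.6 * dnorm(1.7, 0, 1) + 0.4 * dnorm(1.7, 3, 2)),
               tolerance = 1e-10)
})

test_that("forward and Viterbi agree with exhaustive path enumeration", {
  set.seed(101)
  for (i in 1:100) {
    K <- sample(2:3, 1)
    TT <- sample(2:8, 1)
    means <- sort(rnorm(K, 0, 3))
    sds <- runif(K, 0.5, 2)
    A <- matrix(rexp(K * K), K); A <- A / rowSums(A)
    pi0 <- rexp(K); pi0 <- pi0 / sum(pi0)
    m <- hmm_model(means, sds, A, pi0)
    x <- rnorm(TT, sample(means, TT, replace = TRUE), 1)
    expect_equal(log_likelihood(m, x), oracle_loglik(x, means, sds, A, pi0),
                 tolerance = 1e-8)
  }
  # Viterbi against brute force over all 2^T paths, T up to 12
  set.seed(102)
  for (i in 1:100) {
    TT <- sample(3:12, 1)
    means <- sort(rnorm(2, 0, 2)); sds <- runif(2, 0.5, 2)
    A <- matrix(rexp(4), 2); A <- A / rowSums(A)
    pi0 <- rexp(2); pi0 <- pi0 / sum(pi0)
    x <- rnorm(TT, sample(means, TT, replace = TRUE), 1)
    got <- ladseg:::hmm_viterbi(x, means, sds, A, pi0)
    expect_equal(as.integer(got), oracle_viterbi(x, means, sds, A, pi0))
  }
})

test_that("Baum-Welch converges to sample moments for K = 1", {
  set.seed(111)
  x <- rnorm(5000, 4, 2)
  f <- fit_hmm(list(x), K = 1, seed = 1)
  n <- length(x)
  expect_equal(f$means, mean(x), tolerance = 1e-6)
  expect_equal(f$sds, sd(x) * sqrt((n - 1) / n), tolerance = 1e-6)
})

test_that("Baum-Welch recovers well-separated two-state parameters", {
  sim <- two_state_sequence(5000, stay = 0.99, mu = c(0, 6), sd = c(1, 1),
                            seed = 121)
  f <- fit_hmm(list(sim$x), K = 2, seed = 1)
  expect_equal(f$means[1], 0, tolerance = 0.3)          # absolute, mu0 = 0
  expect_lt(abs(f$means[2] - 6) / 6, 0.05)              # within 5%
  expect_lt(abs(f$transition[1, 1] - 0.99), 0.01)
  expect_lt(abs(f$transition[2, 2] - 0.99), 0.01)
  expect_true(all(diff(f$means) > 0))                   # ascending relabel
})

test_that("information criteria follow their closed forms", {
  ic <- information_criteria(loglik = 0, p = 5, n = 100)
  expect_equal(ic[["AIC"]], 10)
  expect_equal(ic[["BIC"]], 5 * log(100), tolerance = 1e-12)
  expect_equal(hmm_n_params(2), 7)
  expect_equal(hmm_n_params(5), 34)
})

test_that("BIC prefers the true two-state model on separated data", {
  sim <- two_state_sequence(4000, stay = 0.99, mu = c(0, 3), seed = 131)
  sel <- select_model(list(sim$x), Ks = 2:4, seed = 1)
  expect_equal(sel$selected[["BIC"]], 2)
  expect_equal(sel$table$p, c(7, 14, 23))
  expect_equal(sel$table$AIC, 2 * sel$table$p - 2 * sel$table$loglik)
  expect_equal(sel$table$BIC,
               sel$table$p * log(sel$table$n) - 2 * sel$table$loglik)
})

test_that("decoding maps high-state runs to bin-aligned clipped intervals", {
  g <- genome_def(c(chr1 = 45000, chr2 = 25000))
  m <- hmm_model(means = c(0, 10), sds = c(1, 1),
                 transition = matrix(c(0.99, 0.01, 0.01, 0.99), 2),
                 initial = c(0.5, 0.5))
  # all bins far above the high mean: one domain spanning each chromosome
  hi <- binned_track(g, 10000, list(chr1 = rep(50, 5), chr2 = rep(50, 3)))
  d <- decode(m, hi)
  expect_equal(d$intervals$chrom, c("chr1", "chr2"))
  expect_equal(d$intervals$start, c(0, 0))
  expect_equal(d$intervals$end, c(45000, 25000))  # clipped to length

  # invalid bins break intervals
  gap <- binned_track(g, 10000, list(chr1 = c(50, 50, NA, 50, 50),
                                     chr2 = rep(0, 3)))
  d2 <- decode(m, gap)
  expect_equal(d2$intervals$start, c(0, 30000))
  expect_equal(d2$intervals$end, c(20000, 45000))

  # all bins invalid: empty domain set
  none <- binned_track(g, 10000)
  expect_equal(nrow(decode(m, none)$intervals), 0L)
})

test_that("decoding recovers planted domains and ignores chromosome order", {
  p <- sim_params(n_chromosomes = 2L, chrom_length = 20e6)
  truth <- simulate_genome(p, seed = 141)
  cr <- simulate_cutrun(truth, p, "H3K9me2", seed = 141)
  fs <- cr$replicates[[1]]
  trk <- bin_rpkm(fs, truth$genome, p$bin_size)
  f <- fit_hmm(track_sequences(trk), K = 2, seed = 1)
  d <- decode(f, trk, mark = "H3K9me2")
  expect_gte(jaccard_domains(d, truth$domains$H3K9me2), 0.95)

  # reversing chromosome order leaves per-chromosome decoding unchanged
  rev_trk <- trk
  rev_trk$genome <- ladseg:::genome_def(rev(unclass(trk$genome)))
  rev_trk$values <- rev(trk$values)
  rev_trk$mask <- rev(trk$mask)
  d_rev <- decode(f, rev_trk, mark = "H3K9me2")
  o <- order(d_rev$intervals$chrom, d_rev$intervals$start)
  expect_equal(d_rev$intervals[o, ], d$intervals,
               ignore_attr = TRUE)
})

test_that("consensus equals the per-base AND oracle and its set algebra", {
  a <- domain_set(genomic_intervals("chr1", 0, 100), mark = "m")
  b <- domain_set(genomic_intervals("chr1", 0, 50), mark = "m")
  expect_equal(consensus_domains(list(a, a))$intervals$end, 100)
  expect_equal(consensus_domains(list(a, b))$intervals$end, 50)

  set.seed(151)
  for (i in 1:20) {
    reps <- lapply(1:3, function(j)
      domain_set(random_interval_set(5000, n = sample(3:8, 1)), mark = "m"))
    cons <- consensus_domains(reps)
    oracle <- oracle_consensus(lapply(reps, `[[`, "intervals"), 5000)
    expect_equal(cons$intervals[, c("chrom", "start", "end")], oracle,
                 ignore_attr = TRUE)
    # commutative + associative; consensus is a subset of every replicate
    perm <- consensus_domains(reps[c(3, 1, 2)])
    expect_equal(perm$intervals, cons$intervals)
    nested <- consensus_domains(list(consensus_domains(reps[1:2]), reps[[3]]))
    expect_equal(nested$intervals[, c("chrom", "start", "end")],
                 cons$intervals[, c("chrom", "start", "end")])
    if (nrow(cons$intervals) > 0)  # empty consensus is trivially a subset
      for (r in reps)
        expect_equal(jaccard_domains(cons,
          domain_set(oracle_consensus(list(r$intervals, cons$intervals), 5000),
                     mark = "m")), 1)
  }
  expect_error(consensus_domains(list(a, domain_set(a$intervals, mark = "x"))),
               "marks")
})

test_that("model JSON serialization round trips", {
  sim <- two_state_sequence(500, seed = 161)
  f <- fit_hmm(list(sim$x), K = 2, seed = 1)
  path <- withr::local_tempfile()
  write_hmm_model(f, path)
  back <- read_hmm_model(path)
  expect_equal(back$means, f$means)
  expect_equal(back$transition, f$transition)
  expect_equal(log_likelihood(back, sim$x), log_likelihood(f, sim$x))
})

test_that("minimum-length post-filter drops only short intervals", {
  d <- domain_set(genomic_intervals("chr1", c(0, 50000, 200000),
                                    c(10000, 120000, 210000)), mark = "m")
  f <- filter_min_length(d, 20000)
  expect_equal(f$intervals$start, 50000)
  expect_equal(nrow(filter_min_length(d, 0)$intervals), 3L)
})
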