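# Independent brute-force oracles and small fixture builders shared across
# the suite. Every oracle is written without reference to the implementation
# path it checks.

options(ladseg.quiet = TRUE)

# exhaustive forward likelihood: sum over all K^T hidden paths
oracle_loglik <- function(x, means, sds, A, pi) {
  TT <- length(x); K <- length(means)
  paths <- expand.grid(rep(list(seq_len(K)), TT))
  tot <- 0
  for (i in seq_len(nrow(paths))) {
    st <- as.integer(paths[i, ])
    p <- pi[st[1L]] * dnorm(x[1L], means[st[1L]], sds[st[1L]])
    for (t in seq_len(TT - 1L))
      p <- p * A[st[t], st[t + 1L]] * dnorm(x[t + 1L], means[st[t + 1L]],
                                            sds[st[t + 1L]])
    tot <- tot + p
  }
  log(tot)
}

# exhaustive Viterbi: argmax over all K^T paths, ties toward the
# lexicographically smallest (lower state index earlier) path
oracle_viterbi <- function(x, means, sds, A, pi) {
  TT <- length(x); K <- length(means)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), TT)))
  # expand.grid varies the first column fastest; reorder rows so paths come
  # in lexicographic order of the full state sequence
  ord <- do.call(order, as.data.frame(paths))
  paths <- paths[ord, , drop = FALSE]
  best <- -Inf; best_path <- NULL
  for (i in seq_len(nrow(paths))) {
    st <- as.integer(paths[i, ])
    lp <- log(pi[st[1L]]) + dnorm(x[1L], means[st[1L]], sds[st[1L]], log = TRUE)
    for (t in seq_len(TT - 1L))
      lp <- lp + log(A[st[t], st[t + 1L]]) +
        dnorm(x[t + 1L], means[st[t + 1L]], sds[st[t + 1L]], log = TRUE)
    if (lp > best) { best <- lp; best_path <- st }
  }
  best_path
}

# per-base boolean AND consensus over replicate interval sets, by run-length
# encoding of a base vector
oracle_consensus <- function(interval_dfs, chrom_len, chrom = "chr1") {
  base <- rep(TRUE, chrom_len)
  for (df in interval_dfs) {
    hit <- rep(FALSE, chrom_len)
    d <- df[df$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(d)))
      hit[(d$start[i] + 1):d$end[i]] <- TRUE
    base <- base & hit
  }
  r <- rle(base)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  data.frame(chrom = chrom, start = starts[keep] - 1, end = ends[keep])
}

# per-base gene/domain coverage fraction
oracle_coverage <- function(gene, domains_df) {
  hit <- rep(FALSE, gene$end - gene$start)
  d <- domains_df[domains_df$chrom == gene$chrom, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    lo <- max(d$start[i], gene$start); hi <- min(d$end[i], gene$end)
    if (hi > lo) hit[(lo - gene$start + 1):(hi - gene$start)] <- TRUE
  }
  mean(hit)
}

# two-sided exact 2x2 p-value by full enumeration with choose()
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n2 <- b + d; k <- a + b; N <- m + n2
  support <- max(0, k - n2):min(k, m)
  prob <- choose(m, support) * choose(n2, k - support) / choose(N, k)
  p_obs <- choose(m, a) * choose(n2, k - a) / choose(N, k)
  sum(prob[prob <= p_obs * (1 + 1e-12)])
}

# base-pair Jaccard between two domain sets
jaccard_domains <- function(a, b) {
  ga <- ladseg:::intervals_to_granges(if (inherits(a, "domain_set")) a$intervals else a)
  gb <- ladseg:::intervals_to_granges(if (inherits(b, "domain_set")) b$intervals else b)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  if (uni == 0) return(NA_real_)
  inter / uni
}

# random non-overlapping sorted interval set on one chromosome
random_interval_set <- function(chrom_len, n = 10, chrom = "chr1") {
  cuts <- sort(sample(seq_len(chrom_len - 1), 2 * n))
  data.frame(chrom = chrom, start = cuts[seq(1, 2 * n, 2)] - 1,
             end = cuts[seq(2, 2 * n, 2)], label = "domain",
             stringsAsFactors = FALSE)
}

# synthetic two-state Gaussian sequence with known states
two_state_sequence <- function(T, stay = 0.99, mu = c(0, 3), sd = c(1, 1),
                               seed = 1) {
  set.seed(seed)
  s <- integer(T); s[1] <- rbinom(1, 1, 0.5) + 1L
  u <- runif(T)
  for (i in seq_len(T - 1))
    s[i + 1] <- if (u[i] < stay) s[i] else 3L - s[i]
  list(x = rnorm(T, mu[s], sd[s]), states = s)
}

# disk-shaped nucleus image with a constant channel value
disk_image <- function(radius = 60, value = 1, size = 2 * radius + 21,
                       pixel_size = 0.1) {
  cx <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), times = size), size, size)
  mask <- (xs - cx)^2 + (ys - cx)^2 <= radius^2
  ch <- matrix(0, size, size); ch[mask] <- value
  nucleus_image(channels = list(marker = ch), mask = mask,
                pixel_size = pixel_size)
}
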