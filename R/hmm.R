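#' Gaussian-emission hidden Markov models over binned signal
#'
#' The genome segmentation model: each valid-bin run of a track is an
#' independent observation sequence; hidden states carry Normal emissions and
#' a first-order transition structure. States are kept sorted by ascending
#' mean, so the last state is always the "high signal" state whose Viterbi
#' runs define domains.
#'
#' @param means,sds per-state emission means and standard deviations (signal
#'   units); states are relabeled ascending by mean on construction.
#' @param transition K x K row-stochastic transition matrix.
#' @param initial initial state distribution (length K, sums to 1).
#' @param loglik trained log-likelihood (NA for hand-built models).
#' @param meta list of training metadata (iterations, tol, seed, restarts).
#' @return object of class `hmm_model`.
#' @export
hmm_model <- function(means, sds, transition, initial, loglik = NA_real_,
                      meta = list()) {
  K <- length(means)
  stopifnot(length(sds) == K, length(initial) == K,
            nrow(transition) == K, ncol(transition) == K)
  if (any(sds <= 0)) stop("state standard deviations must be > 0", call. = FALSE)
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition matrix rows must sum to 1", call. = FALSE)
  if (abs(sum(initial) - 1) > 1e-9)
    stop("initial distribution must sum to 1", call. = FALSE)
  o <- order(means)
  structure(list(K = K, means = means[o], sds = sds[o],
                 transition = transition[o, o, drop = FALSE],
                 initial = initial[o], loglik = loglik, meta = meta),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("<hmm_model> K =", x$K, " means:", signif(x$means, 4),
      " lnL:", signif(x$loglik, 8), "\n")
  invisible(x)
}

#' Extract observation sequences from a track
#'
#' Splits each chromosome into maximal runs of valid bins; invalid
#' (blacklisted/missing) bins break runs, so no transition is modeled across
#' a gap. An optional log2(x + 1) transform is applied per value.
#'
#' @param trk a [binned_track()].
#' @param log_transform apply log2(x + 1) to the signal.
#' @return list of numeric vectors; attribute `runs` records (chrom, start
#'   bin, length) per sequence for mapping decodings back to coordinates.
#' @export
track_sequences <- function(trk, log_transform = FALSE) {
  seqs <- list(); runs <- list()
  for (ch in names(trk$genome)) {
    m <- trk$mask[[ch]]
    if (!any(m)) next
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      v <- trk$values[[ch]][starts[i]:ends[i]]
      if (log_transform) v <- log2(v + 1)
      seqs[[length(seqs) + 1L]] <- v
      runs[[length(runs) + 1L]] <- list(chrom = ch, from = starts[i],
                                        len = r$lengths[i])
    }
  }
  attr(seqs, "runs") <- runs
  seqs
}

#' Forward log-likelihood of sequences under a model
#'
#' Sum of per-sequence forward-algorithm log-likelihoods, computed with a
#' scaled recursion for numerical stability.
#'
#' @param model an [hmm_model()].
#' @param sequences list of numeric vectors (or a single vector).
#' @return total log-likelihood.
#' @export
log_likelihood <- function(model, sequences) {
  if (is.numeric(sequences)) sequences <- list(sequences)
  if (!length(sequences)) stop("no observation sequences", call. = FALSE)
  sum(vapply(sequences, function(x)
    hmm_forward_loglik(x, model$means, model$sds, model$transition,
                       model$initial), 0.0))
}

# deterministic K-state initialization: means at quantile spread (25th/75th
# percentile for K = 2), sd at sample sd, diagonal-0.95 transitions, uniform
# initial distribution; restarts jitter the means.
init_hmm <- function(x_all, K, jitter_sd = 0) {
  probs <- if (K == 1L) 0.5 else seq(0.25, 0.75, length.out = K)
  mu <- as.numeric(quantile(x_all, probs, names = FALSE, type = 7))
  if (jitter_sd > 0) mu <- mu + rnorm(K, 0, jitter_sd)
  mu <- sort(mu)
  s <- sd(x_all)
  if (!is.finite(s) || s == 0) s <- max(abs(x_all), 1e-6)
  A <- matrix(if (K > 1L) 0.05 / (K - 1) else 0, K, K)
  diag(A) <- if (K > 1L) 0.95 else 1
  list(means = mu, sds = rep(s, K), transition = A, initial = rep(1 / K, K))
}

#' Fit an HMM by Baum-Welch
#'
#' Expectation-maximization over all sequences jointly, iterated until the
#' log-likelihood improves by less than `tol` or `max_iter` is reached. The
#' log-likelihood is asserted non-decreasing at every iteration. Degenerate
#' fits (a state's posterior weight collapsing to ~0, or two states merging)
#' trigger a jittered restart, up to `n_restarts` times. The standard
#' deviations are floored at `sigma_floor_frac` times the pooled sample sd.
#'
#' @param sequences list of numeric vectors (valid-bin runs).
#' @param K number of states.
#' @param seed RNG seed governing restart jitter (deterministic fits).
#' @param tol convergence tolerance on the log-likelihood increment.
#' @param max_iter maximum EM iterations.
#' @param n_restarts maximum jittered restarts on degeneracy.
#' @param sigma_floor_frac sd floor as a fraction of the pooled sample sd.
#' @return an [hmm_model()] with states sorted by ascending mean.
#' @export
fit_hmm <- function(sequences, K, seed = 1L, tol = 1e-4, max_iter = 500L,
                    n_restarts = 5L, sigma_floor_frac = 1e-3) {
  if (is.numeric(sequences)) sequences <- list(sequences)
  if (!length(sequences)) stop("no observation sequences", call. = FALSE)
  x_all <- unlist(sequences, use.names = FALSE)
  if (length(unique(x_all)) < K)
    stop("fewer than K distinct observed values", call. = FALSE)
  sigma_floor <- sigma_floor_frac * max(sd(x_all), .Machine$double.eps)
  set.seed(as.integer(seed))
  jitter_scale <- sd(x_all) / 4

  for (attempt in seq_len(n_restarts + 1L)) {
    par <- init_hmm(x_all, K, jitter_sd = if (attempt == 1L) 0 else jitter_scale)
    fit <- tryCatch(
      baum_welch(sequences, par, K, tol, max_iter, sigma_floor),
      ladseg_degenerate = function(e) NULL)
    if (!is.null(fit)) {
      fit$meta <- list(iterations = fit$meta$iterations, tol = tol, seed = seed,
                       attempt = attempt, K = K)
      return(fit)
    }
  }
  stop("HMM fit degenerate after ", n_restarts, " restarts (K = ", K, ")",
       call. = FALSE)
}

baum_welch <- function(sequences, par, K, tol, max_iter, sigma_floor) {
  loglik_prev <- -Inf
  iters <- 0L
  for (iter in seq_len(max_iter)) {
    iters <- iter
    e <- hmm_estep_stats(sequences, par$means, par$sds, par$transition,
                         par$initial)
    loglik <- e$loglik
    gamma_sum <- e$gamma_sum
    gx <- e$gx
    gxx <- e$gxx
    xi_sum <- e$xi_sum
    gamma1 <- e$gamma1
    # EM guarantee: the data log-likelihood never decreases
    if (loglik < loglik_prev - 1e-6 * max(1, abs(loglik_prev)))
      stop("Baum-Welch log-likelihood decreased (", loglik_prev, " -> ",
           loglik, ")", call. = FALSE)
    converged <- is.finite(loglik_prev) && abs(loglik - loglik_prev) < tol
    loglik_prev <- loglik
    if (converged) break

    if (any(gamma_sum < 1e-8 * sum(gamma_sum)))
      stop(structure(class = c("ladseg_degenerate", "error", "condition"),
                     list(message = "state weight collapsed", call = NULL)))
    mu <- gx / gamma_sum
    var <- pmax(gxx / gamma_sum - mu^2, 0)
    par$means <- mu
    par$sds <- pmax(sqrt(var), sigma_floor)
    if (K > 1L) {
      rs <- rowSums(xi_sum)
      A <- xi_sum / ifelse(rs > 0, rs, 1)
      A[rs == 0, ] <- 1 / K
      par$transition <- A
    }
    par$initial <- gamma1 / sum(gamma1)
  }
  hmm_model(par$means, par$sds, par$transition, par$initial,
            loglik = loglik_prev, meta = list(iterations = iters))
}

#' Model selection by AIC and BIC
#'
#' Fits an HMM for each candidate state count and scores it with
#' AIC = 2p - 2 lnL and BIC = p ln(n) - 2 lnL, where the free-parameter count
#' is p = K^2 + 2K - 1 (K(K-1) transitions, K-1 initial probabilities, 2K
#' emission parameters) and n is the total number of observed bins.
#'
#' @param sequences list of numeric vectors.
#' @param Ks candidate state counts (default 2:5).
#' @param seed RNG seed forwarded to each fit.
#' @param ... forwarded to [fit_hmm()].
#' @return list of class `model_selection` with a per-K data.frame
#'   (`table`: K, loglik, p, n, AIC, BIC, error), the fitted models, and the
#'   selected K per criterion.
#' @export
select_model <- function(sequences, Ks = 2:5, seed = 1L, ...) {
  stopifnot(length(Ks) >= 1L)
  n <- sum(lengths(sequences))
  rows <- list(); models <- list()
  for (K in Ks) {
    fit <- tryCatch(fit_hmm(sequences, K, seed = seed, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[as.character(K)]] <- data.frame(K = K, loglik = NA_real_,
                                            p = hmm_n_params(K), n = n,
                                            AIC = NA_real_, BIC = NA_real_,
                                            error = conditionMessage(fit))
    } else {
      ic <- information_criteria(fit$loglik, hmm_n_params(K), n)
      rows[[as.character(K)]] <- data.frame(K = K, loglik = fit$loglik,
                                            p = hmm_n_params(K), n = n,
                                            AIC = ic[["AIC"]], BIC = ic[["BIC"]],
                                            error = NA_character_)
      models[[as.character(K)]] <- fit
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  sel_aic <- tab$K[which.min(tab$AIC)]
  sel_bic <- tab$K[which.min(tab$BIC)]
  structure(list(table = tab, models = models,
                 selected = c(AIC = sel_aic, BIC = sel_bic)),
            class = "model_selection")
}

#' HMM free-parameter count
#' @param K number of states.
#' @return K^2 + 2K - 1.
#' @export
hmm_n_params <- function(K) K^2 + 2 * K - 1

#' AIC and BIC from a log-likelihood
#' @param loglik model log-likelihood.
#' @param p free-parameter count.
#' @param n number of observations.
#' @return named vector c(AIC, BIC).
#' @export
information_criteria <- function(loglik, p, n) {
  c(AIC = 2 * p - 2 * loglik, BIC = p * log(n) - 2 * loglik)
}

#' Viterbi-decode a track into domains
#'
#' Runs the Viterbi algorithm over each valid-bin run and merges maximal runs
#' of high-signal states into bin-aligned intervals (interval ends clip to
#' the chromosome length). For a two-state model the single non-background
#' state defines domains; for K > 2, every state except the lowest-mean
#' background state is reported, labeled by its state index. Invalid bins
#' break intervals. Path-score ties resolve toward the lower state index.
#'
#' @param model a fitted [hmm_model()].
#' @param trk a [binned_track()] on the same signal scale as the training
#'   data.
#' @param log_transform must match the transform used at training time.
#' @param mark,sample labels for the returned [domain_set()].
#' @return a [domain_set()] (empty if every bin is invalid).
#' @export
decode <- function(model, trk, log_transform = FALSE, mark = "", sample = "") {
  seqs <- track_sequences(trk, log_transform = log_transform)
  runs <- attr(seqs, "runs")
  out <- list()
  for (i in seq_along(seqs)) {
    path <- hmm_viterbi(seqs[[i]], model$means, model$sds, model$transition,
                        model$initial)
    if (!any(path > 1L)) next  # state 1 = lowest mean = background
    r <- rle(if (model$K == 2L) path > 1L else as.integer(path))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ch <- runs[[i]]$chrom; from <- runs[[i]]$from
    for (j in which(if (model$K == 2L) r$values else r$values > 1L)) {
      b0 <- from + starts[j] - 1L  # 1-based bin index
      b1 <- from + ends[j] - 1L
      lab <- if (model$K == 2L) "domain" else paste0("state", r$values[j])
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = (b0 - 1) * trk$bin_size,
        end = min(b1 * trk$bin_size, trk$genome[[ch]]),
        label = lab, stringsAsFactors = FALSE)
    }
  }
  ints <- if (length(out)) do.call(rbind, out)
          else genomic_intervals(character(), numeric(), numeric())
  domain_set(ints, mark = mark, sample = sample)
}

#' Replicate-consensus domains
#'
#' Base-pair intersection across all replicate domain sets, keeping only
#' regions shared by every replicate, with bookended or overlapping pieces
#' merged (merge distance 0).
#'
#' @param replicate_domains list of [domain_set()]s for one mark.
#' @return a [domain_set()] labeled "consensus".
#' @export
consensus_domains <- function(replicate_domains) {
  stopifnot(length(replicate_domains) >= 1L)
  marks <- unique(vapply(replicate_domains, function(d) d$mark, ""))
  if (length(marks) > 1L)
    stop("consensus across different marks: ", paste(marks, collapse = ", "),
         call. = FALSE)
  grs <- lapply(replicate_domains, function(d) intervals_to_granges(d$intervals))
  acc <- grs[[1L]]
  for (g in grs[-1L]) acc <- GenomicRanges::intersect(acc, g)
  acc <- GenomicRanges::reduce(GenomicRanges::sort(acc), min.gapwidth = 1L)
  ints <- if (length(acc)) granges_to_intervals(acc, label = "domain")
          else genomic_intervals(character(), numeric(), numeric())
  domain_set(ints, mark = marks, sample = "consensus")
}

#' Drop domains shorter than a minimum length
#'
#' Optional post-filter on decoded or consensus calls; no filter is applied
#' by default anywhere in the pipeline.
#'
#' @param domains a [domain_set()].
#' @param min_bp minimum interval length in bp (intervals strictly shorter
#'   are dropped).
#' @return the filtered [domain_set()].
#' @export
filter_min_length <- function(domains, min_bp) {
  stopifnot(inherits(domains, "domain_set"), min_bp >= 0)
  keep <- (domains$intervals$end - domains$intervals$start) >= min_bp
  domains$intervals <- domains$intervals[keep, , drop = FALSE]
  rownames(domains$intervals) <- NULL
  domains
}

#' Serialize / restore an HMM model as JSON
#' @param model an [hmm_model()].
#' @param path JSON file path.
#' @return `write_hmm_model` returns `path` invisibly; `read_hmm_model`
#'   returns the model.
#' @export
write_hmm_model <- function(model, path) {
  jsonlite::write_json(list(K = model$K, means = model$means, sds = model$sds,
                            transition = model$transition,
                            initial = model$initial, loglik = model$loglik,
                            meta = model$meta),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_hmm_model
#' @export
read_hmm_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- if (is.matrix(x$transition)) x$transition
       else matrix(unlist(x$transition), x$K, x$K, byrow = TRUE)
  hmm_model(x$means, x$sds, A, x$initial, loglik = x$loglik,
            meta = as.list(x$meta))
}
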