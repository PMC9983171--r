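#' Fixed-width genome bins
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param bin_width Bin width (bp, default 200).
#' @return Tibble of bins tiling each chromosome (last partial bin kept).
#' @export
make_bins <- function(chrom_lengths, bin_width = 200L) {
  bind_rows(lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = bin_width)
    tibble(chrom = ch, start = starts, end = pmin(starts + bin_width, len))
  }))
}

## average signal height per bin (sum of value*overlap / bin width)
bin_signal <- function(track, bins) {
  out <- numeric(nrow(bins))
  if (nrow(track) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(as_granges(track), as_granges(bins))
  if (length(hits) > 0L) {
    ti <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
    ov <- pmin(track$end[ti], bins$end[bi]) - pmax(track$start[ti], bins$start[bi])
    agg <- tapply(track$value[ti] * ov, bi, sum)
    out[as.integer(names(agg))] <- agg / (bins$end - bins$start)[as.integer(names(agg))]
  }
  out
}

#' Poisson-tail binarization of per-bin counts
#'
#' A bin is called present (1) when its count is improbably high under a
#' background Poisson rate: `P(X >= count | lambda) < pcut`.
#'
#' @param counts Non-negative integer counts per bin.
#' @param lambda Background rate; defaults to the genome-wide mean count.
#' @param pcut Upper-tail probability cutoff (default 1e-4).
#' @return Integer vector of 0/1 calls.
#' @export
binarize <- function(counts, lambda = NULL, pcut = 1e-4) {
  if (is.null(lambda)) lambda <- mean(counts)
  if (lambda <= 0) abort("background rate lambda must be positive")
  tail <- ppois(counts - 1, lambda, lower.tail = FALSE)
  as.integer(tail < pcut)
}

#' Binarize a set of signal tracks over genome bins
#'
#' Bins each CPM-scaled track, converts bin signal to read-equivalent
#' counts (units of the smallest positive signal value, i.e. one
#' fragment), and applies the Poisson-tail call per track. Track order is
#' preserved and defines the state encoding of
#' [combinatorial_states()].
#'
#' @param tracks Named list of track tibbles (e.g. K4me1_WT, K4me1_DKO,
#'   K27ac_WT, K27ac_DKO).
#' @param bin_width Bin width in bp.
#' @param chrom_lengths Optional named lengths; inferred from the tracks
#'   when omitted.
#' @param pcut Binarization cutoff.
#' @return A binarized-matrix tibble: `chrom`, `start`, `end`, then one
#'   0/1 column per track.
#' @export
binarize_tracks <- function(tracks, bin_width = 200L, chrom_lengths = NULL,
                            pcut = 1e-4) {
  if (is.null(chrom_lengths)) {
    all <- bind_rows(lapply(tracks, function(x) x[, c("chrom", "end")]))
    chrom_lengths <- tapply(all$end, all$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  bins <- make_bins(chrom_lengths, bin_width)
  cols <- lapply(tracks, function(tr) {
    sig <- bin_signal(tr, bins)
    unit <- if (any(sig > 0)) min(tr$value[tr$value > 0]) else 1
    binarize(round(sig / unit), pcut = pcut)
  })
  names(cols) <- names(tracks)
  bind_cols(bins, as_tibble(cols))
}

## track columns of a binarized matrix
bmat_tracks <- function(bmat) setdiff(names(bmat), c("chrom", "start", "end"))

#' Direct combinatorial state assignment
#'
#' With K binary tracks the saturated model has `2^K` states; each bin's
#' state id is 1 plus the binary encoding of its track vector (first
#' track = most significant bit), so e.g. (1,0,1,0) encodes 1010 = 10,
#' state 11.
#'
#' @param bmat Binarized-matrix tibble from [binarize_tracks()].
#' @return `bmat` with a `state` column appended.
#' @export
combinatorial_states <- function(bmat) {
  trk <- bmat_tracks(bmat)
  K <- length(trk)
  state <- rep(1L, nrow(bmat))
  for (k in seq_len(K)) {
    state <- state + bmat[[trk[k]]] * 2L^(K - k)
  }
  mutate(bmat, state = as.integer(state))
}

#' Emission patterns of the combinatorial states
#'
#' @param track_names Track names in encoding order.
#' @return A `2^K` by K 0/1 matrix: row s is the track pattern of state s.
#' @export
state_emission_patterns <- function(track_names) {
  K <- length(track_names)
  E <- matrix(0L, nrow = 2^K, ncol = K, dimnames = list(NULL, track_names))
  for (s in seq_len(2^K)) {
    bits <- as.integer(intToBits(s - 1L))[K:1]
    E[s, ] <- bits
  }
  E
}

#' Fit a Bernoulli-emission hidden Markov model
#'
#' Baum-Welch (EM) over the binarized genome, with independent Bernoulli
#' emissions per track and log-domain forward-backward (chromosomes are
#' independent sequences). Initial emission probabilities are the
#' empirical track frequencies perturbed per state under `seed`; the
#' log-likelihood is non-decreasing over iterations and training stops at
#' relative tolerance `tol` or `max_iter`.
#'
#' @param bmat Binarized-matrix tibble.
#' @param n_states Number of hidden states (default 16).
#' @param seed Seed for the perturbed initialization.
#' @param max_iter,tol EM stopping rule.
#' @return A `bernoulli_hmm` object: `pi`, `A`, `E`, `loglik` trace,
#'   `converged`.
#' @export
hmm_fit <- function(bmat, n_states = 16L, seed = 1L, max_iter = 200L,
                    tol = 1e-4) {
  trk <- bmat_tracks(bmat)
  obs <- as.matrix(bmat[, trk, drop = FALSE])
  storage.mode(obs) <- "double"
  if (all(obs == 0)) abort("binarized matrix is all zero; nothing to fit")
  n_distinct <- nrow(unique(obs))
  if (n_distinct < n_states) {
    warn(sprintf("only %d distinct observation vectors for %d states",
                 n_distinct, n_states))
  }
  set.seed(seed)
  freq <- colMeans(obs)
  E <- matrix(rep(freq, each = n_states), nrow = n_states)
  E <- clamp01(E + matrix(runif(length(E), -0.25, 0.25), nrow = n_states))
  A <- matrix(0.2 / max(n_states - 1, 1), n_states, n_states)
  diag(A) <- if (n_states > 1) 0.8 else 1
  pi0 <- rep(1 / n_states, n_states)

  seqs <- split(seq_len(nrow(obs)), bmat$chrom)
  loglik_trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    logE1 <- log(E); logE0 <- log(1 - E)
    logA <- log(A); logPi <- log(pi0)
    ll <- 0
    gnum <- matrix(0, n_states, length(trk))   # sum gamma * obs
    gden <- numeric(n_states)                  # sum gamma
    xi <- matrix(0, n_states, n_states)
    pi_acc <- numeric(n_states)
    for (idx in seqs) {
      o <- obs[idx, , drop = FALSE]
      logB <- o %*% t(logE1) + (1 - o) %*% t(logE0)
      r <- fb_cpp(logB, logPi, logA)
      ll <- ll + r$loglik
      gnum <- gnum + t(r$gamma) %*% o
      gden <- gden + colSums(r$gamma)
      xi <- xi + r$xi
      pi_acc <- pi_acc + r$gamma[1, ]
    }
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(prev) && abs(ll - prev) < tol * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- ll
    ## M step
    pi0 <- pi_acc / sum(pi_acc)
    if (n_states > 1) {
      A <- xi / pmax(rowSums(xi), .Machine$double.eps)
      A <- A / rowSums(A)
    }
    E <- clamp01(gnum / pmax(gden, .Machine$double.eps))
    pi0 <- pmax(pi0, 1e-12); pi0 <- pi0 / sum(pi0)
    A <- pmax(A, 1e-12); A <- A / rowSums(A)
  }
  structure(
    list(n_states = n_states, tracks = trk, pi = pi0, A = A,
         E = `dimnames<-`(E, list(NULL, trk)),
         loglik = loglik_trace, converged = converged),
    class = "bernoulli_hmm"
  )
}

clamp01 <- function(x, eps = 1e-4) pmin(pmax(x, eps), 1 - eps)

#' @export
print.bernoulli_hmm <- function(x, ...) {
  cat(sprintf("Bernoulli-emission HMM: %d states, %d tracks, loglik %.2f (%s)\n",
              x$n_states, length(x$tracks), tail(x$loglik, 1),
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Decode a state path from a fitted HMM
#'
#' @param bmat Binarized-matrix tibble.
#' @param params A `bernoulli_hmm` from [hmm_fit()].
#' @param mode `"viterbi"` (max-probability path) or `"posterior"`
#'   (per-bin argmax of the forward-backward posterior).
#' @return `bmat` with a `state` column appended.
#' @export
hmm_decode <- function(bmat, params, mode = c("viterbi", "posterior")) {
  mode <- match.arg(mode)
  obs <- as.matrix(bmat[, params$tracks, drop = FALSE])
  storage.mode(obs) <- "double"
  logE1 <- log(params$E); logE0 <- log(1 - params$E)
  logA <- log(params$A); logPi <- log(params$pi)
  state <- integer(nrow(obs))
  for (idx in split(seq_len(nrow(obs)), bmat$chrom)) {
    o <- obs[idx, , drop = FALSE]
    logB <- o %*% t(logE1) + (1 - o) %*% t(logE0)
    if (mode == "viterbi") {
      state[idx] <- viterbi_cpp(logB, logPi, logA)
    } else {
      r <- fb_cpp(logB, logPi, logA)
      state[idx] <- max.col(r$gamma, ties.method = "first")
    }
  }
  mutate(bmat, state = as.integer(state))
}

#' Forward log-likelihood of a binarized matrix under HMM parameters
#'
#' Also returns the backward-pass total for the forward/backward
#' consistency invariant.
#'
#' @param bmat Binarized-matrix tibble.
#' @param params A `bernoulli_hmm`.
#' @return Tibble with `loglik` and `loglik_backward`.
#' @export
hmm_loglik <- function(bmat, params) {
  obs <- as.matrix(bmat[, params$tracks, drop = FALSE])
  storage.mode(obs) <- "double"
  logE1 <- log(params$E); logE0 <- log(1 - params$E)
  ll <- 0; llb <- 0
  for (idx in split(seq_len(nrow(obs)), bmat$chrom)) {
    o <- obs[idx, , drop = FALSE]
    logB <- o %*% t(logE1) + (1 - o) %*% t(logE0)
    r <- fb_cpp(logB, log(params$pi), log(params$A))
    ll <- ll + r$loglik; llb <- llb + r$loglik_backward
  }
  tibble(loglik = ll, loglik_backward = llb)
}

#' Merge a per-bin segmentation into state intervals
#'
#' @param seg Tibble with `chrom`, `start`, `end`, `state` per bin.
#' @return Tibble of merged same-state runs; the intervals partition the
#'   binned genome.
#' @export
segmentation_intervals <- function(seg) {
  seg <- arrange(seg, .data$chrom, .data$start)
  new_run <- c(TRUE, seg$chrom[-1L] != seg$chrom[-nrow(seg)] |
                 seg$state[-1L] != seg$state[-nrow(seg)] |
                 seg$start[-1L] != seg$end[-nrow(seg)])
  seg$run <- cumsum(new_run)
  seg %>%
    group_by(.data$run) %>%
    summarise(chrom = first(.data$chrom), state = first(.data$state),
              run_start = min(.data$start), run_end = max(.data$end),
              .groups = "drop") %>%
    mutate(start = .data$run_start, end = .data$run_end) %>%
    select("chrom", "start", "end", "state") %>%
    arrange(.data$chrom, .data$start)
}

#' Per-state expression test against the all-genes control
#'
#' Restricts state intervals to distal, ATAC-supported segments (at least
#' `overlap_frac` of an ATAC peak covered), links them to nearest TSSs,
#' and tests each state's deduplicated gene values against the all-genes
#' pool with [permutation_control_test()]; Benjamini-Hochberg across
#' states. States whose emission pattern has no mark signal (maximum
#' emission probability below `active_cut`) are excluded; states with no
#' qualifying distal segment are skipped.
#'
#' @param seg Per-bin segmentation (`chrom`, `start`, `end`, `state`).
#' @param atac_peaks ATAC peak intervals.
#' @param genes Gene models for [annotate_features()] and [nearest_tss()].
#' @param gene_values Tibble `feature`, `value`: the per-gene quantity
#'   tested (e.g. DKO/WT expression log2FC).
#' @param emissions State-by-track emission matrix (a fitted `E` or
#'   [state_emission_patterns()]).
#' @param thresholds An [enh_thresholds()] list (ATAC overlap fraction,
#'   promoter window).
#' @param active_cut Emission probability below which a state is
#'   considered mark-free.
#' @param n_perm,seed Permutation settings.
#' @return Tibble: `state`, `n_segments`, `n_genes`, `pvalue`, `fdr`.
#' @export
state_expression_test <- function(seg, atac_peaks, genes, gene_values,
                                  emissions, thresholds = enh_thresholds(),
                                  active_cut = 0.1, n_perm = 1000, seed = 1L) {
  intervals <- segmentation_intervals(seg)
  active <- which(apply(emissions, 1, max) >= active_cut)
  intervals <- intervals[intervals$state %in% active, , drop = FALSE]
  kept <- overlap_filter(intervals, atac_peaks, frac = thresholds$overlap_frac)
  kept <- annotate_features(kept, genes, thresholds = thresholds)
  kept <- kept[kept$feature_class == "Distal", , drop = FALSE]
  kept <- nearest_tss(kept, genes)
  all_vals <- gene_values$value
  rows <- list()
  for (s in sort(unique(kept$state))) {
    gs <- unique(kept$gene_id[kept$state == s & !is.na(kept$gene_id)])
    vals <- gene_values$value[match(gs, gene_values$feature)]
    vals <- vals[!is.na(vals)]
    if (length(vals) < 3L) next
    pt <- permutation_control_test(vals, all_vals, n_perm = n_perm, seed = seed)
    rows[[length(rows) + 1L]] <- tibble(
      state = s, n_segments = sum(kept$state == s), n_genes = length(vals),
      pvalue = pt$pvalue
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0L) out$fdr <- bh_adjust(out$pvalue)
  out
}
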