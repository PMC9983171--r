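test_that("Poisson-tail binarization thresholds match the survival function", {
  expect_equal(binarize(0, lambda = 5), 0L)
  expect_equal(binarize(10, lambda = 1), 1L)  # tail ~1.1e-7 < 1e-4
  for (lambda in c(0.5, 1, 5)) {
    counts <- 0:30
    oracle <- vapply(counts, function(c) {
      ## brute-force tail sum P(X >= c)
      tail_p <- 1 - sum(dpois(seq_len(c) - 1, lambda))
      as.integer(tail_p < 1e-4)
    }, integer(1))
    expect_equal(binarize(counts, lambda = lambda), oracle)
  }
  expect_error(binarize(1:3, lambda = 0), "lambda")
})

test_that("combinatorial state ids are the binary encoding of the track vector", {
  bmat <- tibble::tibble(chrom = "chr1", start = c(0, 200, 400),
                         end = c(200, 400, 600),
                         t1 = c(0L, 1L, 1L), t2 = c(0L, 0L, 1L),
                         t3 = c(0L, 1L, 1L), t4 = c(0L, 0L, 1L))
  s <- combinatorial_states(bmat)$state
  expect_equal(s, c(1L, 11L, 16L))  # 0000, 1010, 1111
  pats <- state_emission_patterns(paste0("t", 1:4))
  expect_equal(unname(pats[11, ]), c(1L, 0L, 1L, 0L))
  expect_equal(unname(pats[1, ]), c(0L, 0L, 0L, 0L))
})

test_that("state histogram matches planted states on noiseless combinations", {
  set.seed(61)
  n <- 3000
  planted <- sample(c(1L, 6L, 11L, 16L), n, replace = TRUE,
                    prob = c(0.5, 0.2, 0.2, 0.1))
  pats <- state_emission_patterns(paste0("t", 1:4))
  bmat <- tibble::tibble(chrom = "chr1", start = (seq_len(n) - 1) * 200,
                         end = seq_len(n) * 200)
  for (k in 1:4) bmat[[paste0("t", k)]] <- pats[planted, k]
  got <- combinatorial_states(bmat)$state
  expect_equal(got, planted)
})

test_that("a one-state HMM collapses to the empirical Bernoulli fit", {
  set.seed(62)
  n <- 2000
  bmat <- tibble::tibble(chrom = "chr1", start = (seq_len(n) - 1) * 200,
                         end = seq_len(n) * 200,
                         t1 = rbinom(n, 1, 0.3), t2 = rbinom(n, 1, 0.7))
  fit <- hmm_fit(bmat, n_states = 1, seed = 1, max_iter = 20)
  freq <- c(mean(bmat$t1), mean(bmat$t2))
  expect_equal(unname(fit$E[1, ]), freq, tolerance = 1e-6)
  closed_form <- sum(bmat$t1 * log(freq[1]) + (1 - bmat$t1) * log(1 - freq[1]) +
                     bmat$t2 * log(freq[2]) + (1 - bmat$t2) * log(1 - freq[2]))
  expect_equal(tail(fit$loglik, 1), closed_form, tolerance = 1e-6)
})

test_that("Baum-Welch log-likelihood is monotone non-decreasing", {
  set.seed(63)
  n <- 1500
  bmat <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = n / 2),
                         start = rep((seq_len(n / 2) - 1) * 200, 2),
                         end = rep(seq_len(n / 2) * 200, 2),
                         t1 = rbinom(n, 1, 0.4), t2 = rbinom(n, 1, 0.2),
                         t3 = rbinom(n, 1, 0.6))
  fit <- hmm_fit(bmat, n_states = 4, seed = 2, max_iter = 30)
  expect_true(all(diff(fit$loglik) > -1e-6))
})

test_that("forward pass and Viterbi match exhaustive path enumeration", {
  set.seed(64)
  for (rep in 1:4) {
    S <- sample(2:3, 1); T_len <- sample(5:8, 1); K <- 2
    obs <- matrix(rbinom(T_len * K, 1, 0.5), ncol = K)
    E <- matrix(runif(S * K, 0.1, 0.9), nrow = S)
    A <- matrix(runif(S * S), S); A <- A / rowSums(A)
    p0 <- runif(S); p0 <- p0 / sum(p0)
    params <- structure(list(n_states = S, tracks = paste0("t", 1:K),
                             pi = p0, A = A,
                             E = `dimnames<-`(E, list(NULL, paste0("t", 1:K))),
                             loglik = 0, converged = TRUE),
                        class = "bernoulli_hmm")
    bmat <- tibble::tibble(chrom = "chr1", start = (seq_len(T_len) - 1) * 200,
                           end = seq_len(T_len) * 200)
    for (k in 1:K) bmat[[paste0("t", k)]] <- obs[, k]

    ## brute force over all S^T paths
    emit <- function(s, t) prod(E[s, ]^obs[t, ] * (1 - E[s, ])^(1 - obs[t, ]))
    paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_len)))
    path_prob <- apply(paths, 1, function(pp) {
      p <- p0[pp[1]] * emit(pp[1], 1)
      for (t in seq_len(T_len - 1)) {
        p <- p * A[pp[t], pp[t + 1]] * emit(pp[t + 1], t + 1)
      }
      p
    })
    ll <- hmm_loglik(bmat, params)
    expect_equal(ll$loglik, log(sum(path_prob)), tolerance = 1e-9)
    expect_equal(ll$loglik, ll$loglik_backward, tolerance = 1e-8)

    best <- paths[which.max(path_prob), ]
    vit <- hmm_decode(bmat, params, mode = "viterbi")$state
    expect_equal(vit, unname(best))
  }
})

test_that("segmentation intervals tile the binned genome", {
  set.seed(65)
  n <- 400
  seg <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = n / 2),
                        start = rep((seq_len(n / 2) - 1) * 200, 2),
                        end = rep(seq_len(n / 2) * 200, 2),
                        state = sample(1:4, n, TRUE))
  iv <- segmentation_intervals(seg)
  expect_equal(sum(iv$end - iv$start), sum(seg$end - seg$start))
  for (ch in c("chr1", "chr2")) {
    x <- iv[iv$chrom == ch, ]
    expect_equal(x$start[-1], x$end[-nrow(x)])  # no gaps, no overlaps
  }
  ## round trip: per-bin states are preserved
  expect_equal(nrow(dplyr::distinct(seg[, c("chrom", "start", "state")])), n)
})

test_that("combinatorial and decoded states agree on near-noiseless data", {
  set.seed(66)
  n <- 4000
  planted <- sample(1:4, n, TRUE, prob = c(0.55, 0.2, 0.15, 0.1))
  pats <- state_emission_patterns(c("t1", "t2"))
  flip <- function(x, p = 0.02) ifelse(runif(length(x)) < p, 1L - x, x)
  bmat <- tibble::tibble(chrom = "chr1", start = (seq_len(n) - 1) * 200,
                         end = seq_len(n) * 200,
                         t1 = flip(pats[planted, 1]),
                         t2 = flip(pats[planted, 2]))
  comb <- combinatorial_states(bmat)$state
  params <- structure(list(n_states = 4, tracks = c("t1", "t2"),
                           pi = rep(0.25, 4),
                           A = matrix(0.25, 4, 4),
                           E = `dimnames<-`(
                             matrix(c(0.02, 0.98)[pats + 1L], nrow = 4),
                             list(NULL, c("t1", "t2"))),
                           loglik = 0, converged = TRUE),
                      class = "bernoulli_hmm")
  dec <- hmm_decode(bmat, params, mode = "posterior")$state
  expect_gte(mean(dec == comb), 0.99)
})

test_that("states without distal segments are skipped by the expression test", {
  set.seed(67)
  ## genes every 5 kb; distal state-2 runs planted in the intergenic gaps
  ## of even periods only; state 3 never occurs
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                          start = (0:19) * 5000, end = (0:19) * 5000 + 1000,
                          strand = "+")
  genes$tss <- genes$start
  bins <- (0:499) * 200
  period <- bins %/% 5000
  offset <- bins %% 5000
  state <- ifelse(offset >= 2400 & offset < 3400 & period %% 2 == 0, 2L, 1L)
  seg <- tibble::tibble(chrom = "chr1", start = bins, end = bins + 200,
                        state = state)
  atac_start <- (0:19) * 5000 + 2600
  atac <- tibble::tibble(chrom = "chr1", start = atac_start,
                         end = atac_start + 400)
  vals <- tibble::tibble(feature = genes$gene_id, value = rnorm(20))
  out <- state_expression_test(seg, atac, genes, vals,
                               emissions = matrix(c(0, 1, 1), ncol = 1),
                               n_perm = 200)
  expect_equal(out$state, 2L)      # the one planted distal state is tested
  expect_false(1 %in% out$state)   # mark-free state excluded
  expect_false(3 %in% out$state)   # absent state skipped
  expect_gte(out$n_genes, 3)
})
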