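# Small simulation configuration for unit tests (desk-scale defaults are
# exercised in the acceptance tests).
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chroms = 2L, chrom_length = 1e6,
               n_enhancers = 200L, n_genes = 120L, depth = 2e5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# random sparse track on a toy genome, bin-structured
random_track <- function(n_bins = 100, bin = 100, p_zero = 0.6, chrom = "chr1") {
  value <- ifelse(runif(n_bins) < p_zero, 0, round(runif(n_bins, 0.5, 5), 3))
  starts <- (seq_len(n_bins) - 1) * bin
  tibble::tibble(chrom = chrom, start = starts, end = starts + bin,
                 value = value)
}

# per-base expansion of a track over [0, len) for brute-force oracles
track_to_base_vector <- function(track, len) {
  v <- numeric(len)
  for (i in seq_len(nrow(track))) {
    v[(track$start[i] + 1):track$end[i]] <- track$value[i]
  }
  v
}

# independent straight-line TMM implementation (the oracle): weighted
# trimmed mean of log ratios, 30% M-trim, 5% A-trim, reference by upper
# quartile closest to the mean upper quartile
tmm_oracle <- function(m) {
  lib <- colSums(m)
  uq <- apply(m, 2, function(y) quantile(y / sum(y), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    y1 <- m[, j]; y2 <- m[, ref]; N1 <- lib[j]; N2 <- lib[ref]
    ok <- y1 > 0 & y2 > 0
    y1 <- y1[ok]; y2 <- y2[ok]
    M <- log2((y1 / N1) / (y2 / N2))
    A <- 0.5 * log2((y1 / N1) * (y2 / N2))
    v <- (N1 - y1) / (N1 * y1) + (N2 - y2) / (N2 * y2)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    fj <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
    if (!is.finite(fj)) fj <- 0
    2^fj
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

# counts tibble from a bare matrix
as_counts_tbl <- function(m, features = paste0("f", seq_len(nrow(m)))) {
  tibble::as_tibble(cbind(data.frame(feature = features),
                          as.data.frame(m)))
}
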