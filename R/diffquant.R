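#' Union of peak sets
#'
#' Merges overlapping and bookended (gap 0) intervals across any number of
#' peak sets into a sorted, disjoint interval set — the consensus peak list
#' used for quantification.
#'
#' @param peaksets A list of interval tibbles (or a single tibble).
#' @return Sorted disjoint interval tibble.
#' @export
union_peaks <- function(peaksets) {
  if (is.data.frame(peaksets)) peaksets <- list(peaksets)
  if (length(peaksets) == 0L) abort("need at least one peak set")
  all <- bind_rows(lapply(peaksets, function(x) x[, c("chrom", "start", "end")]))
  if (nrow(all) == 0L) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  gr <- GenomicRanges::reduce(as_granges(all))
  arrange(granges_to_tibble(gr), .data$chrom, .data$start)
}

#' Count track signal in peaks
#'
#' Per-peak total signal area (sum of value times overlapped width),
#' rounded to integer counts. Additive over disjoint peaks; overlapping
#' peaks are an error.
#'
#' @param track A track tibble.
#' @param peaks Disjoint interval tibble.
#' @return Integer vector of per-peak counts, in peak order.
#' @export
count_in_peaks <- function(track, peaks) {
  validate_intervals(peaks)
  pgr <- as_granges(peaks)
  if (sum(GenomicRanges::width(pgr)) !=
      sum(GenomicRanges::width(GenomicRanges::reduce(pgr)))) {
    abort("peaks must be disjoint")
  }
  counts <- numeric(nrow(peaks))
  if (nrow(track) > 0L) {
    tgr <- as_granges(track)
    hits <- GenomicRanges::findOverlaps(tgr, pgr)
    if (length(hits) > 0L) {
      ti <- S4Vectors::queryHits(hits); pi <- S4Vectors::subjectHits(hits)
      ov <- pmin(track$end[ti], peaks$end[pi]) - pmax(track$start[ti], peaks$start[pi])
      contrib <- track$value[ti] * ov
      agg <- tapply(contrib, pi, sum)
      counts[as.integer(names(agg))] <- agg
    }
  }
  as.integer(round(counts))
}

#' Filter features by minimum CPM
#'
#' Keeps features with counts-per-million above `min_cpm` in at least
#' `min_samples` samples. Library sizes are the column sums of the input
#' (fixed before any filtering, so filtering does not change the CPM scale).
#'
#' @param counts Count tibble (`feature` + sample columns).
#' @param min_cpm CPM threshold (strict `>`).
#' @param min_samples Minimum number of samples above threshold.
#' @return Filtered count tibble.
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_samples = 2) {
  m <- counts_matrix(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) abort("library sizes must be positive")
  cpm <- sweep(m, 2, lib, "/") * 1e6
  keep <- rowSums(cpm > min_cpm) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Trimmed-mean-of-M-values normalisation factors
#'
#' Between-sample scale factors computed as the weighted trimmed mean of
#' per-feature log ratios (30% log-ratio trim, 5% absolute-intensity trim,
#' precision weights), against the sample whose upper quartile is closest
#' to the mean upper quartile. Factors are scaled so their geometric mean
#' is 1.
#'
#' @param counts Count tibble (`feature` + sample columns).
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts) {
  m <- counts_matrix(counts)
  if (ncol(m) < 2L) abort("need at least two samples")
  if (any(colSums(m) == 0)) abort("a sample has all-zero counts")
  f <- edgeR::calcNormFactors(m, method = "TMM")
  setNames(as.numeric(f), colnames(m))
}

#' Log2 CPM density per basepair
#'
#' The per-bp peak density used for abundance summaries:
#' `log2((count / library_size) * 1e6 + 1) / width_bp`.
#'
#' @param count,library_size,width_bp Vectors (recycled).
#' @return Numeric vector of densities.
#' @export
log2cpm_density <- function(count, library_size, width_bp) {
  if (any(width_bp <= 0)) abort("width_bp must be positive")
  log2((count / library_size) * 1e6 + 1) / width_bp
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return FDR (step-up adjusted) values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Differential enrichment / expression test
#'
#' Two-group per-feature test on a count matrix, group B over group A.
#' Log2 fold changes are ratios of TMM-normalised group means with
#' pseudocount 0.5. `nb_wald` fits a per-feature negative-binomial Wald
#' test with method-of-moments dispersion shrunk toward a fitted
#' mean-dispersion trend; `permutation` compares the observed `|log2fc|`
#' to its group-label permutation null (all distinct assignments when
#' there are at most 1000, otherwise 1000 sampled under `seed`).
#' P-values are Benjamini-Hochberg corrected.
#'
#' @param counts Count tibble (`feature` + sample columns).
#' @param group_a,group_b Character vectors of sample column names.
#' @param method `"nb_wald"` or `"permutation"`.
#' @param norm_factors Optional named TMM factors (computed over all
#'   columns of `counts` when omitted).
#' @param lib_sizes Optional named library sizes (pre-filter column sums;
#'   defaults to the column sums of `counts`).
#' @param pseudocount Pseudocount on normalised means for fold changes.
#' @param prior_df Prior degrees of freedom pulling per-feature dispersion
#'   toward the trend.
#' @param n_perm Maximum number of label permutations.
#' @param seed Seed for sampled permutations.
#' @return A `enh_diff` tibble: `feature`, `log2fc`, `pvalue`, `fdr`,
#'   `mean_abundance`.
#' @export
differential_test <- function(counts, group_a, group_b,
                              method = c("nb_wald", "permutation"),
                              norm_factors = NULL, lib_sizes = NULL,
                              pseudocount = 0.5, prior_df = 10,
                              n_perm = 1000, seed = 1L) {
  method <- match.arg(method)
  m <- counts_matrix(counts)
  if (!all(c(group_a, group_b) %in% colnames(m))) {
    abort("group samples not found among count columns")
  }
  if (method == "nb_wald" && (length(group_a) < 2L || length(group_b) < 2L)) {
    abort("nb_wald needs >=2 replicates per group; use method = \"permutation\"")
  }
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  eff <- lib_sizes[colnames(m)] * norm_factors[colnames(m)]
  norm <- sweep(m, 2, eff / mean(eff), "/")

  na <- length(group_a); nb <- length(group_b)
  A <- norm[, group_a, drop = FALSE]; B <- norm[, group_b, drop = FALSE]
  mu_a <- unname(rowMeans(A)); mu_b <- unname(rowMeans(B))
  log2fc <- log2((mu_b + pseudocount) / (mu_a + pseudocount))
  mean_abundance <- (mu_a + mu_b) / 2

  if (method == "nb_wald") {
    phi <- shrunk_dispersion(A, B, prior_df)
    se2 <- (1 / (mu_a + pseudocount) + phi) / na +
           (1 / (mu_b + pseudocount) + phi) / nb
    z <- log((mu_b + pseudocount) / (mu_a + pseudocount)) / sqrt(se2)
    ## moderated reference: residual df plus the prior df backing the trend
    pvalue <- 2 * stats::pt(-abs(z), df = na + nb - 2 + prior_df)
  } else {
    pvalue <- permutation_pvalues(norm[, c(group_a, group_b), drop = FALSE],
                                  na, nb, abs(log2fc), pseudocount,
                                  n_perm, seed)
  }
  out <- tibble(feature = counts$feature, log2fc = log2fc, pvalue = pvalue,
                fdr = bh_adjust(pvalue), mean_abundance = mean_abundance)
  class(out) <- c("enh_diff", class(out))
  attr(out, "method") <- method
  attr(out, "contrast") <- c(a = paste(group_a, collapse = ","),
                             b = paste(group_b, collapse = ","))
  out
}

## method-of-moments dispersion shrunk toward a binned mean-dispersion trend
shrunk_dispersion <- function(A, B, prior_df) {
  na <- ncol(A); nb <- ncol(B)
  mu_a <- rowMeans(A); mu_b <- rowMeans(B)
  ## pooled within-group variance
  va <- apply(A, 1, var); vb <- apply(B, 1, var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  mu <- (na * mu_a + nb * mu_b) / (na + nb)
  ## untruncated method-of-moments estimate: unbiased numerator keeps the
  ## binned trend means from drifting low at small replicate numbers
  raw <- (s2 - mu) / mu^2
  raw[!is.finite(raw)] <- 0

  ## trend: mean raw dispersion in bins of mean abundance
  ok <- mu > 0
  trend <- rep(max(mean(raw[ok]), 1e-8), length(mu))
  if (sum(ok) >= 100) {
    lmu <- log(mu[ok])
    nb_bins <- max(5L, min(20L, floor(sum(ok) / 50)))
    bins <- cut(lmu, breaks = nb_bins, include.lowest = TRUE)
    bm <- tapply(raw[ok], bins, mean)
    mids <- tapply(lmu, bins, mean)
    keep <- !is.na(bm)
    if (sum(keep) >= 2) {
      tr <- approx(mids[keep], pmax(bm[keep], 1e-8), xout = lmu, rule = 2)$y
      trend[ok] <- tr
    }
  }
  df <- na + nb - 2
  w <- df / (df + prior_df)
  pmax(w * pmax(raw, 0) + (1 - w) * trend, 1e-8)
}

permutation_pvalues <- function(norm, na, nb, obs_abs_lfc, pseudocount,
                                n_perm, seed) {
  n <- na + nb
  combos <- combn(n, na)
  if (ncol(combos) <= n_perm) {
    idx <- combos
    exact <- TRUE
  } else {
    set.seed(seed)
    sel <- sample(ncol(combos), n_perm)
    idx <- combos[, sel, drop = FALSE]
    exact <- FALSE
  }
  np <- ncol(idx)
  count_ge <- numeric(nrow(norm))
  for (j in seq_len(np)) {
    a <- idx[, j]; b <- setdiff(seq_len(n), a)
    lfc <- log2((rowMeans(norm[, b, drop = FALSE]) + pseudocount) /
                (rowMeans(norm[, a, drop = FALSE]) + pseudocount))
    count_ge <- count_ge + (abs(lfc) >= obs_abs_lfc - 1e-12)
  }
  if (exact) count_ge / np else (count_ge + 1) / (np + 1)
}

## internal: tibble (feature + samples) -> numeric matrix
counts_matrix <- function(counts) {
  if (!is.data.frame(counts) || names(counts)[1] != "feature") {
    abort("counts must be a tibble with `feature` as its first column")
  }
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$feature
  if (any(m < 0)) abort("counts must be non-negative")
  m
}
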