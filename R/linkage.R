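#' Link peaks to their nearest TSS
#'
#' Assigns every peak the gene whose TSS is closest to the peak midpoint.
#' Ties are broken deterministically: lower TSS coordinate first, then
#' lexicographic gene id. The distance is signed (midpoint minus TSS).
#'
#' @param peaks Interval tibble (extra columns carried through).
#' @param genes Gene models with `gene_id` and `tss` (or `strand`, from
#'   which the TSS is derived).
#' @return `peaks` with `gene_id` and `tss_distance` columns appended;
#'   peaks on chromosomes without genes get `NA`.
#' @export
nearest_tss <- function(peaks, genes) {
  if (nrow(genes) == 0L) abort("gene list is empty")
  if (is.null(genes$tss)) {
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  }
  mid <- (peaks$start + peaks$end) %/% 2
  gene_id <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    ord <- order(g$tss, g$gene_id)
    ts <- g$tss[ord]
    pos <- findInterval(mid[pi], ts)
    for (k in seq_along(pi)) {
      m <- mid[pi[k]]
      i_left <- pos[k]
      d_left <- if (i_left >= 1L) m - ts[i_left] else Inf
      i_right <- pos[k] + 1L
      d_right <- if (i_right <= length(ts)) ts[i_right] - m else Inf
      if (d_left <= d_right) {
        ## first occurrence of the left TSS value: lowest gene id at ties
        i <- match(ts[i_left], ts)
      } else {
        i <- i_right
      }
      gene_id[pi[k]] <- g$gene_id[ord[i]]
      dist[pi[k]] <- m - ts[i]
    }
  }
  mutate(peaks, gene_id = gene_id, tss_distance = dist)
}

#' Restrict a linkage table to nearby links
#'
#' @param linkage Output of [nearest_tss()].
#' @param max_bp Maximum absolute midpoint-to-TSS distance (bp).
#' @return The subset within `max_bp`.
#' @export
distance_filter <- function(linkage, max_bp = 10000) {
  linkage[!is.na(linkage$tss_distance) & abs(linkage$tss_distance) <= max_bp, ,
          drop = FALSE]
}

#' Mean log2 CPM expression per sample class
#'
#' CPM with TMM normalisation, replicates averaged within each
#' condition-by-genotype class, then `log2(x + 1)`.
#'
#' @param counts Expression count tibble (`feature` + sample columns).
#' @param meta Sample metadata ([sample_metadata()] layout).
#' @return Tibble: `feature` plus one log2 CPM column per class
#'   (e.g. `WT_naive`).
#' @export
expression_log2cpm <- function(counts, meta) {
  m <- counts_matrix(counts)
  f <- tmm_factors(counts)
  eff <- colSums(m) * f[colnames(m)]
  cpm <- sweep(m, 2, eff, "/") * 1e6
  classes <- unique(paste(meta$genotype, meta$condition, sep = "_"))
  cols <- lapply(classes, function(cl) {
    s <- meta$sample[paste(meta$genotype, meta$condition, sep = "_") == cl]
    log2(rowMeans(cpm[, s, drop = FALSE]) + 1)
  })
  names(cols) <- classes
  as_tibble(c(list(feature = counts$feature), cols))
}

#' Expression tests for peak categories
#'
#' For each peak category, takes the deduplicated set of linked genes and
#' runs a paired Wilcoxon signed-rank test of per-gene log2 CPM between
#' the two sample classes of each comparison (exact null for n <= 25,
#' normal approximation with continuity correction above; set
#' `paired = FALSE` for the rank-sum variant). P-values are
#' Benjamini-Hochberg corrected across the whole category-by-comparison
#' family. Categories linked to fewer than `min_genes` genes are skipped
#' with a warning.
#'
#' @param linkage Tibble with `gene_id` and `category` columns (one row
#'   per peak).
#' @param expr Per-class log2 CPM tibble from [expression_log2cpm()].
#' @param comparisons List of length-2 character vectors naming the class
#'   columns to compare (second over first).
#' @param min_genes Minimum genes per category.
#' @param paired Paired signed-rank (default) or unpaired rank-sum.
#' @return Tibble: `category`, `comparison`, `n_genes`, `statistic`,
#'   `median_diff`, `pvalue`, `fdr`.
#' @export
category_expression_test <- function(linkage, expr, comparisons,
                                     min_genes = 5, paired = TRUE) {
  cats <- unique(linkage$category)
  rows <- list()
  for (cat in cats) {
    genes <- unique(linkage$gene_id[linkage$category == cat & !is.na(linkage$gene_id)])
    idx <- match(genes, expr$feature)
    idx <- idx[!is.na(idx)]
    if (length(idx) < min_genes) {
      warn(sprintf("category '%s' links to %d genes (< %d); skipped",
                   cat, length(idx), min_genes))
      next
    }
    for (cmp in comparisons) {
      x <- expr[[cmp[1]]][idx]; y <- expr[[cmp[2]]][idx]
      if (paired && all(y == x)) {
        ## no nonzero differences: no evidence of any shift
        stat <- 0; pv <- 1
      } else {
        wt <- suppressWarnings(
          wilcox.test(y, x, paired = paired, exact = length(idx) <= 25,
                      correct = TRUE)
        )
        stat <- unname(wt$statistic)
        pv <- if (is.na(wt$p.value)) 1 else wt$p.value
      }
      rows[[length(rows) + 1L]] <- tibble(
        category = cat, comparison = paste(cmp[2], "vs", cmp[1]),
        n_genes = length(idx), statistic = stat,
        median_diff = median(y - x), pvalue = pv
      )
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0L) out$fdr <- bh_adjust(out$pvalue)
  out
}

#' Monte-Carlo permutation test against an all-genes control
#'
#' Tests whether a gene set's values differ in location from the pool of
#' all gene values. The observed Mann-Whitney U compares the state set to
#' the all-genes control; the null distribution is built from same-size
#' subsets drawn from the pool without replacement (all subsets when
#' exhaustive enumeration fits within `n_perm` draws, otherwise `n_perm`
#' sampled under `seed`). The two-sided empirical p is the fraction of
#' draws whose U deviates from its null centre at least as much as the
#' observed U. Rank-based, hence invariant to adding a constant to all
#' values.
#'
#' @param state_values Values of the gene set (must be drawn from
#'   `all_values`).
#' @param all_values Values of all genes (the control pool).
#' @param n_perm Number of Monte-Carlo draws.
#' @param seed RNG seed for sampled draws.
#' @return A one-row tibble: `n_state`, `n_all`, `u_obs`, `n_draws`,
#'   `exhaustive`, `pvalue`.
#' @export
permutation_control_test <- function(state_values, all_values,
                                     n_perm = 1000, seed = 1L) {
  n1 <- length(state_values); N <- length(all_values)
  if (n1 < 2L) abort("state set must have at least 2 genes")
  if (n_perm < 100) warn("n_perm < 100 gives a coarse permutation p-value")
  ## multiset containment check
  pool <- all_values
  for (v in state_values) {
    i <- match(v, pool)
    if (is.na(i)) abort("state set values must be a subset of all-gene values")
    pool <- pool[-i]
  }
  u_stat <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  centre <- n1 * N / 2
  u_obs <- u_stat(state_values, all_values)
  n_comb <- suppressWarnings(choose(N, n1))
  if (is.finite(n_comb) && n_comb <= n_perm) {
    draws <- combn(N, n1)
    u_null <- apply(draws, 2, function(i) u_stat(all_values[i], all_values))
    p <- mean(abs(u_null - centre) >= abs(u_obs - centre) - 1e-9)
    exhaustive <- TRUE
    nd <- ncol(draws)
  } else {
    set.seed(seed)
    u_null <- vapply(seq_len(n_perm), function(b) {
      u_stat(all_values[sample.int(N, n1)], all_values)
    }, numeric(1))
    p <- (sum(abs(u_null - centre) >= abs(u_obs - centre) - 1e-9) + 1) /
      (n_perm + 1)
    exhaustive <- FALSE
    nd <- n_perm
  }
  tibble(n_state = n1, n_all = N, u_obs = u_obs, n_draws = nd,
         exhaustive = exhaustive, pvalue = p)
}

#' Enhancer-burden regression of expression change
#'
#' Ordinary least-squares (identity-link Gaussian GLM) of per-gene DKO/WT
#' log2 fold change on the number of MLL3/4-dependent enhancers linked to
#' the gene.
#'
#' @param gene_table Tibble with `n_dependent` (enhancer count) and
#'   `log2fc` (gene expression fold change) columns.
#' @return A `burden_fit` object; see [tidy()] / [glance()] methods.
#' @export
enhancer_burden_fit <- function(gene_table) {
  if (nrow(gene_table) < 10L) abort("need at least 10 genes")
  if (var(gene_table$n_dependent) == 0) abort("enhancer counts have zero variance")
  fit <- lm(log2fc ~ n_dependent, data = gene_table)
  ci <- confint(fit, "n_dependent", level = 0.95)
  structure(
    list(model = fit, data = gene_table,
         slope = unname(coef(fit)["n_dependent"]),
         conf_low = ci[1], conf_high = ci[2]),
    class = "burden_fit"
  )
}

#' @export
print.burden_fit <- function(x, ...) {
  cat(sprintf("Enhancer-burden fit: slope %.4f [95%% CI %.4f, %.4f], n = %d genes\n",
              x$slope, x$conf_low, x$conf_high, nrow(x$data)))
  invisible(x)
}

#' Bin genes by the percentage of dependent enhancers lost
#'
#' Bins genes by the percentage of their linked enhancers that are
#' MLL3/4-dependent — bins `0`, `(0,25]`, `(25,50]`, `(50,75]`,
#' `(75,100]` percent — and summarises the per-bin distribution of gene
#' log2 fold change, with an unpaired Wilcoxon of each bin against the 0%
#' bin (Benjamini-Hochberg corrected).
#'
#' @param gene_table Tibble with `pct_dependent` (0-100) and `log2fc`.
#' @return Tibble: `bin`, `n`, `q25`, `median`, `q75`, `pvalue`, `fdr`.
#' @export
enhancer_loss_binning <- function(gene_table) {
  pct <- gene_table$pct_dependent
  bin <- ifelse(pct == 0, "0",
                as.character(cut(pct, c(0, 25, 50, 75, 100),
                                 labels = c("(0,25]", "(25,50]", "(50,75]", "(75,100]"))))
  lev <- c("0", "(0,25]", "(25,50]", "(50,75]", "(75,100]")
  gene_table$bin <- factor(bin, levels = lev)
  ref <- gene_table$log2fc[gene_table$bin == "0"]
  out <- gene_table %>%
    group_by(.data$bin) %>%
    summarise(n = n(),
              q25 = unname(quantile(.data$log2fc, 0.25)),
              median = median(.data$log2fc),
              q75 = unname(quantile(.data$log2fc, 0.75)),
              .groups = "drop")
  pv <- vapply(as.character(out$bin), function(b) {
    if (b == "0" || length(ref) == 0L) return(NA_real_)
    x <- gene_table$log2fc[gene_table$bin == b]
    if (length(x) == 0L) return(NA_real_)
    suppressWarnings(wilcox.test(x, ref)$p.value)
  }, numeric(1))
  out$pvalue <- unname(pv)
  out$fdr <- NA_real_
  ok <- !is.na(out$pvalue)
  if (any(ok)) out$fdr[ok] <- bh_adjust(out$pvalue[ok])
  out
}

#' Enhancer acetylation change around dependent vs independent genes
#'
#' For each gene dependency class, collects the H3K27ac log2 fold change
#' (formative over naive) of linked enhancers, in WT and DKO, and compares
#' dependent vs independent classes per genotype by unpaired Wilcoxon.
#' Classes with no linked enhancers are skipped with a warning.
#'
#' @param gene_classes Output of [classify_genes()] (filtered to the gene
#'   class of interest, e.g. formative genes).
#' @param linkage Tibble with `enhancer_id` and `gene_id` columns (one row
#'   per linked enhancer, typically the H3K4me1/H3K27ac+ subset).
#' @param k27_lfc Tibble with `enhancer_id`, `lfc_wt`, `lfc_dko`: the
#'   H3K27ac formative-over-naive log2 fold change within each genotype.
#' @return A list: `values` (one row per linked enhancer per genotype) and
#'   `summary` (per-genotype medians and Wilcoxon p between classes).
#' @export
gene_centric_acetylation_fc <- function(gene_classes, linkage, k27_lfc) {
  linked <- linkage %>%
    inner_join(gene_classes, by = c(gene_id = "feature")) %>%
    inner_join(k27_lfc, by = "enhancer_id")
  vals <- linked %>%
    tidyr::pivot_longer(cols = c("lfc_wt", "lfc_dko"), names_to = "genotype",
                        values_to = "lfc") %>%
    mutate(genotype = if_else(.data$genotype == "lfc_wt", "WT", "DKO")) %>%
    select("enhancer_id", "gene_id", "gene_dependency", "genotype", "lfc")
  rows <- list()
  for (g in unique(vals$genotype)) {
    dep <- vals$lfc[vals$genotype == g & vals$gene_dependency == "dependent"]
    ind <- vals$lfc[vals$genotype == g & vals$gene_dependency == "independent"]
    if (length(dep) == 0L || length(ind) == 0L) {
      warn(sprintf("genotype %s: a dependency class has no linked enhancers; skipped", g))
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      genotype = g, n_dependent = length(dep), n_independent = length(ind),
      median_dependent = median(dep), median_independent = median(ind),
      pvalue = suppressWarnings(wilcox.test(dep, ind)$p.value)
    )
  }
  list(values = vals, summary = bind_rows(rows))
}
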