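test_that("nearest TSS assignment handles exact hits and ties", {
  genes <- tibble::tibble(gene_id = c("gB", "gA"), chrom = "chr1",
                          start = c(100, 200), end = c(150, 250),
                          strand = "+", tss = c(100, 200))
  hit <- nearest_tss(tibble::tibble(chrom = "chr1", start = 90, end = 110),
                     genes)
  expect_equal(hit$gene_id, "gB")
  expect_equal(hit$tss_distance, 0)

  ## midpoint 150 equidistant from 100 and 200: lower TSS wins
  tie <- nearest_tss(tibble::tibble(chrom = "chr1", start = 100, end = 200),
                     genes)
  expect_equal(tie$gene_id, "gB")

  ## equal TSS coordinates: lexicographic gene id wins
  genes2 <- tibble::tibble(gene_id = c("gZ", "gC"), chrom = "chr1",
                           start = c(100, 100), end = c(150, 160),
                           strand = "+", tss = c(100, 100))
  expect_equal(nearest_tss(tibble::tibble(chrom = "chr1", start = 90,
                                          end = 110), genes2)$gene_id, "gC")
  expect_error(nearest_tss(tibble::tibble(chrom = "chr1", start = 0, end = 1),
                           genes[0, ]), "empty")
})

test_that("nearest TSS agrees with an exhaustive search on random data", {
  set.seed(51)
  n_genes <- 60; n_peaks <- 500
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, TRUE),
    tss = sample.int(1e6, n_genes)
  )
  genes$start <- genes$tss; genes$end <- genes$tss + 1000
  s <- sample.int(1e6, n_peaks)
  peaks <- tibble::tibble(chrom = sample(c("chr1", "chr2"), n_peaks, TRUE),
                          start = s, end = s + 200)
  got <- nearest_tss(peaks, genes)
  mid <- (peaks$start + peaks$end) %/% 2
  oracle <- vapply(seq_len(n_peaks), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    d <- abs(mid[i] - g$tss)
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[order(g$tss[best], g$gene_id[best])][1]
    g$gene_id[best]
  }, character(1))
  expect_equal(got$gene_id, oracle)
  ## every peak links to exactly one gene
  expect_true(all(!is.na(got$gene_id)))
  expect_equal(nrow(got), n_peaks)
})

test_that("distance filtering keeps links within the cutoff", {
  link <- tibble::tibble(chrom = "chr1", start = 0, end = 10,
                         gene_id = "g", tss_distance = c(0, -10000, 10001, 500))
  kept <- distance_filter(link)
  expect_equal(kept$tss_distance, c(0, -10000, 500))
  set.seed(52)
  d <- sample(-30000:30000, 300)
  link2 <- tibble::tibble(chrom = "chr1", start = 0, end = 10,
                          gene_id = "g", tss_distance = d)
  expect_equal(nrow(distance_filter(link2, 10000)), sum(abs(d) <= 10000))
})

test_that("category expression test handles degenerate paired inputs", {
  expr <- tibble::tibble(feature = paste0("g", 1:6),
                         WT = c(1, 2, 3, 4, 5, 6),
                         DKO = c(1, 2, 3, 4, 5, 6))
  link <- tibble::tibble(gene_id = paste0("g", 1:6), category = "cat")
  res <- category_expression_test(link, expr, list(c("WT", "DKO")))
  expect_equal(res$pvalue, 1)
  expect_equal(res$median_diff, 0)

  ## a uniform paired shift drives the signed-rank statistic to its extreme
  expr2 <- dplyr::mutate(expr, DKO = WT + 2)
  res2 <- category_expression_test(link, expr2, list(c("WT", "DKO")))
  expect_equal(res2$statistic, 6 * 7 / 2)  # all positive ranks

  ## small categories are skipped with a warning
  link3 <- tibble::tibble(gene_id = paste0("g", 1:3), category = "tiny")
  expect_warning(category_expression_test(link3, expr, list(c("WT", "DKO"))),
                 "skipped")
})

test_that("permutation control test matches complete enumeration on the toy set", {
  all_vals <- c(1, 2, 3, 4)
  res <- permutation_control_test(c(3, 4, 1), all_vals, n_perm = 1000)
  ## exhaustive: C(4,3) = 4 draws
  expect_true(res$exhaustive)

  u_oracle <- function(x, y) {
    r <- rank(c(x, y)); sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  enumerate_p <- function(state, all) {
    n1 <- length(state); centre <- n1 * length(all) / 2
    u_obs <- u_oracle(state, all)
    draws <- combn(length(all), n1)
    u_all <- apply(draws, 2, function(i) u_oracle(all[i], all))
    mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)
  }
  for (state in list(c(3, 4, 1), c(1, 2, 4), c(2, 3, 4))) {
    got <- suppressWarnings(
      permutation_control_test(state, all_vals, n_perm = 1000))
    expect_equal(got$pvalue, enumerate_p(state, all_vals))
  }

  ## two-gene state set over the 4-gene pool, checked by hand: the state
  ## {3,4} is as extreme as {1,2} and no other draw is, so p = 2/6
  got34 <- permutation_control_test(c(3, 4), all_vals, n_perm = 1000)
  expect_equal(got34$pvalue, 2 / 6)
  expect_equal(got34$pvalue, enumerate_p(c(3, 4), all_vals))
  expect_error(permutation_control_test(3, all_vals), "at least 2")
})

test_that("permutation control test is rank-based and p = 1 for a central set", {
  set.seed(53)
  all_vals <- rnorm(60)
  state <- sample(all_vals, 10)
  a <- permutation_control_test(state, all_vals, n_perm = 300, seed = 2)
  b <- permutation_control_test(state + 100, all_vals + 100, n_perm = 300, seed = 2)
  expect_equal(a$pvalue, b$pvalue)

  ## a state set whose U sits exactly at the null centre has p = 1
  res <- permutation_control_test(c(2, 3.5, 5), c(2, 3.5, 5, 2, 3.5, 5),
                                  n_perm = 1000)
  expect_equal(res$pvalue, 1)

  expect_warning(permutation_control_test(c(1, 2, 3), c(1, 2, 3, 4), n_perm = 50),
                 "coarse")
  expect_error(permutation_control_test(c(1, 99, 2), c(1, 2, 3, 4)),
               "subset")
})

test_that("enhancer burden regression recovers an exact linear relation", {
  tbl <- tibble::tibble(n_dependent = rep(0:4, each = 2))
  tbl$log2fc <- -0.5 * tbl$n_dependent + 0.2
  fit <- suppressWarnings(enhancer_burden_fit(tbl))
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate[td$term == "(Intercept)"], 0.2, tolerance = 1e-12)
  expect_error(enhancer_burden_fit(tbl[1:5, ]), "10")
  flat <- tibble::tibble(n_dependent = rep(1, 12), log2fc = rnorm(12))
  expect_error(enhancer_burden_fit(flat), "variance")
})

test_that("burden slope is negative under coupling and null without", {
  set.seed(54)
  n <- 300
  counts <- rpois(n, 2)
  coupled <- tibble::tibble(n_dependent = counts,
                            log2fc = -0.6 * counts + rnorm(n, 0, 0.4))
  fit1 <- enhancer_burden_fit(coupled)
  expect_lt(fit1$conf_high, 0)
  null <- tibble::tibble(n_dependent = counts, log2fc = rnorm(n, 0, 0.4))
  fit0 <- enhancer_burden_fit(null)
  expect_true(fit0$conf_low <= 0 && 0 <= fit0$conf_high)
})

test_that("loss binning assigns bins by percentage and tests against 0%", {
  tbl <- tibble::tibble(
    pct_dependent = c(0, 0, 0, 50, 50, 50, 100, 100, 100, 40),
    log2fc = c(0, 0.1, -0.1, -1, -1.2, -0.9, -2, -2.2, -1.8, -1.1)
  )
  out <- enhancer_loss_binning(tbl)
  expect_equal(as.character(out$bin[out$n == 4][1]), "(25,50]")
  expect_true(is.na(out$pvalue[out$bin == "0"]))
  meds <- out$median[match(c("0", "(25,50]", "(75,100]"), as.character(out$bin))]
  expect_true(all(diff(meds) < 0))
  ## a gene with 2 dependent of 4 enhancers lands in (25,50]
  expect_equal(as.character(out$bin[out$median == -1.05]), "(25,50]")
})

test_that("gene-centric acetylation summaries separate dependency classes", {
  gene_classes <- tibble::tibble(feature = c("g1", "g2"),
                                 gene_class = "formative",
                                 gene_dependency = c("dependent", "independent"))
  linkage <- tibble::tibble(enhancer_id = c("e1", "e2", "e3"),
                            gene_id = c("g1", "g1", "g2"))
  k27 <- tibble::tibble(enhancer_id = c("e1", "e2", "e3"),
                        lfc_wt = c(2, 2, 2), lfc_dko = c(-0.5, -0.2, 1.9))
  res <- gene_centric_acetylation_fc(gene_classes, linkage, k27)
  expect_equal(nrow(res$values), 6L)
  s <- res$summary
  expect_lt(s$median_dependent[s$genotype == "DKO"],
            s$median_independent[s$genotype == "DKO"])
  ## equal densities give zero fold change
  k27_flat <- dplyr::mutate(k27, lfc_wt = 0, lfc_dko = 0)
  res2 <- gene_centric_acetylation_fc(gene_classes, linkage, k27_flat)
  expect_true(all(res2$values$lfc == 0))
})
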