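#' Configuration for the synthetic enhancer-landscape generator
#'
#' Builds the parameter set for a miniature two-state (naive/formative),
#' two-genotype (WT/DKO) enhancer landscape with planted ground truth. The
#' defaults define the package's reference simulation: a desk-scale genome
#' whose category composition mirrors the landscape observed in mouse ESC
#' differentiation (dynamics heavily dominated by shared peaks; all dynamic
#' H3K4me1 dependent on MLL3/4, most shared H3K4me1 independent; mixed
#' H3K27ac dependency).
#'
#' @param seed Integer seed; every simulation function derives its RNG
#'   stream from this.
#' @param n_chroms,chrom_length Number of chromosomes and length of each (bp).
#' @param n_enhancers,n_genes Number of planted enhancers and genes.
#' @param prop_dynamics Named proportions (naive/formative/shared), sum 1.
#' @param prop_dependent Per-mark named vectors: probability that an
#'   enhancer of each dynamics class is MLL3/4-dependent for that mark.
#' @param p_k27,p_atac Probability an enhancer carries H3K27ac / ATAC.
#' @param p_coupled Probability an enhancer is coupled to its nearest gene.
#' @param enrichment_log2 Peak enrichment over background, log2 (on state).
#' @param lfc_dynamics Planted log2 fold change between on and off states.
#' @param lfc_dependency Planted DKO/WT log2 fold change at dependent sites.
#' @param nb_dispersion NB dispersion of fragment counts at peaks.
#' @param depth Sequencing depth per chromatin sample (fragments in peaks).
#' @param background_rate Background coverage rate (reads per bp).
#' @param track_bin Resolution of simulated signal tracks (bp).
#' @param enhancer_width Planted enhancer width (bp, bin-aligned).
#' @param gene_width_range Range of simulated gene widths (bp).
#' @param coupling Coupling strength kappa in `[0, 1]`: the fraction of a
#'   gene's DKO/WT log2 fold change explained by the acetylation change of
#'   its coupled enhancers. `0` plants fully decoupled chromatin and
#'   transcription; `1` plants full coupling.
#' @param expr_base_log2 Mean and sd of per-gene baseline log2 expression.
#' @param expr_lfc_noise_sd SD of the per-gene genotype log2FC noise.
#' @param expr_dispersion NB dispersion of expression counts.
#' @param n_reps Replicates per condition-by-genotype sample class.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 5e6,
                       n_enhancers = 2000L, n_genes = 1000L,
                       prop_dynamics = c(naive = 0.11, formative = 0.11, shared = 0.78),
                       prop_dependent = list(
                         H3K4me1 = c(naive = 1, formative = 1, shared = 0.15),
                         H3K27ac = c(naive = 0.57, formative = 0.62, shared = 0.22)
                       ),
                       p_k27 = 0.5, p_atac = 0.8, p_coupled = 1,
                       enrichment_log2 = 8, lfc_dynamics = 2, lfc_dependency = -2,
                       nb_dispersion = 0.02, depth = 1e6,
                       background_rate = 0.0004, track_bin = 200L,
                       enhancer_width = 1000L, gene_width_range = c(1000L, 4000L),
                       coupling = 0,
                       expr_base_log2 = c(mean = 6.5, sd = 1.5),
                       expr_lfc_noise_sd = 0.25, expr_dispersion = 0.05,
                       n_reps = 2L) {
  if (abs(sum(prop_dynamics) - 1) > 1e-8) abort("prop_dynamics must sum to 1")
  if (coupling < 0 || coupling > 1) abort("coupling (kappa) must be in [0, 1]")
  if (depth <= 0) abort("depth must be positive")
  if (any(unlist(prop_dependent) < 0) || any(unlist(prop_dependent) > 1)) {
    abort("prop_dependent entries must be probabilities")
  }
  structure(
    list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
         chrom_length = chrom_length, n_enhancers = as.integer(n_enhancers),
         n_genes = as.integer(n_genes), prop_dynamics = prop_dynamics,
         prop_dependent = prop_dependent, p_k27 = p_k27, p_atac = p_atac,
         p_coupled = p_coupled, enrichment_log2 = enrichment_log2,
         lfc_dynamics = lfc_dynamics, lfc_dependency = lfc_dependency,
         nb_dispersion = nb_dispersion, depth = depth,
         background_rate = background_rate, track_bin = as.integer(track_bin),
         enhancer_width = as.integer(enhancer_width),
         gene_width_range = gene_width_range, coupling = coupling,
         expr_base_log2 = expr_base_log2, expr_lfc_noise_sd = expr_lfc_noise_sd,
         expr_dispersion = expr_dispersion, n_reps = as.integer(n_reps)),
    class = "sim_config"
  )
}

#' Sample metadata for a simulated experiment
#'
#' @param config A [sim_config()].
#' @return Tibble with `sample`, `condition`, `genotype`, `replicate`.
#' @export
sample_metadata <- function(config) {
  grid <- expand.grid(replicate = seq_len(config$n_reps),
                      condition = c("naive", "formative"),
                      genotype = c("WT", "DKO"),
                      stringsAsFactors = FALSE)
  tibble(
    sample = paste(grid$genotype, grid$condition, grid$replicate, sep = "_"),
    condition = grid$condition, genotype = grid$genotype,
    replicate = grid$replicate
  )
}

#' Generate ground-truth enhancers and gene models
#'
#' Places non-overlapping genes and non-overlapping, bin-aligned enhancers
#' on the synthetic genome, samples dynamics and per-mark dependency labels
#' from the configured proportions, and links every enhancer to its nearest
#' TSS (computed here by direct exhaustive search, so the linkage module can
#' be checked against the truth). Truth feature labels (Distal / Promoter /
#' Other) are derived from the planted geometry with a +/-1 kb promoter
#' window and the BED6 gene-body rule.
#'
#' @param config A [sim_config()].
#' @return A list with `enhancers` (truth tibble) and `genes` (gene models
#'   with strand-resolved `tss`).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))

  ## genes: slotted placement guarantees non-overlap
  gene_slot <- max(config$gene_width_range) + 2000
  slots_per_chrom_g <- floor(config$chrom_length / gene_slot)
  if (slots_per_chrom_g * config$n_chroms < config$n_genes) {
    abort("genome too small for requested gene count")
  }
  gslot <- sort(sample(slots_per_chrom_g * config$n_chroms, config$n_genes))
  gchrom <- chroms[(gslot - 1L) %/% slots_per_chrom_g + 1L]
  gslot_start <- ((gslot - 1L) %% slots_per_chrom_g) * gene_slot
  gwidth <- round(runif(config$n_genes, config$gene_width_range[1],
                        config$gene_width_range[2]))
  gstart <- gslot_start + round(runif(config$n_genes, 0, gene_slot - gwidth - 1))
  gstrand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes <- tibble(
    gene_id = sprintf("g%04d", seq_len(config$n_genes)),
    chrom = gchrom, start = gstart, end = gstart + gwidth,
    strand = gstrand,
    tss = ifelse(gstrand == "+", gstart, gstart + gwidth - 1)
  ) %>% arrange(.data$chrom, .data$start)
  genes$gene_id <- sprintf("g%04d", seq_len(config$n_genes))

  ## enhancers: slotted, bin-aligned, >=1 kb gaps
  enh_slot <- config$enhancer_width + 1000L
  slots_per_chrom <- floor(config$chrom_length / enh_slot)
  if (slots_per_chrom * config$n_chroms < config$n_enhancers) {
    abort("genome too small for requested enhancer count")
  }
  slot <- sort(sample(slots_per_chrom * config$n_chroms, config$n_enhancers))
  echrom <- chroms[(slot - 1L) %/% slots_per_chrom + 1L]
  slot_start <- ((slot - 1L) %% slots_per_chrom) * enh_slot
  offset <- floor(runif(config$n_enhancers, 0,
                        (enh_slot - config$enhancer_width) / config$track_bin)) *
    config$track_bin
  estart <- slot_start + offset
  estart <- (estart %/% config$track_bin) * config$track_bin

  dynamics <- sample(names(config$prop_dynamics), config$n_enhancers,
                     replace = TRUE, prob = config$prop_dynamics)
  dep_label <- function(mark) {
    p <- config$prop_dependent[[mark]][dynamics]
    ifelse(runif(config$n_enhancers) < p, "dependent", "independent")
  }
  enh <- tibble(
    enhancer_id = sprintf("enh%04d", seq_len(config$n_enhancers)),
    chrom = echrom, start = estart, end = estart + config$enhancer_width,
    dynamics = dynamics,
    dep_H3K4me1 = dep_label("H3K4me1"),
    dep_H3K27ac = dep_label("H3K27ac"),
    has_k27 = runif(config$n_enhancers) < config$p_k27,
    has_atac = runif(config$n_enhancers) < config$p_atac,
    coupled = runif(config$n_enhancers) < config$p_coupled
  )
  enh$dep_H3K27ac[!enh$has_k27] <- NA_character_

  ## nearest TSS by exhaustive per-chromosome search (truth linkage)
  mid <- (enh$start + enh$end) %/% 2
  nearest <- truth_nearest_gene(enh$chrom, mid, genes)
  enh$gene_id <- nearest$gene_id
  enh$tss_distance <- nearest$distance

  ## truth feature-class label from geometry
  enh$feature_class <- truth_feature_label(enh$chrom, mid, genes, window = 1000)

  list(enhancers = enh, genes = genes)
}

truth_nearest_gene <- function(chrom, mid, genes) {
  gene_id <- character(length(mid))
  distance <- rep(NA_real_, length(mid))
  for (ch in unique(chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(chrom == ch)
    if (length(gi) == 0L) { gene_id[pi] <- NA_character_; next }
    g <- genes[gi, ]
    for (p in pi) {
      d <- abs(mid[p] - g$tss)
      best <- which(d == min(d))
      if (length(best) > 1L) {
        best <- best[order(g$tss[best], g$gene_id[best])][1]
      }
      gene_id[p] <- g$gene_id[best]
      distance[p] <- mid[p] - g$tss[best]
    }
  }
  tibble(gene_id = gene_id, distance = distance)
}

truth_feature_label <- function(chrom, mid, genes, window = 1000) {
  out <- character(length(mid))
  for (i in seq_along(mid)) {
    g <- genes[genes$chrom == chrom[i], ]
    if (nrow(g) == 0L) { out[i] <- "Distal"; next }
    if (any(abs(mid[i] - g$tss) <= window)) {
      out[i] <- "Promoter"
    } else if (any(g$start <= mid[i] & mid[i] < g$end)) {
      out[i] <- "Other"
    } else {
      out[i] <- "Distal"
    }
  }
  out
}

## planted log2 enrichment over background for one sample class;
## -Inf where the mark is absent
expected_enrichment <- function(truth, config, mark, genotype, condition) {
  e <- rep(config$enrichment_log2, nrow(truth))
  on <- truth$dynamics == condition | truth$dynamics == "shared"
  e[!on] <- e[!on] - config$lfc_dynamics
  dep <- truth[[paste0("dep_", mark)]]
  if (genotype == "DKO") {
    is_dep <- !is.na(dep) & dep == "dependent"
    e[is_dep] <- e[is_dep] + config$lfc_dependency
  }
  if (mark == "H3K27ac") e[!truth$has_k27] <- -Inf
  if (mark == "ATAC") e[!truth$has_atac] <- -Inf
  e
}

#' Simulate CPM-scaled signal tracks
#'
#' One Poisson-sampled, piecewise-constant track per (mark, genotype,
#' condition) plus a background-only IgG control, at `track_bin` resolution.
#' The expected raw signal in a bin is `background_rate * track_bin`, times
#' `2^enrichment` inside an enhancer carrying the mark; tracks are then
#' scaled to counts-per-million. Zero bins are dropped (bedGraph gap
#' semantics).
#'
#' @param truth Output of [generate_truth()].
#' @param config The [sim_config()] used to generate it.
#' @param marks Marks to simulate tracks for.
#' @return Named list of track tibbles, e.g. `H3K4me1_WT_naive`, plus `IgG`.
#' @export
simulate_tracks <- function(truth, config, marks = c("H3K4me1", "H3K27ac")) {
  set.seed(config$seed + 1L)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  nbin <- floor(config$chrom_length / config$track_bin)
  bin_tbl <- tibble(
    chrom = rep(chroms, each = nbin),
    start = rep((seq_len(nbin) - 1L) * config$track_bin, config$n_chroms)
  )
  bin_tbl$end <- bin_tbl$start + config$track_bin
  bg_bin <- config$background_rate * config$track_bin

  ## map enhancer rows to their (fully contained) bins
  bins_per_enh <- config$enhancer_width %/% config$track_bin
  enh_bin_idx <- function(truth) {
    chrom_off <- (match(truth$chrom, chroms) - 1L) * nbin
    idx <- rep(chrom_off + truth$start %/% config$track_bin + 1L, each = bins_per_enh) +
      rep(seq_len(bins_per_enh) - 1L, times = nrow(truth))
    idx
  }
  idx <- enh_bin_idx(truth$enhancers)

  out <- list()
  totals <- numeric(0)
  for (mark in marks) {
    for (genotype in c("WT", "DKO")) {
      for (condition in c("naive", "formative")) {
        rate <- rep(bg_bin, nrow(bin_tbl))
        e <- expected_enrichment(truth$enhancers, config, mark, genotype, condition)
        mult <- rep(pmax(2^e, 1), each = bins_per_enh)
        rate[idx] <- bg_bin * mult
        val <- rpois(length(rate), rate)
        totals <- c(totals, sum(val))
        cpm <- val * (1e6 / sum(val))
        tr <- bin_tbl
        tr$value <- cpm
        out[[paste(mark, genotype, condition, sep = "_")]] <-
          tr[tr$value > 0, , drop = FALSE]
      }
    }
  }
  ## IgG is the same background process, scaled as a depth-matched control
  ## (per-read CPM weight equal to the mark tracks') so that its block AUCs
  ## live on the same scale as target background blocks
  val <- rpois(nrow(bin_tbl), bg_bin)
  tr <- bin_tbl
  tr$value <- val * (1e6 / mean(totals))
  out$IgG <- tr[tr$value > 0, , drop = FALSE]
  out
}

#' Simulate per-enhancer fragment counts
#'
#' Negative-binomial counts at planted enhancers carrying `mark`, for all
#' condition-by-genotype sample classes and replicates. Expected counts are
#' `depth * width * 2^enrichment / W`, with `W` a fixed all-sites reference
#' weight, so planted fold changes are exact on the raw count scale;
#' sample classes that lose signal (e.g. DKO at dependent sites) end up
#' with correspondingly smaller in-peak library sizes, which TMM
#' normalisation corrects downstream.
#'
#' @param truth Output of [generate_truth()].
#' @param config The matching [sim_config()].
#' @param mark Which mark's count matrix to generate.
#' @return A count tibble: `feature` plus one column per sample.
#' @export
simulate_counts <- function(truth, config, mark = "H3K4me1") {
  offset <- match(mark, c("H3K4me1", "H3K27ac", "ATAC"))
  set.seed(config$seed + 2L + offset)
  meta <- sample_metadata(config)
  enh <- truth$enhancers
  present <- if (mark == "H3K27ac") enh$has_k27 else
    if (mark == "ATAC") enh$has_atac else rep(TRUE, nrow(enh))
  enh <- enh[present, , drop = FALSE]
  width <- enh$end - enh$start
  w_ref <- sum(width * 2^config$enrichment_log2)
  cols <- lapply(seq_len(nrow(meta)), function(j) {
    e <- expected_enrichment(enh, config, mark, meta$genotype[j], meta$condition[j])
    w <- width * 2^e
    mu <- config$depth * w / w_ref
    rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  })
  names(cols) <- meta$sample
  as_tibble(c(list(feature = enh$enhancer_id), cols))
}

## planted H3K27ac log2FC (DKO/WT) for each enhancer in a given condition
planted_acetylation_lfc <- function(enh, config, condition) {
  e_wt <- expected_enrichment(enh, config, "H3K27ac", "WT", condition)
  e_dko <- expected_enrichment(enh, config, "H3K27ac", "DKO", condition)
  lfc <- e_dko - e_wt
  lfc[!is.finite(lfc)] <- 0
  lfc
}

#' Simulate gene expression counts with tunable chromatin coupling
#'
#' Per-gene baseline expression is log-normal; genes pick up a
#' condition effect from the dynamics of their coupled enhancers, and a
#' genotype (DKO/WT) effect equal to `kappa` times the mean planted
#' H3K27ac log2FC of their coupled enhancers in that condition, plus
#' per-gene noise. At `kappa = 0` expression is independent of enhancer
#' state; at `kappa = 1` a gene whose single coupled enhancer loses
#' acetylation at log2FC -2 is itself planted at log2FC -2.
#'
#' @param truth Output of [generate_truth()].
#' @param genes Gene models (from the same truth).
#' @param config The matching [sim_config()].
#' @return A count tibble: `feature` (gene id) plus one column per sample.
#' @export
simulate_expression <- function(truth, genes, config) {
  set.seed(config$seed + 7L)
  meta <- sample_metadata(config)
  enh <- truth$enhancers
  n <- nrow(genes)
  base <- rnorm(n, config$expr_base_log2[["mean"]], config$expr_base_log2[["sd"]])

  coupled <- enh[enh$coupled & !is.na(enh$gene_id), , drop = FALSE]
  dyn_eff <- c(naive = -config$lfc_dynamics, formative = config$lfc_dynamics,
               shared = 0)
  cond_effect <- vapply(genes$gene_id, function(g) {
    e <- coupled[coupled$gene_id == g, , drop = FALSE]
    if (nrow(e) == 0L) 0 else mean(dyn_eff[e$dynamics])
  }, numeric(1))

  geno_effect <- function(condition) {
    acet <- planted_acetylation_lfc(coupled, config, condition)
    eff <- vapply(genes$gene_id, function(g) {
      i <- which(coupled$gene_id == g & coupled$has_k27)
      if (length(i) == 0L) 0 else mean(acet[i])
    }, numeric(1))
    config$coupling * eff + rnorm(n, 0, config$expr_lfc_noise_sd)
  }
  geno_naive <- geno_effect("naive")
  geno_formative <- geno_effect("formative")

  cols <- lapply(seq_len(nrow(meta)), function(j) {
    l2 <- base +
      (meta$condition[j] == "formative") * cond_effect +
      (meta$genotype[j] == "DKO") *
        (if (meta$condition[j] == "naive") geno_naive else geno_formative)
    rnbinom(n, mu = 2^l2, size = 1 / config$expr_dispersion)
  })
  names(cols) <- meta$sample
  as_tibble(c(list(feature = genes$gene_id), cols))
}

#' Run the full synthetic generator
#'
#' @param config A [sim_config()].
#' @return A list: `config`, `truth` (enhancer tibble), `genes`, `tracks`,
#'   `counts` (per-mark list), `expression`, `meta`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  truth <- generate_truth(config)
  list(
    config = config,
    truth = truth$enhancers,
    genes = truth$genes,
    tracks = simulate_tracks(truth, config),
    counts = list(
      H3K4me1 = simulate_counts(truth, config, "H3K4me1"),
      H3K27ac = simulate_counts(truth, config, "H3K27ac")
    ),
    expression = simulate_expression(truth, truth$genes, config),
    meta = sample_metadata(config)
  )
}

#' Write a simulated experiment to disk
#'
#' Emits bedGraph tracks, a BED of true enhancers (truth labels packed into
#' the name field), BED6 gene models, the truth table and count matrices as
#' TSV. Output is deterministic given the config seed.
#'
#' @param sim Output of [simulate_experiment()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim$tracks)) {
    write_bedgraph(sim$tracks[[nm]], file.path(outdir, paste0(nm, ".bedgraph")))
  }
  enh <- sim$truth
  enh_bed <- tibble(chrom = enh$chrom, start = enh$start, end = enh$end,
                    name = paste(enh$enhancer_id, enh$dynamics,
                                 enh$dep_H3K4me1, sep = "|"))
  write_bed(enh_bed, file.path(outdir, "true_enhancers.bed"))
  atac <- enh[enh$has_atac, c("chrom", "start", "end", "enhancer_id")]
  names(atac)[4] <- "name"
  write_bed(atac, file.path(outdir, "atac_peaks.bed"))
  g <- sim$genes
  gene_bed <- tibble(chrom = g$chrom, start = g$start, end = g$end,
                     name = g$gene_id, score = 0, strand = g$strand)
  write_bed(gene_bed, file.path(outdir, "genes.bed"))
  utils::write.table(enh, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (mk in names(sim$counts)) {
    write_count_table(sim$counts[[mk]],
                      file.path(outdir, paste0("counts_", mk, ".tsv")))
  }
  write_count_table(sim$expression, file.path(outdir, "expression.tsv"))
  invisible(outdir)
}
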