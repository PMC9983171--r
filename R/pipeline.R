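#' Run the full enhancer analysis pipeline on a simulated experiment
#'
#' Chains the package end to end: peak calling against the IgG control and
#' union-peak construction (`features = "called"`), or direct
#' quantification at the planted enhancers (`features = "planted"`);
#' differential enrichment for the WT transition and for DKO/WT within
#' each state; dynamics, dependency, feature and joint-mark
#' classification; ATAC overlap filtering; nearest-TSS linkage;
#' differential expression and gene classes; and a combinatorial
#' chromatin-state segmentation with per-state expression tests.
#'
#' @param sim Output of [simulate_experiment()].
#' @param thresholds An [enh_thresholds()] list.
#' @param features Quantify at `"planted"` enhancers (counts keyed by
#'   ground-truth features) or at `"called"` union peaks from the
#'   simulated tracks.
#' @param state_condition Condition whose four tracks feed the
#'   chromatin-state segmentation.
#' @param n_perm,seed Permutation settings for the state expression test.
#' @return A list of intermediate and final tables; see the vignette for a
#'   walk-through.
#' @export
run_enhancer_pipeline <- function(sim, thresholds = enh_thresholds(),
                                  features = c("planted", "called"),
                                  state_condition = "formative",
                                  n_perm = 1000, seed = 1L) {
  features <- match.arg(features)
  meta <- sim$meta
  cls <- function(g, co) meta$sample[meta$genotype == g & meta$condition == co]

  quantify <- function(mark) {
    counts <- sim$counts[[mark]]
    present <- sim$truth$enhancer_id %in% counts$feature
    intervals <- sim$truth[present,
                           c("chrom", "start", "end", "enhancer_id")]
    if (features == "called") {
      pat <- paste0("^", mark, "_")
      trk <- sim$tracks[grepl(pat, names(sim$tracks))]
      sets <- lapply(trk, call_peaks, control = sim$tracks$IgG)
      peaks <- union_peaks(sets)
      peaks$peak_id <- sprintf("%s_peak%05d", mark, seq_len(nrow(peaks)))
      hits <- GenomicRanges::findOverlaps(as_granges(intervals), as_granges(peaks))
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ## aggregate planted-enhancer fragment counts onto their union peak
      map <- tibble(feature = intervals$enhancer_id[qi], peak_id = peaks$peak_id[si])
      counts <- counts %>%
        inner_join(map, by = "feature") %>%
        group_by(.data$peak_id) %>%
        summarise(across(all_of(meta$sample), sum), .groups = "drop") %>%
        rename(feature = "peak_id")
      intervals <- peaks %>%
        filter(.data$peak_id %in% counts$feature) %>%
        select("chrom", "start", "end", feature = "peak_id")
      counts <- counts[match(intervals$feature, counts$feature), ]
    } else {
      intervals <- rename(intervals, feature = "enhancer_id")
    }
    list(counts = counts, intervals = intervals)
  }

  analyse_mark <- function(q) {
    nf <- tmm_factors(q$counts)
    dyn <- differential_test(q$counts, cls("WT", "naive"), cls("WT", "formative"),
                             norm_factors = nf)
    dep_n <- differential_test(q$counts, cls("WT", "naive"), cls("DKO", "naive"),
                               norm_factors = nf)
    dep_f <- differential_test(q$counts, cls("WT", "formative"),
                               cls("DKO", "formative"), norm_factors = nf)
    tab <- q$intervals %>%
      left_join(tidy(categorize_dynamics(dyn, thresholds)), by = "feature") %>%
      mutate(
        lfc_dko_naive = dep_n$log2fc[match(.data$feature, dep_n$feature)],
        lfc_dko_formative = dep_f$log2fc[match(.data$feature, dep_f$feature)],
        dependency = categorize_dependency(.data$lfc_dko_naive,
                                           .data$lfc_dko_formative, thresholds)
      )
    tab <- annotate_features(tab, sim$genes, thresholds = thresholds)
    list(table = tab, dyn = dyn, dep_naive = dep_n, dep_formative = dep_f)
  }

  k4q <- quantify("H3K4me1")
  k27q <- quantify("H3K27ac")
  k4 <- analyse_mark(k4q)
  k27 <- analyse_mark(k27q)

  atac <- sim$truth[sim$truth$has_atac, c("chrom", "start", "end")]
  k27_atac <- overlap_filter(k27$table, atac, frac = thresholds$overlap_frac)
  k4_joint <- joint_mark_categories(k4$table, k27_atac)
  linkage <- nearest_tss(k4_joint, sim$genes)

  ## expression
  expr_nf <- tmm_factors(sim$expression)
  wt_dge <- differential_test(sim$expression, cls("WT", "naive"),
                              cls("WT", "formative"), norm_factors = expr_nf)
  dko_n_dge <- differential_test(sim$expression, cls("WT", "naive"),
                                 cls("DKO", "naive"), norm_factors = expr_nf)
  dko_f_dge <- differential_test(sim$expression, cls("WT", "formative"),
                                 cls("DKO", "formative"), norm_factors = expr_nf)
  gene_classes <- classify_genes(wt_dge, dko_n_dge, dko_f_dge, thresholds)
  expr_classes <- expression_log2cpm(sim$expression, meta)

  ## chromatin states for one condition
  track_names <- paste(rep(c("H3K4me1", "H3K27ac"), each = 2),
                       c("WT", "DKO"), state_condition, sep = "_")
  bmat <- binarize_tracks(sim$tracks[track_names],
                          bin_width = sim$config$track_bin)
  seg <- combinatorial_states(bmat)
  state_dge <- if (state_condition == "formative") dko_f_dge else dko_n_dge
  state_tests <- state_expression_test(
    seg[, c("chrom", "start", "end", "state")],
    atac, sim$genes,
    tibble(feature = state_dge$feature, value = state_dge$log2fc),
    emissions = state_emission_patterns(track_names),
    thresholds = thresholds, n_perm = n_perm, seed = seed
  )

  list(
    k4 = k4, k27 = k27, k27_atac = k27_atac, linkage = linkage,
    wt_dge = wt_dge, dko_naive_dge = dko_n_dge, dko_formative_dge = dko_f_dge,
    gene_classes = gene_classes, expr_log2cpm = expr_classes,
    segmentation = seg, state_tests = state_tests,
    thresholds = thresholds
  )
}
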