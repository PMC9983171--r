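#' Classification thresholds
#'
#' The cutoffs of the enhancer category scheme. Dynamic peaks: FDR <
#' `fdr_dyn` and |log2FC| > `lfc_dyn`; shared peaks: FDR > `fdr_shared`
#' and |log2FC| < `lfc_shared`. Dependency: dependent when either state's
#' DKO/WT log2FC < `dep_lfc`; independent when both > `indep_lfc`;
#' intermediate otherwise. `overlap_frac` is the required fraction of an
#' ATAC peak covered; `promoter_window_bp` is the TSS window for the
#' Promoter feature class.
#'
#' @param fdr_dyn,lfc_dyn Significance and fold-change cutoffs for dynamic
#'   (naive/formative) peaks.
#' @param fdr_shared,lfc_shared Cutoffs bounding shared (unchanged) peaks.
#' @param dep_lfc,indep_lfc Dependent / independent log2FC cutoffs
#'   (`dep_lfc < indep_lfc <= 0`).
#' @param overlap_frac Required overlap fraction for ATAC intersection.
#' @param promoter_window_bp Promoter window around the TSS (bp).
#' @return A named list of thresholds.
#' @export
enh_thresholds <- function(fdr_dyn = 0.05, lfc_dyn = 1,
                           fdr_shared = 0.1, lfc_shared = 0.7,
                           dep_lfc = -1, indep_lfc = -0.7,
                           overlap_frac = 0.75, promoter_window_bp = 1000) {
  if (!(dep_lfc < indep_lfc && indep_lfc <= 0)) {
    abort("need dep_lfc < indep_lfc <= 0")
  }
  if (overlap_frac <= 0 || overlap_frac > 1) abort("overlap_frac must be in (0, 1]")
  list(fdr_dyn = fdr_dyn, lfc_dyn = lfc_dyn, fdr_shared = fdr_shared,
       lfc_shared = lfc_shared, dep_lfc = dep_lfc, indep_lfc = indep_lfc,
       overlap_frac = overlap_frac, promoter_window_bp = promoter_window_bp)
}

#' Peak dynamics labels from a differential result
#'
#' Labels each peak by its behaviour in the WT formative-vs-naive
#' comparison: `formative` (significant gain), `naive` (significant loss),
#' `shared` (confidently unchanged: FDR above `fdr_shared` and small fold
#' change), `unclassified` otherwise.
#'
#' @param diff An `enh_diff` tibble (formative over naive).
#' @param thresholds An [enh_thresholds()] list.
#' @return `diff` with a `dynamics` column appended.
#' @export
categorize_dynamics <- function(diff, thresholds = enh_thresholds()) {
  t <- thresholds
  mutate(diff, dynamics = case_when(
    .data$fdr < t$fdr_dyn & .data$log2fc > t$lfc_dyn ~ "formative",
    .data$fdr < t$fdr_dyn & .data$log2fc < -t$lfc_dyn ~ "naive",
    .data$fdr > t$fdr_shared & abs(.data$log2fc) < t$lfc_shared ~ "shared",
    TRUE ~ "unclassified"
  ))
}

#' MLL3/4 dependency labels from per-state DKO/WT fold changes
#'
#' `dependent` when the mark drops below `dep_lfc` in either state,
#' `independent` when it stays above `indep_lfc` in both, `intermediate`
#' in between.
#'
#' @param lfc_naive,lfc_formative DKO/WT log2 fold changes per state.
#' @param thresholds An [enh_thresholds()] list.
#' @return Character vector of dependency labels.
#' @export
categorize_dependency <- function(lfc_naive, lfc_formative,
                                  thresholds = enh_thresholds()) {
  t <- thresholds
  case_when(
    lfc_naive < t$dep_lfc | lfc_formative < t$dep_lfc ~ "dependent",
    lfc_naive > t$indep_lfc & lfc_formative > t$indep_lfc ~ "independent",
    TRUE ~ "intermediate"
  )
}

#' Genomic feature class of peaks
#'
#' Classifies each peak by its midpoint: `Promoter` within the promoter
#' window of any TSS; otherwise `Distal` when intergenic (or intronic,
#' when exon structure is provided); otherwise `Other` (gene-body overlap
#' with BED6-only genes, or exonic overlap with structure).
#'
#' @param peaks Interval tibble.
#' @param genes Gene models with `tss` (see [generate_truth()] or BED6
#'   input with strand, from which `tss` is derived).
#' @param exons Optional exon interval tibble; introns then count as Distal.
#' @param thresholds An [enh_thresholds()] list.
#' @return `peaks` with a `feature_class` column appended.
#' @export
annotate_features <- function(peaks, genes, exons = NULL,
                              thresholds = enh_thresholds()) {
  if (is.null(genes$tss)) {
    if (is.null(genes$strand)) abort("genes need a `tss` or a `strand` column")
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  }
  mid <- (peaks$start + peaks$end) %/% 2
  w <- thresholds$promoter_window_bp

  mid_gr <- GenomicRanges::GRanges(peaks$chrom,
                                   IRanges::IRanges(mid + 1L, mid + 1L))
  prom_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(pmax(genes$tss - w, 0) + 1L,
                                                     genes$tss + w + 1L))
  is_prom <- IRanges::overlapsAny(mid_gr, prom_gr)
  body_gr <- as_granges(genes)
  in_body <- IRanges::overlapsAny(mid_gr, body_gr)
  if (!is.null(exons)) {
    in_exon <- IRanges::overlapsAny(mid_gr, as_granges(exons))
    fc <- ifelse(is_prom, "Promoter",
                 ifelse(in_body & in_exon, "Other", "Distal"))
  } else {
    fc <- ifelse(is_prom, "Promoter", ifelse(in_body, "Other", "Distal"))
  }
  mutate(peaks, feature_class = fc)
}

#' Filter peaks by fractional overlap with a second set
#'
#' Keeps `a` peaks having at least one `b` peak whose overlap covers at
#' least `frac` of the `b` peak (fraction measured on `b` by default, the
#' ATAC-peak convention; set `on = "a"` for a fraction-of-a sensitivity
#' variant).
#'
#' @param a,b Interval tibbles.
#' @param frac Required overlap fraction.
#' @param on Which peak the fraction is measured on (`"b"` or `"a"`).
#' @return The qualifying subset of `a` (row order preserved).
#' @export
overlap_filter <- function(a, b, frac = 0.75, on = c("b", "a")) {
  on <- match.arg(on)
  if (nrow(a) == 0L || nrow(b) == 0L) return(a[integer(0), , drop = FALSE])
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b))
  ai <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  denom <- if (on == "b") b$end[bi] - b$start[bi] else a$end[ai] - a$start[ai]
  keep <- sort(unique(ai[ov >= frac * denom]))
  a[keep, , drop = FALSE]
}

#' Joint H3K4me1-by-H3K27ac categories
#'
#' Labels each H3K4me1 peak by the behaviour of co-located H3K27ac:
#' `gain` (overlapping formative H3K27ac), `lose` (naive), `maintain`
#' (shared or not significantly changing), `never` (no overlapping
#' H3K27ac peak). Co-location is any overlap (>= 1 bp); when several
#' H3K27ac peaks overlap, the largest overlap wins.
#'
#' @param k4 H3K4me1 peak tibble (intervals; extra columns carried through).
#' @param k27 H3K27ac peak tibble with a `dynamics` column
#'   (from [categorize_dynamics()]).
#' @return `k4` with a `joint` column appended.
#' @export
joint_mark_categories <- function(k4, k27) {
  joint <- rep("never", nrow(k4))
  if (nrow(k27) > 0L && nrow(k4) > 0L) {
    hits <- GenomicRanges::findOverlaps(as_granges(k4), as_granges(k27))
    if (length(hits) > 0L) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ov <- pmin(k4$end[qi], k27$end[si]) - pmax(k4$start[qi], k27$start[si])
      ord <- order(qi, -ov)
      best <- !duplicated(qi[ord])
      qi_b <- qi[ord][best]; si_b <- si[ord][best]
      map <- c(formative = "gain", naive = "lose", shared = "maintain",
               unclassified = "maintain")
      joint[qi_b] <- unname(map[k27$dynamics[si_b]])
    }
  }
  mutate(k4, joint = joint)
}

#' Gene dependency classes from differential expression results
#'
#' Classifies genes as `formative` (significant WT gain in the transition)
#' or `naive` (significant WT loss), then splits each into MLL3/4
#' `dependent` vs `independent`: a formative gene is dependent when it is
#' also significantly down in DKO formative cells and shows no preexisting
#' naive expression defect (naive DKO/WT log2CPM fold change above
#' `dep_lfc`); a naive gene is dependent when significantly down in DKO
#' naive cells.
#'
#' @param wt_dge `enh_diff` for WT formative over naive expression.
#' @param dko_naive_dge,dko_formative_dge `enh_diff` for DKO over WT within
#'   each state.
#' @param thresholds An [enh_thresholds()] list (`fdr_dyn`/`lfc_dyn` reused
#'   as the DGE significance cutoffs; `dep_lfc` as the preexisting-defect
#'   bound).
#' @return Tibble: `feature`, `gene_class` in {formative, naive, none},
#'   `gene_dependency` in {dependent, independent} (NA for `none`).
#' @export
classify_genes <- function(wt_dge, dko_naive_dge, dko_formative_dge,
                           thresholds = enh_thresholds()) {
  t <- thresholds
  x <- wt_dge %>%
    select("feature", wt_lfc = "log2fc", wt_fdr = "fdr") %>%
    left_join(select(dko_naive_dge, "feature", dko_n_lfc = "log2fc",
                     dko_n_fdr = "fdr"), by = "feature") %>%
    left_join(select(dko_formative_dge, "feature", dko_f_lfc = "log2fc",
                     dko_f_fdr = "fdr"), by = "feature")
  x %>%
    mutate(
      gene_class = case_when(
        .data$wt_fdr < t$fdr_dyn & .data$wt_lfc > t$lfc_dyn ~ "formative",
        .data$wt_fdr < t$fdr_dyn & .data$wt_lfc < -t$lfc_dyn ~ "naive",
        TRUE ~ "none"
      ),
      gene_dependency = case_when(
        .data$gene_class == "formative" &
          .data$dko_f_fdr < t$fdr_dyn & .data$dko_f_lfc < 0 &
          .data$dko_n_lfc > t$dep_lfc ~ "dependent",
        .data$gene_class == "naive" &
          .data$dko_n_fdr < t$fdr_dyn & .data$dko_n_lfc < 0 ~ "dependent",
        .data$gene_class == "none" ~ NA_character_,
        TRUE ~ "independent"
      )
    ) %>%
    select("feature", "gene_class", "gene_dependency")
}
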