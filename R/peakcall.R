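#' Contiguous signal blocks of a track
#'
#' The sparse-enrichment primitive: maximal runs of strictly positive
#' signal, with total area (`auc` = sum of value times width), maximum
#' height and summit position. Adjacent blocks separated by at least one
#' zero base stay separate (no merging across gaps).
#'
#' @param track A track tibble (`chrom`, `start`, `end`, `value`).
#' @return Tibble of blocks: `chrom`, `start`, `end`, `auc`, `max_value`,
#'   `summit`.
#' @export
signal_blocks <- function(track) {
  x <- track[track$value > 0, , drop = FALSE]
  if (nrow(x) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  auc = numeric(), max_value = numeric(), summit = numeric()))
  }
  x <- arrange(x, .data$chrom, .data$start)
  new_run <- c(TRUE, x$chrom[-1L] != x$chrom[-nrow(x)] |
                 x$start[-1L] != x$end[-nrow(x)])
  x$run <- cumsum(new_run)
  x %>%
    group_by(.data$run) %>%
    summarise(
      chrom = first(.data$chrom),
      auc = sum(.data$value * (.data$end - .data$start)),
      max_value = max(.data$value),
      summit = .data$start[which.max(.data$value)][1],
      block_start = min(.data$start),
      block_end = max(.data$end),
      .groups = "drop"
    ) %>%
    mutate(start = .data$block_start, end = .data$block_end) %>%
    select("chrom", "start", "end", "auc", "max_value", "summit") %>%
    arrange(.data$chrom, .data$start)
}

#' Call peaks by sparse-enrichment AUC thresholding
#'
#' SEACR-style peak calling on CPM-scaled tracks: candidate blocks are runs
#' of positive target signal; in `control` mode a block is retained when its
#' AUC strictly exceeds the empirical `1 - alpha` quantile (type 7) of the
#' control (IgG) block AUCs; in `top_fraction` mode the top `top_fraction`
#' of target blocks by AUC are retained. The called set is unchanged when
#' target and control are both scaled by the same constant.
#'
#' @param target Target track tibble.
#' @param control IgG control track (control mode).
#' @param top_fraction Fraction of blocks to keep (top-fraction mode).
#'   Exactly one of `control` / `top_fraction` must be given.
#' @param alpha Control-quantile threshold (default 0.05).
#' @return A peak tibble (blocks retained), sorted, with attributes
#'   `mode`, `alpha`/`top_fraction` and `threshold`.
#' @export
call_peaks <- function(target, control = NULL, top_fraction = NULL,
                       alpha = 0.05) {
  if (is.null(control) == is.null(top_fraction)) {
    abort("provide exactly one of `control` or `top_fraction`")
  }
  blocks <- signal_blocks(target)
  if (!is.null(control)) {
    cb <- signal_blocks(control)
    if (nrow(cb) == 0L) {
      abort("control track has no signal blocks; use `top_fraction` mode instead")
    }
    thr <- unname(quantile(cb$auc, 1 - alpha, type = 7))
    out <- blocks[blocks$auc > thr, , drop = FALSE]
    attr(out, "mode") <- "control"
    attr(out, "alpha") <- alpha
    attr(out, "threshold") <- thr
  } else {
    if (top_fraction <= 0 || top_fraction > 1) abort("top_fraction must be in (0, 1]")
    n_keep <- floor(top_fraction * nrow(blocks))
    ord <- order(-blocks$auc, blocks$chrom, blocks$start)
    out <- blocks[sort(ord[seq_len(n_keep)]), , drop = FALSE]
    attr(out, "mode") <- "top_fraction"
    attr(out, "top_fraction") <- top_fraction
    attr(out, "threshold") <- if (n_keep > 0) min(out$auc) else Inf
  }
  arrange(out, .data$chrom, .data$start)
}
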