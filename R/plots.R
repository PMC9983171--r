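#' MA-style plot of a differential result
#'
#' Mean abundance against log2 fold change, significant features
#' highlighted.
#'
#' @param object An `enh_diff` tibble.
#' @param fdr_cut,lfc_cut Highlight cutoffs.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enh_diff <- function(object, fdr_cut = 0.05, lfc_cut = 1, ...) {
  df <- mutate(tidy(object),
               significant = .data$fdr < fdr_cut & abs(.data$log2fc) > lfc_cut)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$mean_abundance + 1),
                                   y = .data$log2fc,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "black")) +
    ggplot2::labs(x = "log2 mean abundance", y = "log2 fold change") +
    ggplot2::theme_classic()
}

#' Scatter and fit line for an enhancer-burden regression
#'
#' @param object A `burden_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.burden_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$n_dependent, y = .data$log2fc)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "blue") +
    ggplot2::labs(x = "MLL3/4-dependent enhancers per gene",
                  y = "expression log2FC (DKO/WT)") +
    ggplot2::theme_classic()
}

#' Emission heatmap of a fitted HMM
#'
#' @param object A `bernoulli_hmm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bernoulli_hmm <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$track, y = factor(.data$state),
                               fill = .data$emission)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "state", fill = "P(mark)") +
    ggplot2::theme_classic()
}

#' Category composition bar plot
#'
#' Stacked composition of dependency labels within each dynamics class.
#'
#' @param categories Tibble with `dynamics` and `dependency` columns.
#' @return A ggplot object.
#' @export
plot_category_composition <- function(categories) {
  df <- categories %>%
    filter(.data$dynamics != "unclassified") %>%
    dplyr::count(.data$dynamics, .data$dependency)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dynamics, y = .data$n,
                                   fill = .data$dependency)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "fraction of peaks", fill = NULL) +
    ggplot2::theme_classic()
}

#' Binned enhancer-loss boxplot summary
#'
#' @param binned Output of [enhancer_loss_binning()].
#' @return A ggplot object (median and quartiles per bin).
#' @export
plot_loss_bins <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$bin, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75)) +
    ggplot2::labs(x = "% of linked enhancers MLL3/4-dependent",
                  y = "gene expression log2FC (DKO/WT)") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
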