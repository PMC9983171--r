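#' Tidy a differential test result
#'
#' @param x An `enh_diff` tibble.
#' @param ... Unused.
#' @return The underlying tibble (one row per feature).
#' @export
tidy.enh_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "enh_diff")
  out
}

#' One-row summary of a differential test result
#'
#' @param x An `enh_diff` tibble.
#' @param fdr_cut,lfc_cut Significance cutoffs for the counts.
#' @param ... Unused.
#' @return Tibble: feature counts up/down/total at the cutoffs, method.
#' @export
glance.enh_diff <- function(x, fdr_cut = 0.05, lfc_cut = 1, ...) {
  tibble(
    n_features = nrow(x),
    n_up = sum(x$fdr < fdr_cut & x$log2fc > lfc_cut),
    n_down = sum(x$fdr < fdr_cut & x$log2fc < -lfc_cut),
    method = attr(x, "method") %||% NA_character_
  )
}

#' Tidy an enhancer-burden fit
#'
#' @param x A `burden_fit`.
#' @param ... Unused.
#' @return One row per model term with estimate, std.error, statistic,
#'   p.value, conf.low, conf.high.
#' @export
tidy.burden_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  ci <- confint(x$model)
  tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"]),
    conf.low = unname(ci[, 1]),
    conf.high = unname(ci[, 2])
  )
}

#' One-row summary of an enhancer-burden fit
#'
#' @param x A `burden_fit`.
#' @param ... Unused.
#' @return Tibble with slope, its CI, r.squared and gene count.
#' @export
glance.burden_fit <- function(x, ...) {
  tibble(
    slope = x$slope, conf.low = x$conf_low, conf.high = x$conf_high,
    r.squared = summary(x$model)$r.squared, n_genes = nrow(x$data)
  )
}

#' Tidy a fitted Bernoulli-emission HMM
#'
#' @param x A `bernoulli_hmm`.
#' @param ... Unused.
#' @return Long tibble of emission probabilities: `state`, `track`,
#'   `emission`.
#' @export
tidy.bernoulli_hmm <- function(x, ...) {
  as_tibble(x$E) %>%
    mutate(state = row_number()) %>%
    tidyr::pivot_longer(cols = all_of(x$tracks), names_to = "track",
                        values_to = "emission") %>%
    select("state", "track", "emission")
}

#' One-row summary of a fitted HMM
#'
#' @param x A `bernoulli_hmm`.
#' @param ... Unused.
#' @return Tibble: states, tracks, final log-likelihood, iterations,
#'   convergence flag.
#' @export
glance.bernoulli_hmm <- function(x, ...) {
  tibble(
    n_states = x$n_states, n_tracks = length(x$tracks),
    loglik = tail(x$loglik, 1), n_iter = length(x$loglik),
    converged = x$converged
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
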