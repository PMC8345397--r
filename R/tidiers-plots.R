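#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a logistic fit
#'
#' @param x A `crcprs_logit` object.
#' @param ... Unused.
#' @return Tibble of per-term estimates, Wald SEs, ORs, CIs and p-values.
#' @method tidy crcprs_logit
#' @export
tidy.crcprs_logit <- function(x, ...) {
  x$coefficients
}

#' One-row model summary of a logistic fit
#'
#' @param x A `crcprs_logit` object.
#' @param ... Unused.
#' @return Tibble: `n`, `log_likelihood`, `converged`, `df`.
#' @method glance crcprs_logit
#' @export
glance.crcprs_logit <- function(x, ...) {
  tibble::tibble(n = x$n, log_likelihood = x$log_likelihood,
                 converged = x$converged, df = nrow(x$coefficients))
}

#' Tidy an analysis report
#'
#' Stacks the report's result tables into one long tibble keyed by `block`.
#'
#' @param x A `crcprs_report`.
#' @param ... Unused.
#' @return Tibble with a `block` column (`group_stats`, `quantile_profile`,
#'   `highlow`, `decomposition`) and the block's columns.
#' @method tidy crcprs_report
#' @export
tidy.crcprs_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$group_stats, block = "group_stats"),
    dplyr::mutate(x$quantile_profile, block = "quantile_profile"),
    dplyr::mutate(x$highlow, block = "highlow"),
    dplyr::mutate(x$decomposition, block = "decomposition")
  ) |> dplyr::relocate(block)
}

#' One-row summary of an analysis report
#'
#' @param x A `crcprs_report`.
#' @param ... Unused.
#' @return Tibble with cohort size, included variant count, the
#'   case-vs-control OR per score unit and the full-model AUC.
#' @method glance crcprs_report
#' @export
glance.crcprs_report <- function(x, ...) {
  fcrc <- x$group_stats[x$group_stats$group == "fcrc", ]
  auc_full <- x$decomposition$metric_full[x$decomposition$metric == "auc"][1]
  tibble::tibble(
    n_individuals = x$provenance$n_individuals,
    n_variants_included = x$provenance$n_variants_included,
    fcrc_or_per_unit = if (nrow(fcrc)) fcrc$or else NA_real_,
    auc_full = auc_full
  )
}

#' Violin plot of score distributions by group
#'
#' @param object Scored tibble from [compute_wprs()] (or the `scored`
#'   element of a report).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crcprs_scores
#' @export
autoplot.crcprs_scores <- function(object, ...) {
  plot_score_distributions(object)
}

#' @rdname autoplot.crcprs_scores
#' @param scored Scored tibble with `group` and `wprs` columns.
#' @export
plot_score_distributions <- function(scored) {
  ggplot2::ggplot(scored[scored$complete, ],
                  ggplot2::aes(x = .data$group, y = .data$wprs, fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.12, outlier.size = 0.4, fill = "white") +
    ggplot2::labs(x = NULL, y = "wPRS (risk-allele equivalents)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Quantile odds-ratio profile plot
#'
#' ORs (log scale) per score quantile against the reference quantile, with
#' 95% CI error bars — the quantile risk-stratification figure.
#'
#' @param profile Tibble from [quantile_or_profile()].
#' @return A ggplot object.
#' @export
plot_quantile_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$quantile, y = .data$or)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.3, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$reference), size = 2, na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "wPRS quantile", y = "OR vs reference quantile (log scale)") +
    ggplot2::theme_minimal()
}

#' Contribution decomposition bar plot
#'
#' @param decomposition Tibble from [contribution_decomposition()] (or the
#'   report's `decomposition` block).
#' @return A ggplot object.
#' @export
plot_decomposition <- function(decomposition) {
  ggplot2::ggplot(decomposition,
                  ggplot2::aes(x = .data$variable, y = .data$contribution_pct,
                               fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Contribution (percentage points)") +
    ggplot2::theme_minimal()
}
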