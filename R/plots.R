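# ggplot2 views of the main result types.

#' Plot a log-log degree-frequency fit
#'
#' @param object a `degree_fit` from [degree_distribution_fit()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.degree_fit <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(.data$degree, .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "frequency density",
                  title = sprintf("slope = %.2f, R² = %.2f",
                                  object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a DiffK distribution with its fitted null
#'
#' @param object a `diffk_table` (ideally after [diffk_pvalues()]).
#' @param ... ignored.
#' @return a ggplot histogram of DiffK values.
#' @export
autoplot.diffk_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$diffk)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "DiffK (log k1+10 − log k2+10)", y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment odds-ratio curve
#'
#' @param or_curve output of [enrichment_odds_ratio()].
#' @return a ggplot of odds ratio vs correlation cutoff.
#' @export
plot_or_curve <- function(or_curve) {
  ggplot2::ggplot(dplyr::filter(or_curve, !is.na(.data$odds_ratio)),
                  ggplot2::aes(.data$cutoff, .data$odds_ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "correlation cutoff", y = "odds ratio") +
    ggplot2::theme_minimal()
}

#' Plot hierarchy level sizes (pyramid view)
#'
#' @param object a `hierarchy_assignment` from [assign_levels()].
#' @param tf_only count TFs only (default TRUE).
#' @param ... ignored.
#' @return a ggplot bar chart of genes per level.
#' @export
autoplot.hierarchy_assignment <- function(object, tf_only = TRUE, ...) {
  lv <- object$levels
  if (tf_only) lv <- dplyr::filter(lv, .data$is_tf)
  counts <- dplyr::count(lv, .data$level)
  ggplot2::ggplot(counts, ggplot2::aes(factor(.data$level), .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "hierarchy level", y = "genes",
                  title = sprintf("downward fraction %.2f",
                                  object$downward_fraction)) +
    ggplot2::theme_minimal()
}

#' Plot a motif catalog
#'
#' @param object a `motif_catalog` from [motif_significance()].
#' @param ... ignored.
#' @return a ggplot of observed vs null counts per canonical id.
#' @export
autoplot.motif_catalog <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(factor(.data$id), .data$observed_count,
                               fill = .data$is_motif)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(ggplot2::aes(y = .data$null_mean), shape = 4) +
    ggplot2::facet_wrap(~size, scales = "free_x") +
    ggplot2::labs(x = "canonical motif id", y = "count",
                  fill = "motif") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
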