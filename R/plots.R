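# ggplot2 figures for the report objects.

#' Bar chart of an efficiency metric per matrix and method
#'
#' Mean with a standard-deviation error bar, one panel per matrix — the
#' standard way of eyeballing the variable-count / signal-strength layers of
#' the efficiency assessment.
#'
#' @param report An [efficiency_report()].
#' @param metric `"n_variables"` or `"total_signal"`.
#' @return A ggplot object.
#' @export
plot_efficiency <- function(report, metric = c("n_variables", "total_signal")) {
  metric <- match.arg(metric)
  cells <- report$cells
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sd")
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$method, y = .data[[mcol]],
                                      fill = .data$method)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                        ymax = .data[[mcol]] + .data[[scol]]),
                           width = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$matrix), scales = "free_y") +
    ggplot2::labs(
      y = if (metric == "n_variables") "Variables identified (mean ± sd)"
          else "Total signal strength (mean ± sd)",
      x = NULL,
      title = sprintf("Extraction efficiency, polarity %s", report$polarity)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of CV strata per group
#'
#' @param strata A tibble of per-group strata (columns `group`, `bin`,
#'   `fraction_pct`), e.g. the `strata` element of a [run_pipeline()] result.
#' @return A ggplot object.
#' @export
plot_cv_strata <- function(strata) {
  ggplot2::ggplot(strata, ggplot2::aes(x = .data$group, y = .data$fraction_pct,
                                       fill = .data$bin)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Fraction of variables (%)", fill = "CV stratum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-class relative-abundance bar chart
#'
#' @param report An [efficiency_report()].
#' @param classes Lipid classes to show; default all.
#' @return A ggplot object.
#' @export
plot_class_abundance <- function(report, classes = NULL) {
  d <- report$class_profiles
  if (!is.null(classes)) d <- d[d$lipid_class %in% classes, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lipid_class, y = .data$abundance_mean,
                                  fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$abundance_mean - .data$abundance_se,
                   ymax = .data$abundance_mean + .data$abundance_se),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$matrix), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Relative abundance (‰, mean ± se)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Scores plot for a PCA fit
#'
#' @param object A `dims_pca` object.
#' @param labels Optional group label per sample (e.g. matrix subtype) used
#'   for colouring.
#' @param components Two components to plot. Default `c(1, 2)`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dims_pca
#' @export
autoplot.dims_pca <- function(object, labels = NULL, components = c(1, 2), ...) {
  pcs <- paste0("PC", components)
  d <- object$scores
  if (!all(pcs %in% names(d))) {
    rlang::abort("Requested components were not retained in the fit.")
  }
  if (!is.null(labels)) d$group <- labels
  ev <- 100 * object$explained_variance[components]
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]]))
  gg <- if (is.null(labels)) gg + ggplot2::geom_point() else
    gg + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  gg +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", pcs[1], ev[1]),
                  y = sprintf("%s (%.1f%%)", pcs[2], ev[2]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
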