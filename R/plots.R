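#' Scatter plot of a harmonized instrument set
#'
#' Per-variant SNP-outcome against SNP-exposure effects with error bars and,
#' when results are supplied, the fitted slope of each estimator (MR-Egger
#' keeps its intercept; all other methods pass through the origin).
#'
#' @param object A `harmonized_set` (or any tibble with `bx`, `se_x`, `by`,
#'   `se_y`).
#' @param results Optional `mr_result` tibble of fitted estimators.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.harmonized_set <- function(object, results = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - 1.96 * .data$se_y,
                                        ymax = .data$by + 1.96 * .data$se_y),
                           width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - 1.96 * .data$se_x,
                                         xmax = .data$bx + 1.96 * .data$se_x),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNP-exposure effect (cups/day per allele)",
                  y = "SNP-outcome effect (outcome SD per allele)")
  if (!is.null(results)) {
    lines <- dplyr::transmute(
      results, method = .data$method, slope = .data$beta,
      intercept = dplyr::coalesce(.data$egger_intercept, 0)
    )
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)
    )
  }
  p
}

#' Forest plot of MR / regression estimates
#'
#' @param results Tibble with columns `beta`, `se` and a label column.
#' @param label Name of the label column (default `"method"`).
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(results, label = "method") {
  results <- dplyr::mutate(results, .label = .data[[label]])
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$beta, y = .data$.label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                   xmax = .data$beta + 1.96 * .data$se), height = 0.15) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Causal effect (outcome SD per cup/day)", y = NULL)
}

#' Scree plot for the effective-tests PCA
#'
#' @param x An `effective_tests` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.effective_tests <- function(x, ...) {
  d <- tidy(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component,
                                  y = .data$cumulative)) +
    ggplot2::geom_hline(yintercept = x$variance_target, linetype = 2) +
    ggplot2::geom_vline(xintercept = x$n_components, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Principal component",
                  y = "Cumulative variance fraction")
}
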