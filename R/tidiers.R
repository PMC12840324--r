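#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a per-scan evaluation
#'
#' @param x A `scan_eval`.
#' @param ... Unused.
#' @return The per-node tibble (one row per ground-truth node).
#' @export
tidy.scan_eval <- function(x, ...) x$nodes

#' One-row summary of a per-scan evaluation
#'
#' @param x A `scan_eval`.
#' @param ... Unused.
#' @return The one-row metrics tibble.
#' @export
glance.scan_eval <- function(x, ...) x$metrics

#' Tidy a cohort evaluation
#'
#' @param x A `cohort_eval`.
#' @param ... Unused.
#' @return The stratified cohort table in long form (status x SAD bin).
#' @export
tidy.cohort_eval <- function(x, ...) x$report$strata

#' One-row summary of a cohort evaluation
#'
#' @param x A `cohort_eval`.
#' @param ... Unused.
#' @return One-row tibble with cohort-level recall (macro and micro),
#'   precision, FP statistics and mean segmentation metrics.
#' @export
glance.cohort_eval <- function(x, ...) x$report$summary

#' Plot node size against segmentation sensitivity
#'
#' The scatter relating each ground-truth node's SAD to its per-node
#' sensitivity, coloured by metastatic status, with the localization
#' threshold and the 10 mm RECIST cut marked.
#'
#' @param object A `cohort_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_eval <- function(object, ...) {
  df <- sad_sensitivity_data(object)
  df$status <- ifelse(df$metastatic, "metastatic", "non-metastatic")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sad_mm, y = .data$sensitivity,
                                   colour = .data$status,
                                   shape = .data$status)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$config$tau_localize,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 10, linetype = "dotted") +
    ggplot2::labs(x = "short-axis diameter (mm)",
                  y = "per-node sensitivity", colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the stratified recall profile
#'
#' Recall by SAD bin and metastatic status for a cohort evaluation,
#' optionally against expected values from a degradation configuration.
#'
#' @param x A `cohort_eval`.
#' @param expected Optional [expected_metrics()] result to overlay.
#' @return A ggplot object.
#' @export
plot_recall_by_bin <- function(x, expected = NULL) {
  df <- dplyr::filter(x$report$strata, .data$sad_bin != "all")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sad_bin, y = .data$recall,
                                        fill = .data$status)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "SAD bin (mm)", y = "recall", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(expected)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(expected$per_bin,
                           sad_bin = factor(.data$sad_bin,
                                            levels = levels(df$sad_bin))),
      ggplot2::aes(x = .data$sad_bin, y = .data$expected_recall),
      inherit.aes = FALSE, shape = 4, size = 3)
  }
  p
}
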