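# ggplot2 visualizations for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = attr(object, "source")) +
    ggplot2::theme_minimal()
}

#' Plot a Bi-distributional pair's Universal ROC curve
#'
#' @param object A `biroc_pair`.
#' @param n_points Grid resolution (default 512).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.biroc_pair <- function(object, n_points = 512, ...) {
  R <- uroc_function(object)
  p <- seq(0, 1, length.out = n_points)
  autoplot.roc_curve(new_roc_curve(p, R(p), "parametric", object$label))
}

#' Plot Monte Carlo selection frequencies
#'
#' One bar panel per criterion showing how often each candidate pair was
#' selected across runs.
#'
#' @param object A `mc_frequency` from [run_monte_carlo()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mc_frequency <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("auc", "aic_roc", "icomp_roc"),
                              names_to = "criterion", values_to = "count")
  long$candidate <- factor(long$candidate, levels = object$candidate)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$candidate, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~criterion, ncol = 1) +
    ggplot2::labs(x = NULL, y = "Selections",
                  title = paste0("Selection frequencies over ",
                                 attr(object, "n_runs"), " runs")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a GA convergence trace
#'
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ga_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$generation, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Generation",
                  y = paste0("Best fitness (", object$config$fitness, ")"),
                  title = paste("GA convergence,", object$config$preset)) +
    ggplot2::theme_minimal()
}
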