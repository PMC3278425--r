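#' Scatter plot of a classification feature against a nuisance feature
#'
#' One point per subject, coloured by group, with per-group least-squares
#' lines — the standard view for judging whether (and how) a nuisance
#' feature interacts with a classification feature, before and after
#' correction.
#'
#' @param data A `nuis_data`.
#' @param feature Classification-feature name (default: the first).
#' @param nuisance Nuisance-feature name (default: the first).
#' @return A ggplot object.
#' @export
plot_feature_vs_nuisance <- function(data, feature = feature_names(data)[1],
                                     nuisance = nuisance_names(data)[1]) {
  stopifnot(inherits(data, "nuis_data"),
            feature %in% feature_names(data),
            nuisance %in% nuisance_names(data))
  df <- data$data
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[nuisance]], y = .data[[feature]],
    colour = .data[[data$group]]
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.8) +
    ggplot2::labs(colour = "group") +
    ggplot2::theme_minimal()
}

#' Compare per-repeat accuracies across methods
#'
#' Boxplot of the paired per-repeat accuracies of several
#' [run_method()] results evaluated on the same cross-validation plan.
#'
#' @param ... `method_result` objects (or a single list of them).
#' @return A ggplot object.
#' @export
plot_method_comparison <- function(...) {
  results <- list(...)
  if (length(results) == 1 && !inherits(results[[1]], "method_result")) {
    results <- results[[1]]
  }
  stopifnot(all(vapply(results, inherits, logical(1), "method_result")))
  df <- dplyr::bind_rows(lapply(results, tidy))
  df$label <- ifelse(df$nuisance_subset == "", df$method,
                     paste0(df$method, "\n[", df$nuisance_subset, "]"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18,
                          size = 3, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "per-repeat accuracy") +
    ggplot2::theme_minimal()
}

#' @describeIn best_by_size Plot the best accuracy per subset size (line per
#'   method), the accuracy-vs-number-of-nuisance-features view.
#' @param object A `subset_search` tibble.
#' @param ... Unused.
#' @export
autoplot.subset_search <- function(object, ...) {
  df <- best_by_size(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$subset_size, y = .data$mean_accuracy,
    colour = .data$method, group = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(df$subset_size)) +
    ggplot2::labs(x = "number of nuisance features",
                  y = "best mean accuracy", colour = "method") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
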