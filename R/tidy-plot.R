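## broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained classifier
#' @param x A [train_classifier()] fit.
#' @param ... Unused.
#' @return Tibble with one row per feature: name, standardisation center and
#'   scale.
#' @method tidy trained_classifier
#' @export
tidy.trained_classifier <- function(x, ...) {
  tibble::tibble(feature = x$feature_names, center = unname(x$center),
                 scale = unname(x$scale))
}

#' @rdname tidy.trained_classifier
#' @method glance trained_classifier
#' @export
glance.trained_classifier <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family,
    option = switch(x$spec$family, svm = x$spec$svm_kernel,
                    knn = x$spec$knn_metric, ec = x$spec$ec_method),
    task = x$task, n_features = length(x$feature_names),
    n_classes = length(x$levels), n_train = sum(x$n_per_class))
}

#' Tidy an evaluation report into a long confusion table
#' @param x An [evaluate()] report.
#' @param ... Unused.
#' @return Tibble with `true`, `predicted`, `n`.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  df <- as.data.frame(x$confusion)
  tibble::tibble(true = df$true, predicted = df$predicted, n = df$Freq)
}

#' @rdname tidy.evaluation_report
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(task = x$task, accuracy_pct = x$accuracy_pct,
                 n_test = x$n_test,
                 mean_recall = mean(x$per_class_recall))
}

raster_df <- function(mat, value_name = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(mat)), ncol(mat)),
    col = rep(seq_len(ncol(mat)), each = nrow(mat)),
    !!value_name := as.vector(mat))
}

#' Plot a phase image
#' @param object A [phase_image()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phase_image
#' @export
autoplot.phase_image <- function(object, ...) {
  df <- raster_df(object$phase, "phase")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "phase (rad)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot a segmentation label map
#' @param object A [segment_cells()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot segmentation_result
#' @export
autoplot.segmentation_result <- function(object, ...) {
  df <- raster_df(object$labels, "label")
  df$label <- factor(df$label)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("%d cells", nrow(object$cells))) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#' @param object An [evaluate()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("%s: %.1f%% accuracy", object$task,
                                  object$accuracy_pct)) +
    ggplot2::theme_minimal()
}

#' Plot time-resolved state fractions
#' @param object A [classify_time_series()] result.
#' @param ... Unused.
#' @return A ggplot (stacked area of the three state fractions over time).
#' @method autoplot timeseries_fractions
#' @export
autoplot.timeseries_fractions <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "time_min", "frac_live",
                  "frac_apoptotic", "frac_necrotic"),
    -"time_min", names_to = "state", values_to = "fraction")
  df$state <- factor(sub("frac_", "", df$state),
                     levels = c("live", "apoptotic", "necrotic"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$fraction,
                                   fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "time after treatment (min)", y = "fraction of cells") +
    ggplot2::theme_minimal()
}

#' Plot an accuracy-vs-subset-size curve
#' @param object A [feature_subset_analysis()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot feature_subset_curve
#' @export
autoplot.feature_subset_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n_features,
                                       .data$accuracy_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$n_features) +
    ggplot2::labs(x = "number of features (ranked)", y = "accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of two features coloured by class
#'
#' The classic average-phase vs dry-mass scatter used to visualise class
#' separation.
#'
#' @param features Labelled feature tibble (from [dataset_features()]).
#' @param x,y Feature column names.
#' @param color Label column to colour by (`"state"` or `"line"`).
#' @return A ggplot.
#' @export
plot_feature_scatter <- function(features, x = "phi_av", y = "dm_pg",
                                 color = "state") {
  ggplot2::ggplot(features, ggplot2::aes(.data[[x]], .data[[y]],
                                         color = .data[[color]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::theme_minimal()
}
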