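#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster
#'
#' @param object An `enm_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enm_raster <- function(object, ...) {
  df <- as_tibble.enm_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a three-class habitat map
#'
#' @param object A `classified_map`.
#' @param ... Unused.
#' @return A ggplot with the unsuitable / sub-suitable / suitable legend.
#' @export
autoplot.classified_map <- function(object, ...) {
  df <- as_tibble.enm_raster(object)
  df$class <- factor(df$value, levels = c(0, 1, 2),
                     labels = c("unsuitable", "sub-suitable", "suitable"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c("grey85", "#8fd07c", "#1a7d2e")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "habitat")
}

#' Plot a range-change map
#'
#' @param object A `change_map`.
#' @param ... Unused.
#' @return A ggplot with the four change categories.
#' @export
autoplot.change_map <- function(object, ...) {
  df <- as_tibble.enm_raster(object)
  codes <- attr(object, "codes")
  df$category <- factor(df$value, levels = unname(codes),
                        labels = names(codes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(never_present = "grey90",
                                          expansion = "#2166ac",
                                          contraction = "#b2182b",
                                          no_change_present = "#66bd63")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "change")
}

#' Plot variable importance
#'
#' @param object An `importance_table`.
#' @param ... Unused.
#' @return A ggplot of percent contribution and permutation importance.
#' @export
autoplot.importance_table <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("percent_contribution",
                                     "permutation_importance"),
                            names_to = "measure", values_to = "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$layer, .data$pct),
                                   y = .data$pct, fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL)
}

#' Plot a single-factor response curve
#'
#' @param object A `response_curve`.
#' @param ... Unused.
#' @return A ggplot of logistic suitability against the layer value.
#' @export
autoplot.response_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$value, y = .data$logistic)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "layer value", y = "logistic suitability")
}

#' Plot a selection-frequency surface
#'
#' @param object A `run_ensemble`.
#' @param units Units tibble with `row` and `col` lattice positions (as from
#'   [generate_planning_lattice()]).
#' @param ... Unused.
#' @return A ggplot of per-unit selection frequency.
#' @export
plot_selection_frequency <- function(object, units, ...) {
  df <- dplyr::left_join(units, object$selection_frequency, by = "id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "selection\nfrequency")
}

#' @importFrom rlang .data
NULL
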