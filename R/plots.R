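#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `roc_curve` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "False-positive rate (1 - specificity)",
      y = "True-positive rate (sensitivity)",
      title = sprintf("AUC = %.3f, cutoff = %.3f", object$auc,
                      object$cutoff)
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot an individual-treatment-effect distribution
#'
#' Histogram with a density overlay of the per-child effects.
#'
#' @param object An `ite_summary` from [summarize_ite()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ite_summary
#' @export
autoplot.ite_summary <- function(object, ...) {
  h <- object$histogram
  width <- h$upper[1] - h$lower[1]
  dens <- h$count / (object$n * width)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = dens)) +
    ggplot2::geom_col(width = width, fill = "steelblue", alpha = 0.7) +
    ggplot2::geom_line(stat = "identity", colour = "grey30") +
    ggplot2::labs(x = expression(theta[i] ~ "(" * Delta * " probability)"),
                  y = "Density",
                  title = "Individual treatment effects") +
    ggplot2::theme_minimal()
}

#' Plot an intensity surface
#'
#' @param object An `intensity_grid` from [estimate_intensity()].
#' @param ... Unused.
#' @return A ggplot raster of expected deaths per cell.
#' @method autoplot intensity_grid
#' @export
autoplot.intensity_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Expected deaths") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = paste0("Conflict intensity, ",
                                 month_label(object$month),
                                 " (", object$window_months,
                                 "-month window)")) +
    ggplot2::theme_minimal()
}

#' Plot per-level treatment effects
#'
#' Point estimates with 95% credible regions per education level
#' (negative = protective).
#'
#' @param cate_by_level Tibble from [run_analysis()]'s `cate_by_level`.
#' @return A ggplot.
#' @export
plot_cate_by_level <- function(cate_by_level) {
  ggplot2::ggplot(cate_by_level,
                  ggplot2::aes(x = factor(.data$level),
                               y = .data$delta_probability)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::labs(x = "Maternal education level",
                  y = expression(Delta ~ "probability"),
                  title = "Effect of maternal education on severe undernutrition") +
    ggplot2::theme_minimal()
}

#' Plot the survey-constrained partition
#'
#' Voronoi cells coloured by merged area, with cluster seeds.
#'
#' @param partition A `conflict_partition` from [build_partition()].
#' @return A ggplot.
#' @export
plot_partition <- function(partition) {
  cl <- partition$clusters
  polys <- purrr::imap(partition$polygons, function(V, i) {
    tibble::tibble(lon = V[, 1], lat = V[, 2],
                   cluster_id = cl$cluster_id[i])
  }) |>
    dplyr::bind_rows() |>
    dplyr::left_join(partition$assignment, by = "cluster_id")
  ggplot2::ggplot(polys, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_polygon(ggplot2::aes(group = .data$cluster_id,
                                       fill = .data$area_id),
                          colour = "white", linewidth = 0.2,
                          show.legend = FALSE) +
    ggplot2::geom_point(data = cl,
                        ggplot2::aes(shape = factor(.data$survey_round)),
                        size = 1) +
    ggplot2::scale_shape_discrete(name = "Survey round") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = "Survey-constrained Voronoi-merge partition") +
    ggplot2::theme_minimal()
}
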