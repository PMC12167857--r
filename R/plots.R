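#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_col geom_errorbar
#'   scale_fill_viridis_c scale_fill_manual coord_equal labs theme_minimal
NULL

#' Plot a suitability map
#'
#' @param object A `suitability_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.suitability_map <- function(object, ...) {
  df <- map_to_tibble(object)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1), name = "suitability") +
    coord_equal() +
    labs(title = paste0("Habitat suitability (", object$period_tag, ")"),
         x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a CV uncertainty map
#' @inheritParams autoplot.suitability_map
#' @export
autoplot.cv_map <- function(object, ...) {
  df <- map_to_tibble(object)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(option = "magma", name = "CV") +
    coord_equal() +
    labs(title = paste0("Prediction uncertainty, SD/mean (",
                        object$period_tag, ")"), x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a binary suitability map
#' @inheritParams autoplot.suitability_map
#' @export
autoplot.binary_map <- function(object, ...) {
  df <- map_to_tibble(object)
  df$suitable <- factor(df$value, levels = c(0, 1),
                        labels = c("unsuitable", "suitable"))
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$suitable)) +
    geom_raster() +
    scale_fill_manual(values = c(unsuitable = "grey85", suitable = "firebrick"),
                      name = NULL) +
    coord_equal() +
    labs(title = sprintf("Binary range (threshold %.3f, %s)",
                         object$threshold, object$period_tag),
         x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot permutation variable importance
#'
#' Bars of mean importance (1 - r) with +/- 1 SD whiskers over shuffles.
#'
#' @param object An `importance_scores` tibble.
#' @param ... Unused.
#' @export
autoplot.importance_scores <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$mean)
  df$variable <- factor(df$variable, levels = df$variable)
  ggplot(df, aes(x = .data$mean, y = .data$variable)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(xmin = pmax(0, .data$mean - .data$sd),
                      xmax = .data$mean + .data$sd), width = 0.3) +
    labs(x = "permutation importance (1 - r)", y = NULL,
         title = "Variable importance") +
    theme_minimal()
}

#' Plot range expansion/contraction between two scenarios
#'
#' @param summary A `range_change_summary` (one or more rows).
#' @return A ggplot of km2 by change class and scenario.
#' @export
plot_range_change <- function(summary) {
  long <- tidyr::pivot_longer(tibble::as_tibble(summary),
                              c("expansion_km2", "contraction_km2",
                                "unchanged_km2"),
                              names_to = "class", values_to = "km2")
  long$class <- sub("_km2$", "", long$class)
  ggplot(long, aes(x = .data$to, y = .data$km2, fill = .data$class)) +
    geom_col(position = "dodge") +
    scale_fill_manual(values = c(expansion = "forestgreen",
                                 contraction = "firebrick",
                                 unchanged = "grey60"), name = NULL) +
    labs(x = "scenario", y = expression(km^2),
         title = "Projected range change") +
    theme_minimal()
}
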