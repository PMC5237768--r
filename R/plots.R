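#' @importFrom ggplot2 ggplot aes geom_polygon geom_line facet_wrap labs
#'   scale_fill_viridis_c coord_equal theme_minimal autoplot
NULL

#' Plot a per-element density field
#'
#' Draws the mesh as filled polygons colored by apparent density (or any
#' per-element quantity).
#'
#' @param mesh A [bone_mesh()].
#' @param values Per-element values (e.g. a density field); defaults to
#'   the region labels.
#' @param name Legend title.
#' @return A ggplot object.
#' @export
plot_density_field <- function(mesh, values = NULL, name = "density (g/cm3)") {
  conn <- as.matrix(mesh$elements[, c("n1", "n2", "n3", "n4")])
  ne <- nrow(conn)
  df <- tibble(
    element = rep(seq_len(ne), each = 4L),
    x = mesh$nodes$x[as.vector(t(conn))],
    y = mesh$nodes$y[as.vector(t(conn))]
  )
  if (is.null(values)) {
    df$value <- rep(mesh$elements$region, each = 4L)
    p <- ggplot(df, aes(x, y, group = element, fill = value)) +
      geom_polygon(color = NA) +
      labs(fill = "region")
  } else {
    stopifnot(length(values) == ne)
    df$value <- rep(values, each = 4L)
    p <- ggplot(df, aes(x, y, group = element, fill = value)) +
      geom_polygon(color = NA) +
      scale_fill_viridis_c(name = name)
  }
  p + coord_equal() + theme_minimal() + labs(x = "x (cm)", y = "y (cm)")
}

#' Plot the per-day metrics of a simulation trace
#'
#' @param object A `simulation_trace`.
#' @param metrics Metric columns to show.
#' @param ... Unused.
#' @return A ggplot object with one facet per metric.
#' @export
autoplot.simulation_trace <- function(object,
                                      metrics = c("osteo_score",
                                                  "new_bone_fraction",
                                                  "refilled_area_mm2",
                                                  "total_mass"),
                                      ...) {
  long <- object$metrics |>
    dplyr::select(day, dplyr::any_of(metrics)) |>
    tidyr::pivot_longer(-day, names_to = "metric", values_to = "value") |>
    dplyr::filter(is.finite(value))
  ggplot(long, aes(day, value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    theme_minimal() +
    labs(x = "day", y = NULL)
}

#' Plot a sweep summary
#'
#' Final osteogenesis score per sweep cell.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot(object$summary,
         aes(factor(E1_0), final_score,
             group = factor(T_days), color = factor(T_days))) +
    geom_line() +
    ggplot2::geom_point() +
    theme_minimal() +
    labs(x = "initial implant modulus E1_0 (MPa)",
         y = "final osteogenesis score (MPa)",
         color = "T (days)")
}
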