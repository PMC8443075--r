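# ggplot2 display methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a curvature profile
#'
#' @param object a `curvature_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot curvature_profile
#' @export
autoplot.curvature_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radial position (mm)", y = "sagittal power (D)") +
    ggplot2::theme_minimal()
}

#' Plot a curvature-change map
#'
#' @param object a `curvature_delta`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot curvature_delta
#' @export
autoplot.curvature_delta <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radial position (mm)",
                  y = expression(Delta ~ "sagittal power (D)")) +
    ggplot2::theme_minimal()
}

#' Plot the per-angle flattening summaries of a study
#'
#' Central and peripheral dioptric change versus angular position, one panel
#' per mechanical mode, coloured by design.
#'
#' @param object a `study_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot study_result
#' @export
autoplot.study_result <- function(object, ...) {
  d <- tidy(object)
  long <- rbind(
    data.frame(d[c("design", "angle", "mode")], which = "central",
               delta = d$central_delta),
    data.frame(d[c("design", "angle", "mode")], which = "peripheral",
               delta = d$peripheral_delta))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$angle, y = .data$delta,
                                     colour = .data$design,
                                     linetype = .data$which)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "angular position (deg)",
                  y = expression(Delta ~ "sagittal power (D)")) +
    ggplot2::theme_minimal()
}

#' Plot a mesh (optionally deformed)
#'
#' Element edges of the active elements, coloured by material set.
#'
#' @param mesh a `cornea_mesh`.
#' @param displacements optional nodal displacement matrix to deform by.
#' @param scale displacement magnification.
#' @return a ggplot.
#' @export
plot_mesh <- function(mesh, displacements = NULL, scale = 1) {
  xy <- mesh$nodes
  if (!is.null(displacements)) xy <- xy + scale * displacements
  els <- which(mesh$active)
  corner_loop <- c(1, 5, 2, 6, 3, 7, 4, 8, 1)
  polys <- do.call(rbind, lapply(els, function(e) {
    idx <- mesh$elements[e, corner_loop]
    data.frame(x = xy[idx, 1], y = xy[idx, 2], id = e,
               material = mesh$elem_material[e])
  }))
  ggplot2::ggplot(polys, ggplot2::aes(x = .data$x, y = .data$y,
                                      group = .data$id,
                                      fill = .data$material)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
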