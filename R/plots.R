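# ggplot2 front-ends for the result containers.

#' @rdname thickness_profile_1d
#' @param object A `thickness_profile`.
#' @param ... Unused.
#' @method autoplot thickness_profile
#' @export
autoplot.thickness_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$thickness)),
                  ggplot2::aes(x = .data$x, y = .data$thickness)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "x (nm)", y = "membrane thickness d (nm)")
}

#' @rdname thickness_map_2d
#' @param object A `thickness_map`.
#' @param value Column to plot: `"thickness"` (default) or `"perturbation"`.
#' @param ... Unused.
#' @method autoplot thickness_map
#' @export
autoplot.thickness_map <- function(object, value = "thickness", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$dx, y = .data$dy,
                               fill = .data[[value]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "x - x_peptide (nm)", y = "y - y_peptide (nm)",
                  fill = paste0(value, " (nm)"))
}

#' @rdname simulate_sorting_ensemble
#' @param object An `ensemble_trajectory`.
#' @param alpha Per-replica line transparency.
#' @param ... Unused.
#' @method autoplot ensemble_trajectory
#' @export
autoplot.ensemble_trajectory <- function(object, alpha = 0.2, ...) {
  mp <- ensemble_mean_path(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$x,
                                       group = .data$replica)) +
    ggplot2::geom_line(alpha = alpha, colour = "grey40") +
    ggplot2::geom_line(data = mp,
                       ggplot2::aes(y = .data$mean_x, group = NULL),
                       colour = "black", linewidth = 1) +
    ggplot2::labs(x = "time (ns)", y = "peptide COM x (nm)")
}

#' @rdname fit_relaxation
#' @param object A `relaxation_fit`.
#' @method autoplot relaxation_fit
#' @export
autoplot.relaxation_fit <- function(object, ...) {
  df <- tibble::tibble(time = object$times, observed = object$observed,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time (ns)", y = "ensemble-mean x (nm)")
}

#' @rdname wham_1d
#' @param object A `free_energy_profile`.
#' @param ... Unused.
#' @method autoplot free_energy_profile
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  coord <- attr(object, "coordinate")
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$delta_F)),
                  ggplot2::aes(x = .data[[coord]], y = .data$delta_F)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = coord, y = expression(Delta * F ~ "(" * k[B] * T * ")"))
}

#' @rdname compose_surface_2d
#' @param object A `free_energy_surface`.
#' @param ... Unused.
#' @method autoplot free_energy_surface
#' @export
autoplot.free_energy_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$d, y = .data$theta,
                                       fill = .data$delta_F)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "white", direction = -1) +
    ggplot2::labs(x = "membrane thickness d (nm)", y = "tilt (deg)",
                  fill = expression(Delta * F ~ "(" * k[B] * T * ")"))
}
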