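#' Plot cell trajectories
#'
#' One path per track in the (x, y) plane, with start (solid) and end (open)
#' points.
#'
#' @param ensemble An [as_ensemble()] object.
#' @param max_tracks Plot at most this many tracks (first by id).
#' @return A ggplot object.
#' @export
plot_tracks <- function(ensemble, max_tracks = 30) {
  x <- as_tibble(ensemble)
  ids <- head(unique(x$track_id), max_tracks)
  x <- x[x$track_id %in% ids, ]
  ends <- dplyr::summarise(
    dplyr::group_by(x, .data$track_id),
    x0 = .data$x_um[1], y0 = .data$y_um[1],
    x1 = .data$x_um[dplyr::n()], y1 = .data$y_um[dplyr::n()],
    .groups = "drop")
  ggplot2::ggplot(x, ggplot2::aes(.data$x_um, .data$y_um, group = .data$track_id,
                                  colour = .data$track_id)) +
    ggplot2::geom_path(alpha = 0.8, show.legend = FALSE) +
    ggplot2::geom_point(data = ends, ggplot2::aes(.data$x0, .data$y0),
                        inherit.aes = FALSE, size = 1) +
    ggplot2::geom_point(data = ends, ggplot2::aes(.data$x1, .data$y1),
                        inherit.aes = FALSE, size = 1, shape = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a mean-squared-displacement series
#'
#' Mean (points) and median (open squares) squared displacement against time,
#' with the interquartile band, and optionally the zero-intercept fitted
#' line.
#'
#' @param object An [ensemble_msd()] result.
#' @param fit Optional [fit_diffusivity()] object whose line to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msd_series <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$t_hr, .data$mean_sq_um2)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25_um2, ymax = .data$q75_um2),
                         alpha = 0.15) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median_sq_um2), shape = 0, size = 1.5) +
    ggplot2::labs(x = "time (hr)",
                  y = expression(bar(L^2) ~ (mu * m^2))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(slope = fit$slope, intercept = 0,
                                  colour = "red")
  }
  p
}

#' Plot the separation history of a cell pair
#'
#' Separation s(t) together with the displacement of the pair centroid from
#' its initial position, against elapsed time.
#'
#' @param object A [pair_kinematics()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pair_series <- function(object, ...) {
  d <- object$data
  centroid_disp <- sqrt((d$cx_um - d$cx_um[1])^2 + (d$cy_um - d$cy_um[1])^2)
  long <- dplyr::bind_rows(
    tibble(t_hr = d$elapsed_hr, value_um = d$s_um, series = "separation"),
    tibble(t_hr = d$elapsed_hr, value_um = centroid_disp,
           series = "centroid displacement"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t_hr, .data$value_um,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time since pairing (hr)", y = "distance (µm)",
                  colour = NULL, title = object$pair_id) +
    ggplot2::theme_minimal()
}

#' Plot empirical first-contact statistics
#'
#' @param object A [simulate_encounter()] result.
#' @param ... Unused.
#' @return A ggplot object of the contact fraction against time.
#' @export
autoplot.encounter_sim <- function(object, ...) {
  ggplot2::ggplot(object$contact_fraction,
                  ggplot2::aes(.data$t_hr, .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (hr)", y = "fraction of pairs in contact") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
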