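#' Phase portrait of the replicator dynamics
#'
#' Draws the velocity field on the unit square (arrow lengths scaled to the
#' local speed) with optional trajectory overlays, the style commonly used
#' for two-population evolutionary games: patient frequency `x` on the
#' horizontal axis, hospital frequency `y` on the vertical axis.
#'
#' @param params A [game_params()] object.
#' @param resolution Lattice resolution of the arrow field.
#' @param trajectories Optional list of [replicator_trajectory()] results to
#'   overlay.
#' @param arrow_scale Length of the longest arrow, in state units.
#' @return A ggplot object.
#' @examples
#' plot_phase(baseline_params(), resolution = 11)
#' @export
plot_phase <- function(params, resolution = 15, trajectories = NULL,
                       arrow_scale = 0.06) {
  pf <- phase_field(params, resolution)
  speed <- sqrt(pf$dx_dt^2 + pf$dy_dt^2)
  top <- max(speed)
  scl <- ifelse(speed > 0, arrow_scale * speed / top / speed, 0)
  pf <- dplyr::mutate(pf, xend = .data$x + .data$dx_dt * scl,
                      yend = .data$y + .data$dy_dt * scl)
  p <- ggplot2::ggplot(pf, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.4, "mm")),
      colour = "grey40", linewidth = 0.3) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "patient frequency of cross-regional treatment (x)",
      y = "hospital frequency of direct settlement (y)") +
    ggplot2::theme_minimal()
  if (!is.null(trajectories)) {
    tr <- purrr::imap_dfr(trajectories, function(t, i)
      dplyr::mutate(as_tibble(as.data.frame(t)), run = as.character(i)))
    p <- p + ggplot2::geom_path(
      data = tr, ggplot2::aes(group = .data$run), colour = "firebrick",
      linewidth = 0.5)
  }
  p
}

#' @rdname replicator_trajectory
#' @param object A `game_trajectory` object.
#' @method autoplot game_trajectory
#' @export
autoplot.game_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(as.data.frame(object)), c("x", "y"),
    names_to = "population", values_to = "frequency")
  long$population <- dplyr::recode(long$population,
                                   x = "patients: cross-regional",
                                   y = "hospitals: direct settlement")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$frequency,
                                     colour = .data$population)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time", y = "strategy frequency", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' @rdname sweep_parameter
#' @param object A `game_sweep` object.
#' @method autoplot game_sweep
#' @export
autoplot.game_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(as.data.frame(object)),
    c("patient_limit", "hospital_limit"),
    names_to = "population", values_to = "limit")
  long$population <- dplyr::recode(long$population,
                                   patient_limit = "patients: cross-regional",
                                   hospital_limit = "hospitals: direct settlement")
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$limit,
                                     colour = .data$population)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(linewidth = 0.4, na.rm = TRUE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = attr(object, "parameter"),
                  y = "limiting strategy frequency", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
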