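#' Plot methods
#'
#' `autoplot()` methods give quick-look ggplot2 figures for every result
#' type: quiver plots for velocity fields, phase-shaded strain timecourses,
#' radial profiles and stress profiles coloured by time, Hill fits with the
#' fitted curve, and telescopic sweep summaries.
#'
#' @param object The object to plot.
#' @param time Frame(s) to show (nearest available); default first, middle
#'   and last.
#' @param arrow_scale Multiplier from velocity (um/s) to arrow length (um).
#' @param ... Unused.
#' @return A ggplot object.
#' @name actoflow-plots
NULL

pick_times <- function(times, time) {
  if (is.null(time)) time <- unique(times[c(1, ceiling(length(times) / 2), length(times))])
  vapply(time, function(t) times[which.min(abs(times - t))], numeric(1))
}

#' @rdname actoflow-plots
#' @export
autoplot.field_series <- function(object, time = NULL, arrow_scale = 50, ...) {
  tt <- pick_times(attr(object, "times"), time)
  d <- object[object$time %in% tt, ]
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_segment(aes(xend = .data$x + arrow_scale * .data$vx,
                     yend = .data$y + arrow_scale * .data$vy),
                 arrow = grid::arrow(length = grid::unit(0.9, "mm")),
                 linewidth = 0.25, colour = "firebrick") +
    facet_wrap(~time, labeller = label_both) +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
}

#' @rdname actoflow-plots
#' @export
autoplot.scalar_field_series <- function(object, time = NULL, ...) {
  tt <- pick_times(attr(object, "times"), time)
  d <- object[object$time %in% tt, ]
  ggplot(d, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    facet_wrap(~time, labeller = label_both) +
    scale_fill_viridis_c(name = attr(object, "label") %||% "value") +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
}

#' @rdname actoflow-plots
#' @export
autoplot.strain_timecourse <- function(object, ...) {
  t1 <- attr(object, "t1"); t2 <- attr(object, "t2")
  ggplot(as_tibble(object), aes(x = .data$time, y = .data$strain)) +
    annotate("rect", xmin = -Inf, xmax = t1, ymin = -Inf, ymax = Inf,
             alpha = 0.08, fill = "grey40") +
    annotate("rect", xmin = t2, xmax = Inf, ymin = -Inf, ymax = Inf,
             alpha = 0.08, fill = "steelblue") +
    geom_line(linewidth = 0.6) +
    geom_point(aes(colour = .data$phase), size = 1.4) +
    labs(x = "time (s)", y = "strain (contraction-positive)",
         colour = "phase") +
    theme_minimal()
}

#' @rdname actoflow-plots
#' @export
autoplot.radial_profile <- function(object, ...) {
  d <- as_tibble(object) |> filter(.data$n > 0)
  ggplot(d, aes(x = .data$r, y = .data$mean,
                colour = .data$time, group = .data$time)) +
    geom_line() +
    scale_colour_viridis_c(name = "time (s)") +
    labs(x = "r (um)", y = "bin mean") +
    theme_minimal()
}

#' @rdname actoflow-plots
#' @export
autoplot.stress_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$r, y = .data$sigma,
                                colour = .data$time, group = .data$time)) +
    geom_line() +
    scale_colour_viridis_c(name = "time (s)") +
    labs(x = "r (um)", y = "radial stress (zeta um^2/s)") +
    theme_minimal()
}

#' @rdname actoflow-plots
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  g <- ggplot(d, aes(x = .data$rho, y = .data$eps_max)) +
    geom_point(size = 1.6, alpha = 0.8) +
    labs(x = expression(rho ~ (mu * m^-2)), y = expression(epsilon[max])) +
    theme_minimal()
  if (object$converged) {
    grid_rho <- tibble(rho = seq(min(d$rho), max(d$rho), length.out = 200))
    grid_rho$eps <- predict(object, grid_rho)
    p <- setNames(object$estimate$estimate, object$estimate$term)
    g <- g +
      geom_line(data = grid_rho, aes(y = .data$eps), colour = "red") +
      geom_vline(xintercept = p[["rho_half"]], linetype = "dashed")
  }
  g
}

#' @rdname actoflow-plots
#' @export
autoplot.gel_solution <- function(object, time = NULL, ...) {
  tt <- pick_times(object$times, time)
  idx <- match(tt, object$times)
  d <- purrr::map2(tt, idx, function(t, k) {
    tibble(time = t, r = object$r, v_inward = -object$v[, k])
  }) |> list_rbind()
  ggplot(d, aes(x = .data$r, y = .data$v_inward, colour = .data$time,
                group = .data$time)) +
    geom_line() +
    geom_vline(xintercept = object$params$xi, linetype = "dashed") +
    scale_colour_viridis_c(name = "time (s)") +
    labs(x = "r (um)", y = "inward radial velocity (um/s)") +
    theme_minimal()
}

#' @rdname actoflow-plots
#' @export
autoplot.gel_sweep <- function(object, ...) {
  d <- as_tibble(object) |>
    tidyr::pivot_longer(c("v_max", "strain_rate", "eps_max"),
                        names_to = "metric", values_to = "value")
  ggplot(d, aes(x = .data$xi, y = .data$value,
                colour = factor(.data$stiffness))) +
    geom_line() + geom_point() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = expression(xi ~ (mu * m)), y = NULL,
         colour = expression(E / sigma[0])) +
    theme_minimal()
}
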