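#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a stationary distribution
#'
#' @param x A [stationary_density()] object.
#' @param ... Unused.
#' @return A tibble with columns `p`, `density`, `log_unnormalized`.
#' @export
tidy.demsoc_stationary <- function(x, ...) x$grid

#' One-row summary of a stationary distribution
#'
#' @param x A [stationary_density()] object.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `integrable`, `a0`, `a1`,
#'   `mass_above_half`, `log_normalization`.
#' @export
glance.demsoc_stationary <- function(x, ...) {
  tibble::tibble(
    family = x$model$family,
    integrable = x$integrable,
    a0 = x$exponents[1],
    a1 = x$exponents[2],
    mass_above_half = x$mass_above_half,
    log_normalization = x$log_normalization
  )
}

#' Tidy an exact-simulation run
#'
#' @param x A [simulate_ssa()] object.
#' @param ... Unused.
#' @return The trajectory tibble (`time`, `N1`, `N2`) when recorded,
#'   otherwise the final-state tibble.
#' @export
tidy.demsoc_ssa <- function(x, ...) x$trajectory %||% x$final

#' One-row summary of an exact-simulation run
#'
#' @param x A [simulate_ssa()] object.
#' @param ... Unused.
#' @export
glance.demsoc_ssa <- function(x, ...) {
  tibble::tibble(
    family = x$model$family,
    events = x$events,
    stop_reason = x$stop_reason,
    t_end = x$final$t_end,
    N1 = x$final$N1,
    N2 = x$final$N2,
    mean_density = x$mean_density,
    clamped = x$clamped
  )
}

#' Tidy a frequency-SDE path
#'
#' @param x A [simulate_frequency_sde()] object.
#' @param ... Unused.
#' @export
tidy.demsoc_sde <- function(x, ...) x$path

#' Plot a stationary distribution
#'
#' @param object A [stationary_density()] object.
#' @param ... Unused.
#' @return A ggplot: density against actor frequency, with the
#'   favourability mass annotated.
#' @export
autoplot.demsoc_stationary <- function(object, ...) {
  stopifnot(object$integrable)
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$p,
                                            y = .data$density)) +
    ggplot2::geom_line(colour = "#204a87") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(
      x = "actor frequency p",
      y = expression(pi(p)),
      title = sprintf("%s: mass above 1/2 = %.3f", object$model$family,
                      object$mass_above_half)
    )
}

#' Plot an exact-simulation trajectory
#'
#' @param object A [simulate_ssa()] object with a recorded trajectory.
#' @param ... Unused.
#' @export
autoplot.demsoc_ssa <- function(object, ...) {
  stopifnot(!is.null(object$trajectory))
  long <- tidyr::pivot_longer(object$trajectory, c("N1", "N2"),
                              names_to = "type", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$count,
                                     colour = .data$type)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "individuals", colour = NULL)
}

#' Plot occupancy of a frequency-SDE run against the analytic density
#'
#' @param object A [simulate_frequency_sde()] object.
#' @param stationary Optional [stationary_density()] overlay.
#' @param ... Unused.
#' @export
autoplot.demsoc_sde <- function(object, stationary = NULL, ...) {
  occ <- object$occupancy
  width <- occ$p_mid[2] - occ$p_mid[1]
  g <- ggplot2::ggplot(occ, ggplot2::aes(x = .data$p_mid,
                                         y = .data$mass / width)) +
    ggplot2::geom_col(width = width, fill = "grey70") +
    ggplot2::labs(x = "actor frequency p", y = "occupancy density")
  if (!is.null(stationary)) {
    g <- g + ggplot2::geom_line(
      data = stationary$grid,
      ggplot2::aes(x = .data$p, y = .data$density),
      colour = "#a40000"
    )
  }
  g
}
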