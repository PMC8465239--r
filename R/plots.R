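#' Plot a binned profile
#'
#' Density profiles are drawn per species; order-parameter and tension
#' profiles as a single curve with their natural reference line (0).
#'
#' @param object A `dpd_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dpd_profile <- function(object, ...) {
  q <- attr(object, "quantity") %||% "profile"
  ax <- attr(object, "axis") %||% "z"
  if (q == "density") {
    ggplot2::ggplot(object, ggplot2::aes(.data$z, .data$density,
                                         colour = .data$species)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = paste0(ax, " (rc)"), y = "number density (rc^-3)",
                    colour = "species")
  } else {
    ycol <- intersect(c("p2", "sigma", "vx"), names(object))[1]
    ggplot2::ggplot(object, ggplot2::aes(.data$z, .data[[ycol]])) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = paste0(ax, " (rc)"),
                    y = switch(ycol, p2 = "P2 order parameter",
                               sigma = "tension (kBT/rc^3)",
                               vx = "vx (rc/tau)"))
  }
}

#' Plot the two-branch shear velocity profile with its fits
#'
#' @param object A `shear_fit` from [velocity_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shear_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(.data$z, .data$vx, colour = .data$branch)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$driven)) +
    ggplot2::geom_smooth(data = ~ dplyr::filter(.x, !.data$driven),
                         method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(x = "z (rc)", y = "vx (rc/tau)",
                  shape = "driven slab",
                  title = sprintf("shear rate %.4g", object$shear_rate))
}

#' Plot gyration components and shape factor over time
#'
#' @param object An `rg_series` from [rg_components_series()].
#' @param ... Unused.
#' @return A ggplot faceted by lipid type.
#' @export
autoplot.rg_series <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("rgxx", "rgyy", "rgzz"),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ type, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "step", y = "Rg component (rc)")
}

#' Plot a slab pressure profile
#'
#' @param object A `pressure_profile`.
#' @param ... Unused.
#' @return A ggplot of the three diagonal components against z.
#' @export
autoplot.pressure_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("pxx", "pyy", "pzz"),
                              names_to = "component", values_to = "p")
  ggplot2::ggplot(long, ggplot2::aes(.data$z, .data$p,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (rc)", y = "pressure (kBT/rc^3)")
}

#' Plot a phase diagram over the tail-length grid
#'
#' @param object A `phase_diagram` from [phase_sweep()].
#' @param ... Unused.
#' @return A ggplot tile map of the modal label per cell.
#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot2::ggplot(modal_phase(object),
                  ggplot2::aes(factor(.data$nt1), factor(.data$nt2),
                               fill = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = "NT1 (type-1 tail beads)",
                  y = "NT2 (type-2 beads per tail)", fill = "phase")
}

#' Plot the energy trace of a run
#'
#' @param object A `dpd_run`.
#' @param ... Unused.
#' @return A ggplot of potential, kinetic and total energy against step.
#' @export
autoplot.dpd_run <- function(object, ...) {
  es <- energy_series(object)
  long <- tidyr::pivot_longer(es, c("potential", "kinetic", "total"),
                              names_to = "part", values_to = "energy")
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$energy,
                                     colour = .data$part)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "energy (kBT)")
}
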