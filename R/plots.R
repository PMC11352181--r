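#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated concentration curve
#'
#' @param object a `gut_sim` object.
#' @param ... unused.
#' @return A ggplot of peripheral blood concentration vs time (hours).
#' @method autoplot gut_sim
#' @export
autoplot.gut_sim <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(.data$time_s / 3600, .data$concentration)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(
      x = "Time (h)", y = "Peripheral concentration (mg/L)",
      title = if (!is.null(object$drug)) object$drug$name else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fit against its observations (normalized scale)
#'
#' @param object a `gut_fit` object.
#' @param ... unused.
#' @return A ggplot overlaying the normalized observed points and the
#'   normalized fitted curve.
#' @method autoplot gut_fit
#' @export
autoplot.gut_fit <- function(object, ...) {
  sim_at <- interp_series(object$fitted, object$obs$time_s)
  obs_n <- dplyr::mutate(
    object$obs,
    normalized = .data$concentration / max(.data$concentration)
  )
  fit_n <- dplyr::mutate(
    object$fitted,
    normalized = .data$concentration / max(sim_at)
  )
  ggplot2::ggplot(mapping = ggplot2::aes(.data$time_s / 3600,
                                         .data$normalized)) +
    ggplot2::geom_line(data = fit_n, color = "firebrick") +
    ggplot2::geom_point(data = obs_n, color = "black") +
    ggplot2::labs(
      x = "Time (h)", y = "Normalized concentration",
      title = paste0(object$drug$name, " (", object$dose_mg, " mg), phi = ",
                     signif(object$objective, 3))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the axial permeability profile
#'
#' Shows alpha(x) along the whole intestine for a parameter set, with the
#' jejunum/ileum-colon boundary marked.
#'
#' @param params a `gut_absorption` object.
#' @param phys physiology from [default_physiology()].
#' @param n number of grid points.
#' @return A ggplot.
#' @export
plot_alpha_profile <- function(params, phys = default_physiology(), n = 400) {
  Ltot <- phys$Lj + phys$Li + phys$Lc
  x <- seq(0, Ltot, length.out = n)
  df <- tibble::tibble(
    x_m = x,
    alpha = alpha_profile(x, params, phys),
    segment = ifelse(x < phys$Lj, "jejunum", "ileum-colon")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x_m, .data$alpha,
                                   color = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = phys$Lj, linetype = 2, alpha = 0.5) +
    ggplot2::labs(x = "Axial position (m)", y = "alpha (1/s)",
                  color = NULL) +
    ggplot2::theme_minimal()
}
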