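# ggplot2 graphics for profiles, regions, and the structure-versus-size view.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a profile log-likelihood
#'
#' @param object A `spheroid_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spheroid_profile <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$psi, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = -object$threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$ci, linetype = "dotted") +
    ggplot2::labs(
      x = object$term, y = "normalised profile log-likelihood",
      title = sprintf("%s: %.4g (%.4g, %.4g)", object$term, object$mle,
                      object$ci[1], object$ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a traced confidence-region boundary
#'
#' @param object A `spheroid_region`.
#' @param xlab,ylab Axis labels.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spheroid_region <- function(object, xlab = "parameter 1",
                                     ylab = "parameter 2", ...) {
  ggplot2::ggplot(object$boundary, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = object$mle[1], y = object$mle[2], shape = 3) +
    ggplot2::labs(x = xlab, y = ylab,
                  title = sprintf("%d%% confidence region", round(100 * object$alpha))) +
    ggplot2::theme_minimal()
}

#' Structure as a function of spheroid size
#'
#' Scatter of the measured relative inhibited (`phi`) and necrotic (`eta`)
#' radii against outer radius, coloured by seeding density, with the
#' structural-model curves overlaid when a fit (or parameter pair) is
#' supplied. This is the package's central diagnostic: under the model the
#' inner structure collapses onto a single curve in `R` regardless of
#' seeding density or time.
#'
#' @param data Measurement tibble.
#' @param Q,Rc Optional structural parameters for the overlay.
#' @return A ggplot.
#' @export
plot_structure_size <- function(data, Q = NULL, Rc = NULL) {
  long <- tidyr::pivot_longer(data, c("phi", "eta"), names_to = "component",
                              values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$R_um, y = .data$value,
                                          colour = factor(.data$seeding_density))) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~component, labeller = ggplot2::label_value) +
    ggplot2::labs(x = "outer radius R (µm)", y = "relative radius",
                  colour = "seeding density") +
    ggplot2::theme_minimal()
  if (!is.null(Q) && !is.null(Rc)) {
    Rgrid <- seq(max(1, min(data$R_um) * 0.8), max(data$R_um) * 1.05, length.out = 200)
    st <- spheroid_structure(Rgrid, Q, Rc)
    curve <- tidyr::pivot_longer(st[, c("R", "phi", "eta")], c("phi", "eta"),
                                 names_to = "component", values_to = "value")
    p <- p + ggplot2::geom_line(data = curve,
                                ggplot2::aes(x = .data$R, y = .data$value),
                                inherit.aes = FALSE)
  }
  p
}
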