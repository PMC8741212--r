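# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.spheroid_fit
#' @export
tidy.spheroid_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta_hat), estimate = as.numeric(x$theta_hat))
}

#' Tidy methods for spheroid model objects
#'
#' `tidy()` returns one row per parameter / grid point / boundary vertex;
#' `glance()` returns a one-row model summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.spheroid_fit
NULL

#' @rdname tidy.spheroid_fit
#' @export
glance.spheroid_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$loglik, nobs = x$n,
                 df = length(x$theta_hat), converged = x$converged)
}

#' @rdname tidy.spheroid_fit
#' @export
tidy.spheroid_profile <- function(x, ...) {
  tibble::tibble(term = x$term, psi = x$grid$psi, value = x$grid$value)
}

#' @rdname tidy.spheroid_fit
#' @export
glance.spheroid_profile <- function(x, ...) {
  tibble::tibble(term = x$term, estimate = x$mle,
                 conf.low = x$ci[1], conf.high = x$ci[2],
                 alpha = x$alpha, unbounded = any(x$unbounded))
}

#' @rdname tidy.spheroid_fit
#' @export
tidy.spheroid_lrt <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value)
}

#' @rdname tidy.spheroid_fit
#' @export
tidy.spheroid_region <- function(x, ...) {
  x$boundary
}

#' @rdname tidy.spheroid_fit
#' @export
tidy.phase3_fit <- function(x, ...) {
  tibble::tibble(
    term = c("Rc_emp", "phi_c", "q_R", "q_phi", "q_eta"),
    estimate = c(x$anchor[1], x$anchor[2], x$direction)
  )
}

#' @rdname tidy.spheroid_fit
#' @export
glance.phase3_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, orth_rss = x$orth_rss)
}
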