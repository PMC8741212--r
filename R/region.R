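# Confidence-region boundary tracing by integrating the likelihood
# annihilating field: the rotation of the log-likelihood gradient by 90
# degrees, along which the log-likelihood is constant. A Newton correction
# along the gradient re-projects onto the contour after every step, so
# drift does not accumulate.

num_grad2 <- function(f, x, h = NULL) {
  h <- h %||% pmax(abs(x), 1e-4) * 1e-6
  g <- numeric(2)
  for (i in 1:2) {
    e <- numeric(2); e[i] <- h[i]
    g[i] <- (f(x + e) - f(x - e)) / (2 * h[i])
  }
  g
}

# Newton steps along the gradient until |f - target| < tol.
project_to_contour <- function(f, x, target, gradient, tol = 1e-10, maxit = 30) {
  for (k in seq_len(maxit)) {
    fx <- f(x)
    if (!is.finite(fx)) return(NULL)
    if (abs(fx - target) < tol) return(x)
    g <- gradient(x)
    ng2 <- sum(g^2)
    if (ng2 < 1e-300) return(NULL)
    x <- x + (target - fx) / ng2 * g
  }
  if (abs(f(x) - target) < 1e-6) x else NULL
}

#' Trace the boundary of a two-dimensional confidence region
#'
#' Finds a boundary point by bisection along a ray from the maximiser until
#' the log-likelihood has dropped by `wilks_threshold(alpha, nu)`, then
#' traces the level set by integrating the rotated-gradient (likelihood
#' annihilating) field with an adaptive arc-length step and a Newton
#' re-projection onto the contour at every step. Tracing terminates when the
#' path returns to within one step of the start point (closed contour) or
#' leaves the bounds (open contour, flagged).
#'
#' @param objective Function of a length-2 parameter returning the
#'   log-likelihood.
#' @param mle Length-2 maximiser of `objective`.
#' @param alpha Confidence level (default 0.95).
#' @param nu Degrees of freedom for the threshold (default 2; use 3 for
#'   fixed-coordinate slices of a 3-parameter region).
#' @param gradient Optional analytic gradient; central differences otherwise.
#' @param step Initial arc-length step; defaults to a scale set by the
#'   distance from the MLE to the boundary.
#' @param lower,upper Optional box bounds; the contour is reported open if
#'   it leaves the box.
#' @param ray Unit direction in which to search for the first boundary point
#'   (default the first coordinate axis).
#' @param max_steps Safety cap on the number of trace steps.
#' @return An object of class `spheroid_region`: `boundary` (tibble x, y),
#'   `level` (target log-likelihood), `closed` flag, `alpha`, `nu`, `mle`.
#' @export
trace_confidence_region <- function(objective, mle, alpha = 0.95, nu = 2,
                                    gradient = NULL, step = NULL,
                                    lower = c(-Inf, -Inf), upper = c(Inf, Inf),
                                    ray = c(1, 0), max_steps = 5000) {
  # Parameters can differ by orders of magnitude in scale; trace in
  # curvature-scaled coordinates so arc-length steps are isotropic.
  scale <- tryCatch(plugin_se(objective, as.numeric(mle)), error = function(e) NULL)
  if (is.null(scale) || any(!is.finite(scale)) || any(scale <= 0)) {
    scale <- pmax(abs(as.numeric(mle)), 1) * 0.05
  }
  mle <- as.numeric(mle) / scale
  lower <- lower / scale
  upper <- upper / scale
  f <- function(u) {
    v <- objective(u * scale)
    if (is.finite(v)) v else -Inf
  }
  gr <- if (is.null(gradient)) {
    function(u) num_grad2(f, u)
  } else {
    function(u) gradient(u * scale) * scale
  }
  ll_hat <- f(mle)
  if (!is.finite(ll_hat)) abort("Objective is not finite at `mle`.")
  target <- ll_hat - wilks_threshold(alpha, nu)
  ray <- ray / sqrt(sum(ray^2))

  # bracket along the ray: expand until below target, then bisect
  # (in scaled coordinates the boundary sits at distance ~sqrt(2 * drop))
  fb <- function(x) if (all(x > lower) && all(x < upper)) f(x) else -Inf
  t_hi <- 1
  for (k in 1:200) {
    if (fb(mle + t_hi * ray) < target) break
    t_hi <- t_hi * 1.6
  }
  t_lo <- 0
  for (k in 1:200) {
    mid <- (t_lo + t_hi) / 2
    v <- fb(mle + mid * ray)
    if (is.finite(v) && v > target) t_lo <- mid else t_hi <- mid
    if ((t_hi - t_lo) < 1e-14 * max(1, t_hi)) break
  }
  x0 <- project_to_contour(f, mle + 0.5 * (t_lo + t_hi) * ray, target, gr)
  if (is.null(x0)) abort("Failed to locate a boundary point along the ray.")

  h <- step %||% (0.5 * (t_lo + t_hi) * 0.05)
  pts <- list(x0)
  x <- x0
  closed <- FALSE
  for (k in seq_len(max_steps)) {
    g <- gr(x)
    ng <- sqrt(sum(g^2))
    if (ng < 1e-300) break
    tanv <- c(-g[2], g[1]) / ng    # rotate gradient: constant-likelihood direction
    xn <- x + h * tanv
    if (!(all(xn > lower) && all(xn < upper))) {
      closed <- FALSE
      break
    }
    xp <- project_to_contour(f, xn, target, gr)
    if (is.null(xp)) {
      h <- h / 2
      if (h < 1e-12) break
      next
    }
    corr <- sqrt(sum((xp - xn)^2))
    if (corr > 0.2 * h) {  # curvature too high for this step
      h <- h / 2
      if (h < 1e-12) break
      next
    }
    x <- xp
    pts[[length(pts) + 1]] <- x
    if (corr < 0.01 * h) h <- min(h * 1.3, 0.5 * (t_lo + t_hi) * 0.2)
    if (k > 5 && sqrt(sum((x - x0)^2)) < 1.2 * h) {
      closed <- TRUE
      break
    }
  }
  boundary <- tibble::tibble(
    x = vapply(pts, `[[`, numeric(1), 1) * scale[1],
    y = vapply(pts, `[[`, numeric(1), 2) * scale[2]
  )
  if (closed) boundary <- dplyr::bind_rows(boundary, boundary[1, ])
  structure(list(boundary = boundary, level = target, closed = closed,
                 alpha = alpha, nu = nu, mle = mle * scale, loglik_hat = ll_hat),
            class = "spheroid_region")
}

#' @export
print.spheroid_region <- function(x, ...) {
  cat(sprintf("<spheroid_region> %d%% region, %d boundary points, %s contour\n",
              round(100 * x$alpha), nrow(x$boundary),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Three-dimensional confidence region as two-dimensional slices
#'
#' Constructs an `alpha`-level region for a 3-parameter model as a sequence
#' of two-dimensional contours: one coordinate is fixed on a grid through
#' the maximiser and the remaining two are traced at the 3-degree-of-freedom
#' threshold. Slices on which the conditional maximum falls below the
#' threshold lie outside the region and are returned empty.
#'
#' @param objective Function of a length-3 parameter returning the
#'   log-likelihood.
#' @param mle Length-3 maximiser.
#' @param slice_on Index (1-3) of the coordinate to fix.
#' @param n_slices Number of slices (default 7).
#' @param half_width Half-range of the slice grid around the MLE coordinate;
#'   defaults to 3 curvature-based standard errors.
#' @param alpha Confidence level.
#' @param lower,upper Length-3 box bounds.
#' @return A tibble with columns `slice` (fixed coordinate value) and
#'   `region` (list of `spheroid_region` or `NULL` for empty slices).
#' @export
slice_region_3d <- function(objective, mle, slice_on = 3, n_slices = 7,
                            half_width = NULL, alpha = 0.95,
                            lower = rep(-Inf, 3), upper = rep(Inf, 3)) {
  stopifnot(length(mle) == 3)
  thr <- wilks_threshold(alpha, 3)
  ll_hat <- objective(mle)
  if (is.null(half_width)) {
    se <- plugin_se(objective, as.numeric(mle))
    half_width <- 3 * se[slice_on]
  }
  vals <- seq(mle[slice_on] - half_width, mle[slice_on] + half_width,
              length.out = n_slices)
  vals <- vals[vals > lower[slice_on] & vals < upper[slice_on]]
  free <- setdiff(1:3, slice_on)
  regions <- purrr::map(vals, function(v) {
    obj2 <- function(x2) {
      th <- numeric(3)
      th[slice_on] <- v
      th[free] <- x2
      objective(th)
    }
    # conditional maximum within the slice
    neg <- function(x2) { o <- obj2(x2); if (is.finite(o)) -o else 1e15 }
    cm <- stats::optim(as.numeric(mle[free]), neg, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 2000))
    if (-cm$value < ll_hat - thr) return(NULL)  # slice outside the region
    # contour at the absolute level set by the full-model maximum
    trace_slice_at_level(obj2, cm$par, ll_hat - thr, lower[free], upper[free])
  })
  tibble::tibble(slice = vals, region = regions)
}

# Trace a contour of obj2 at an absolute log-likelihood level (used for
# slices, where the threshold references the full-model maximum).
trace_slice_at_level <- function(obj2, cmax, level, lower, upper) {
  drop <- obj2(cmax) - level
  if (drop <= 0) return(NULL)
  alpha_eff <- stats::pchisq(2 * drop, df = 2)
  trace_confidence_region(obj2, cmax, alpha = alpha_eff, nu = 2,
                          lower = lower, upper = upper)
}
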