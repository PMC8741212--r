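#' Log-likelihood drop defining a Wilks confidence set
#'
#' By Wilks' theorem, an approximate `alpha`-level confidence set for a
#' `nu`-dimensional parameter is the region where the normalised
#' log-likelihood stays above `-qchisq(alpha, nu) / 2`. For a univariate
#' 95% profile interval the drop is about 1.92.
#'
#' @param alpha Confidence level in (0, 1), e.g. 0.95.
#' @param nu Degrees of freedom (>= 1).
#' @return The log-likelihood drop `qchisq(alpha, nu) / 2`.
#' @export
#' @examples
#' wilks_threshold(0.95, 1) # ~1.9207
wilks_threshold <- function(alpha = 0.95, nu = 1) {
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must lie in (0, 1).")
  if (nu < 1) abort("`nu` must be >= 1.")
  stats::qchisq(alpha, df = nu) / 2
}

# Profile the objective at fixed psi (parameter `index`), optimising the
# nuisance parameters from a warm start. Returns list(value, nuisance).
profile_point <- function(objective, index, psi, nuisance_start, lower, upper,
                          reltol = 1e-10) {
  d <- length(lower)
  free <- setdiff(seq_len(d), index)
  if (length(free) == 0) {
    return(list(value = objective(psi), nuisance = numeric(0)))
  }
  build <- function(lam) {
    th <- numeric(d)
    th[index] <- psi
    th[free] <- lam
    th
  }
  lo <- lower[free]; up <- upper[free]
  neg <- function(lam) {
    v <- objective(build(pmin(up - 1e-12, pmax(lo + 1e-12, lam))))
    if (!is.finite(v)) 1e15 else -v
  }
  start <- pmin(up - 1e-9, pmax(lo + 1e-9, nuisance_start))
  res <- stats::optim(start, neg, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = reltol))
  lam <- pmin(up - 1e-12, pmax(lo + 1e-12, res$par))
  list(value = objective(build(lam)), nuisance = lam)
}

# Plug-in standard errors from the curvature of the objective at theta_hat.
plugin_se <- function(objective, theta_hat, rel_h = 1e-4) {
  d <- length(theta_hat)
  h <- pmax(abs(theta_hat), 1e-3) * rel_h
  H <- matrix(NA_real_, d, d)
  f0 <- objective(theta_hat)
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- ej <- numeric(d); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (objective(theta_hat + ei) - 2 * f0 + objective(theta_hat - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <- (objective(theta_hat + ei + ej) - objective(theta_hat + ei - ej) -
          objective(theta_hat - ei + ej) + objective(theta_hat - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V) || any(diag(V) <= 0)) {
    return(pmax(abs(theta_hat), 1) * 0.1) # fall back to a coarse scale
  }
  sqrt(diag(V))
}

#' Profile log-likelihood and confidence interval for one parameter
#'
#' Profiles the fitted model's log-likelihood over a grid in the interest
#' parameter, maximising the nuisance parameters at each grid point with a
#' warm start from the adjacent point (sweeping outward from the MLE in both
#' directions), then locates the `alpha`-level interval endpoints by
#' bisection where the normalised profile crosses
#' `-wilks_threshold(alpha, 1)`. The grid spans the MLE plus/minus `span`
#' plug-in standard errors (41 points by default) and is extended adaptively
#' until the profile drops below the threshold; endpoints that hit the
#' parameter bounds first are flagged unbounded.
#'
#' @param fit A `spheroid_fit` from [fit_spheroid_model()].
#' @param parm Parameter name or index to profile.
#' @param alpha Confidence level (default 0.95).
#' @param n_grid Number of grid points (default 41).
#' @param span Half-width of the initial grid in standard errors (default 4).
#' @param lower,upper Optional parameter bounds (defaults from the model).
#' @param ci_rel_tol Bisection tolerance for the interval endpoints,
#'   relative to the plug-in standard error (default 1e-4).
#' @return An object of class `spheroid_profile`: tibble `grid` with columns
#'   `psi`, `value` (normalised profile, max 0) and list-column `nuisance`;
#'   plus `ci` (lower, upper), `unbounded` flags, `term`, `alpha`,
#'   `threshold`, `mle`.
#' @export
profile_likelihood <- function(fit, parm, alpha = 0.95, n_grid = 41, span = 4,
                               lower = NULL, upper = NULL, ci_rel_tol = 1e-4) {
  spec <- fit$spec
  d <- length(fit$theta_hat)
  index <- if (is.character(parm)) match(parm, spec$par_names) else as.integer(parm)
  if (is.na(index) || index < 1 || index > d) abort("Unknown parameter in `parm`.")
  b <- spec$default_bounds(fit$data)
  lower <- lower %||% b$lower
  upper <- upper %||% b$upper
  objective <- fit$objective
  theta_hat <- as.numeric(fit$theta_hat)
  ll_hat <- fit$loglik
  thr <- wilks_threshold(alpha, 1)
  se <- plugin_se(objective, theta_hat)[index]

  prof_val <- function(psi, start) {
    pr <- profile_point(objective, index, psi, start, lower, upper)
    list(value = pr$value - ll_hat, nuisance = pr$nuisance)
  }

  # sweep one side (dir = +1 / -1), warm-started; extend until below -thr
  sweep_side <- function(dir) {
    width <- span * se
    psis <- theta_hat[index] + dir * seq(0, width, length.out = ceiling(n_grid / 2))[-1]
    lim <- if (dir > 0) upper[index] else lower[index]
    psis <- psis[if (dir > 0) psis < lim else psis > lim]
    rows <- list()
    start <- theta_hat[-index]
    last_psi <- theta_hat[index]
    extensions <- 0
    repeat {
      for (psi in psis) {
        pr <- prof_val(psi, start)
        rows[[length(rows) + 1]] <- list(psi = psi, value = pr$value, nuisance = pr$nuisance)
        start <- if (length(pr$nuisance)) pr$nuisance else start
        last_psi <- psi
        if (pr$value < -thr - 0.5) break # safely past the threshold
      }
      vals <- vapply(rows, `[[`, numeric(1), "value")
      if (any(vals <= -thr) || extensions >= 6) break
      step <- se * span / max(1, ceiling(n_grid / 2) - 1)
      nxt <- last_psi + dir * step * (1:5)
      nxt <- nxt[if (dir > 0) nxt < lim else nxt > lim]
      if (length(nxt) == 0) break
      psis <- nxt
      extensions <- extensions + 1
    }
    rows
  }
  up_rows <- sweep_side(+1)
  dn_rows <- sweep_side(-1)
  row_tbl <- function(r) tibble::tibble(psi = r$psi, value = r$value,
                                        nuisance = list(r$nuisance))
  grid <- dplyr::bind_rows(
    purrr::map(rev(dn_rows), row_tbl),
    tibble::tibble(psi = theta_hat[index], value = 0, nuisance = list(theta_hat[-index])),
    purrr::map(up_rows, row_tbl)
  )

  # CI endpoints: bisection on the profile at -thr within bracketing grid cells
  find_endpoint <- function(dir) {
    side <- if (dir > 0) grid[grid$psi >= theta_hat[index], ] else
      grid[grid$psi <= theta_hat[index], ]
    side <- side[order(side$psi * dir), ]
    below <- which(side$value <= -thr)
    if (length(below) == 0) {
      return(list(value = if (dir > 0) upper[index] else lower[index], unbounded = TRUE))
    }
    i1 <- below[1]
    if (i1 == 1) return(list(value = side$psi[1], unbounded = FALSE))
    a <- side$psi[i1 - 1]; fa <- side$value[i1 - 1]
    bb <- side$psi[i1]; fb <- side$value[i1]
    start <- side$nuisance[[i1 - 1]]
    for (k in 1:40) {
      mid <- (a + bb) / 2
      pr <- prof_val(mid, start)
      start <- if (length(pr$nuisance)) pr$nuisance else start
      if (pr$value > -thr) { a <- mid; fa <- pr$value } else { bb <- mid; fb <- pr$value }
      if (abs(bb - a) < ci_rel_tol * max(1e-8, se)) break
    }
    list(value = (a + bb) / 2, unbounded = FALSE)
  }
  hi <- find_endpoint(+1)
  lo <- find_endpoint(-1)

  structure(list(
    term = spec$par_names[index],
    grid = grid,
    ci = c(lower = lo$value, upper = hi$value),
    unbounded = c(lower = lo$unbounded, upper = hi$unbounded),
    alpha = alpha,
    threshold = thr,
    mle = theta_hat[index],
    se = se
  ), class = "spheroid_profile")
}

#' @export
print.spheroid_profile <- function(x, ...) {
  cat(sprintf("<spheroid_profile: %s>\n", x$term))
  cat(sprintf("MLE %.4g, %d%% CI (%.4g, %.4g)%s\n", x$mle, round(100 * x$alpha),
              x$ci[1], x$ci[2],
              if (any(x$unbounded)) " [unbounded endpoint]" else ""))
  invisible(x)
}
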