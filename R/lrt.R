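# Likelihood-ratio equivalence tests between experimental groups
# (typically seeding densities). The statistic is
#   T = 2 * (sum_g l(theta_hat_g) - l(theta_hat_*)) ~ chi2(nu),
# where theta_hat_* is fitted to all groups jointly under the null of a
# shared parameter vector, and nu counts the additional free parameters in
# the group-wise (alternative) fit.

new_lrt <- function(T, nu, p, fits = NULL, null_fit = NULL) {
  if (T < 0) {
    if (T > -1e-6) {
      T <- 0
    } else {
      warn(sprintf("Negative LRT statistic (%.3g) beyond optimiser tolerance; clipping at 0.", T))
      T <- 0
    }
  }
  structure(list(statistic = T, df = nu, p.value = p %||% stats::pchisq(T, nu, lower.tail = FALSE),
                 fits = fits, null_fit = null_fit),
            class = "spheroid_lrt")
}

#' @export
print.spheroid_lrt <- function(x, ...) {
  cat(sprintf("<spheroid_lrt> T = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

split_groups <- function(data, group) {
  gvar <- rlang::enquo(group)
  groups <- as.list(dplyr::group_split(dplyr::group_by(data, !!gvar)))
  if (length(groups) < 2) abort("Need at least 2 groups for an equivalence test.")
  labels <- vapply(groups, function(g) as.character(dplyr::pull(g, !!gvar)[1]), character(1))
  stats::setNames(groups, labels)
}

group_sigmas <- function(groups, Sigma = NULL, covariance = c("per_group", "pooled")) {
  covariance <- match.arg(covariance)
  if (!is.null(Sigma)) return(lapply(groups, function(g) Sigma))
  if (covariance == "pooled") {
    m <- dplyr::bind_rows(lapply(groups, function(g) {
      X <- obs_matrix(g)
      tibble::tibble(n = nrow(X), Sigma = list(stats::cov(X)))
    }))
    Sp <- pooled_covariance(m)
    lapply(groups, function(g) Sp)
  } else {
    lapply(groups, function(g) stats::cov(obs_matrix(g)))
  }
}

#' Likelihood-ratio test for parameter equivalence across groups
#'
#' Tests whether one shared parameter vector describes all groups (the null)
#' against group-specific parameters (the alternative). Each group keeps its
#' own plug-in covariance (or the pooled covariance, as used for
#' steady-state analyses); only the model parameters are shared under the
#' null. Degrees of freedom: `(G - 1) * dim(theta)`.
#'
#' @param data Measurement tibble containing all groups.
#' @param group Grouping column (unquoted), e.g. `seeding_density`.
#' @param model Model name passed to [fit_spheroid_model()].
#' @param Sigma Optional fixed covariance used for every group.
#' @param covariance `"per_group"` (default) or `"pooled"` plug-in
#'   covariance when `Sigma` is not given.
#' @param n_starts Multi-start count for the joint (null) fit.
#' @return A `spheroid_lrt` object: `statistic`, `df`, `p.value`, plus the
#'   group fits and the null fit.
#' @export
lrt_equivalence <- function(data, group, model = "steady_state", Sigma = NULL,
                            covariance = c("per_group", "pooled"), n_starts = 4) {
  groups <- split_groups(data, {{ group }})
  sigmas <- group_sigmas(groups, Sigma, covariance)
  spec <- model_spec(model)
  fits <- purrr::map2(groups, sigmas, function(g, S) {
    fit_spheroid_model(g, model, Sigma = S)
  })
  ll_alt <- sum(vapply(fits, function(f) f$loglik, numeric(1)))
  d <- length(spec$par_names)

  objs <- purrr::map2(groups, sigmas, function(g, S) make_objective(model, g, S))
  joint_obj <- function(theta) {
    sum(vapply(objs, function(o) o(theta), numeric(1)))
  }
  # start from the inversion of the pooled mean and from each group MLE
  all_X <- obs_matrix(dplyr::bind_rows(groups))
  b <- spec$default_bounds(dplyr::bind_rows(groups))
  theta0 <- spec$closed_mle(colMeans(all_X))
  starts <- c(list(theta0), lapply(fits, function(f) as.numeric(f$theta_hat)))
  starts <- purrr::compact(starts)
  best <- NULL
  for (s in starts) {
    if (!is.finite(joint_obj(s))) next
    res <- maximize_likelihood(joint_obj, b$lower, b$upper, theta0 = s, n_starts = 0)
    if (is.null(best) || res$loglik_hat > best$loglik_hat) best <- res
  }
  if (is.null(best)) {
    res <- maximize_likelihood(joint_obj, b$lower, b$upper, n_starts = n_starts)
    best <- res
  }
  ll_null <- best$loglik_hat
  G <- length(groups)
  nu <- (G - 1) * d
  new_lrt(2 * (ll_alt - ll_null), nu, NULL, fits = fits,
          null_fit = stats::setNames(as.numeric(best$theta_hat), spec$par_names))
}

#' Likelihood-ratio test for equivalence of a single parameter
#'
#' The null model shares only the indexed parameter across groups; all other
#' parameters remain free per group. One degree of freedom per extra group.
#'
#' @inheritParams lrt_equivalence
#' @param parm Parameter name or index to constrain equal across groups.
#' @return A `spheroid_lrt` object.
#' @export
lrt_single_parameter <- function(data, group, parm, model = "steady_state",
                                 Sigma = NULL, covariance = c("per_group", "pooled")) {
  groups <- split_groups(data, {{ group }})
  sigmas <- group_sigmas(groups, Sigma, covariance)
  spec <- model_spec(model)
  d <- length(spec$par_names)
  index <- if (is.character(parm)) match(parm, spec$par_names) else as.integer(parm)
  if (is.na(index) || index < 1 || index > d) abort("Unknown parameter in `parm`.")
  fits <- purrr::map2(groups, sigmas, function(g, S) fit_spheroid_model(g, model, Sigma = S))
  ll_alt <- sum(vapply(fits, function(f) f$loglik, numeric(1)))
  G <- length(groups)
  b <- spec$default_bounds(dplyr::bind_rows(groups))

  # null: profile the shared parameter; nuisances optimised per group
  objs <- purrr::map2(groups, sigmas, function(g, S) make_objective(model, g, S))
  null_profile <- function(psi) {
    sum(vapply(seq_len(G), function(i) {
      pr <- profile_point(objs[[i]], index, psi, as.numeric(fits[[i]]$theta_hat)[-index],
                          b$lower, b$upper)
      pr$value
    }, numeric(1)))
  }
  psis <- vapply(fits, function(f) as.numeric(f$theta_hat)[index], numeric(1))
  pad <- max(diff(range(psis)), 0.05 * abs(mean(psis)), 1e-5)
  interval <- c(max(b$lower[index] + 1e-9, min(psis) - pad),
                min(b$upper[index] - 1e-9, max(psis) + pad))
  opt <- stats::optimize(function(p) -null_profile(p), interval = interval, tol = 1e-9)
  ll_null <- -opt$objective
  new_lrt(2 * (ll_alt - ll_null), G - 1, NULL, fits = fits,
          null_fit = opt$minimum)
}
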