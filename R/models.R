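# Model registry: each fit-able model exposes its parameter names, bounds,
# objective, and (where available) a closed-form MLE. All three models are
# saturated 3-parameter descriptions of a 3-dimensional mean, which is why
# closed-form MLEs via the sample mean exist whenever the inversion is
# feasible.

model_spec <- function(model = c("statistical", "steady_state", "structural")) {
  model <- match.arg(model)
  switch(model,
    statistical = list(
      model = "statistical",
      par_names = c("R", "phi", "eta"),
      objective = function(theta, data, Sigma) loglik_mean(data, theta, Sigma),
      mean_fn = function(theta) theta,
      closed_mle = function(xbar) xbar,
      default_bounds = function(data) {
        X <- obs_matrix(data)
        list(lower = c(max(1e-3, min(X[, 1]) * 0.2), 0, 0),
             upper = c(max(X[, 1]) * 2, 1, 1))
      }
    ),
    steady_state = list(
      model = "steady_state",
      par_names = c("Q", "Rc", "gamma"),
      objective = function(theta, data, Sigma) loglik_steady_state(theta, data, Sigma),
      mean_fn = function(theta) steady_state_mu(theta),
      closed_mle = function(xbar) {
        fit <- tryCatch(invert_steady_state(xbar[1], xbar[2], xbar[3]),
                        error = function(e) NULL)
        if (is.null(fit)) NULL else c(Q = fit$Q, Rc = fit$Rc, gamma = fit$gamma)
      },
      default_bounds = function(data) {
        X <- obs_matrix(data)
        list(lower = c(1e-3, 1, 1e-3),
             upper = c(1 - 1e-6, max(X[, 1]) * 2, 20))
      }
    ),
    structural = list(
      model = "structural",
      par_names = c("R", "Q", "Rc"),
      objective = function(theta, data, Sigma) loglik_structural(theta, data, Sigma),
      mean_fn = function(theta) {
        st <- spheroid_structure(theta[1], theta[2], theta[3])
        c(theta[1], st$phi, st$eta)
      },
      closed_mle = function(xbar) {
        fit <- tryCatch(invert_structure(xbar[1], xbar[2], xbar[3]),
                        error = function(e) NULL)
        if (is.null(fit)) NULL else c(R = xbar[1], Q = fit$Q, Rc = fit$Rc)
      },
      default_bounds = function(data) {
        X <- obs_matrix(data)
        list(lower = c(max(1e-3, min(X[, 1]) * 0.2), 1e-3, 1),
             upper = c(max(X[, 1]) * 2, 1 - 1e-6, max(X[, 1]) * 2))
      }
    )
  )
}

# Fast log-likelihood closure over fixed data and covariance. With Sigma
# fixed, l(mu) = const - (n/2) (xbar - mu)' Sigma^-1 (xbar - mu), so only
# the model mean needs recomputing per evaluation. Falls back to the
# general path when Sigma has (near-)zero variances.
make_objective <- function(model, data, Sigma) {
  spec <- model_spec(model)
  X <- obs_matrix(data)
  if (any(diag(Sigma) <= 1e-12)) {
    return(function(theta) {
      v <- spec$objective(theta, data, Sigma)
      as.numeric(v)
    })
  }
  n <- nrow(X)
  xbar <- colMeans(X)
  Sinv <- solve(Sigma)
  Xc <- sweep(X, 2, xbar)
  const <- -0.5 * n * (3 * log(2 * pi) + determinant(Sigma)$modulus[1]) -
    0.5 * sum((Xc %*% Sinv) * Xc)
  mean_fast <- switch(model,
    statistical = function(theta) {
      if (all(is.finite(theta)) && theta[1] > 0) theta else NULL
    },
    steady_state = steady_state_mu,
    structural = function(theta) {
      if (!all(is.finite(theta)) || theta[1] <= 0 || theta[2] <= 0 ||
          theta[2] >= 1 || theta[3] <= 0) {
        return(NULL)
      }
      structure_mu(theta[1], theta[2], theta[3])
    }
  )
  function(theta) {
    mu <- mean_fast(theta)
    if (is.null(mu)) return(-Inf)
    d <- xbar - mu
    const - 0.5 * n * as.numeric(d %*% Sinv %*% d)
  }
}

# Resolve the plug-in covariance for a fit: user-supplied, or the sample
# covariance of `data` (optionally pooled over groups of `pool_by`).
resolve_sigma <- function(data, Sigma = NULL, pool_by = NULL) {
  if (!is.null(Sigma)) {
    stopifnot(all(dim(Sigma) == c(3, 3)))
    return(Sigma)
  }
  if (!is.null(pool_by)) {
    m <- sample_moments(dplyr::group_by(data, dplyr::across(dplyr::all_of(pool_by))))
    return(pooled_covariance(m))
  }
  stats::cov(obs_matrix(data))
}
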