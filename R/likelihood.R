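# Multivariate-normal log-likelihoods connecting the deterministic model to
# noisy structure measurements.

# Log-density of rows of X under N(mu, Sigma), summed. Coordinates whose
# variance is (numerically) zero are dropped with a warning, provided the
# data agree with the mean there; this keeps phase-1/2 records (phi or eta
# exactly 0 with no spread) usable.
mvn_loglik <- function(X, mu, Sigma, zero_tol = 1e-12) {
  d <- diag(Sigma)
  keep <- d > zero_tol
  if (!all(keep)) {
    dropped <- which(!keep)
    bad <- abs(sweep(X[, dropped, drop = FALSE], 2, mu[dropped])) > 1e-8
    if (any(bad)) {
      abort("Zero-variance coordinate(s) disagree with the mean: likelihood is degenerate.")
    }
    warn(sprintf(
      "Dropping zero-variance coordinate(s) %s from the likelihood.",
      paste(obs_cols[dropped], collapse = ", ")
    ))
    X <- X[, keep, drop = FALSE]
    mu <- mu[keep]
    Sigma <- Sigma[keep, keep, drop = FALSE]
  }
  k <- length(mu)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    abort(sprintf("Covariance is not positive definite (smallest eigenvalue %.3g).", ev))
  }
  Z <- backsolve(ch, t(X) - mu, transpose = TRUE)
  -0.5 * nrow(X) * (k * log(2 * pi) + 2 * sum(log(diag(ch)))) - 0.5 * sum(Z^2)
}

#' Multivariate-normal log-likelihood of structure observations
#'
#' Sum over observations of the trivariate normal log-density
#' \eqn{\ell(\mu; X) = \sum_i \log f(x_i; \mu, \Sigma)} with plug-in
#' covariance. This is the "statistical model": `mu` is the free mean of
#' `(R, phi, eta)` with no mechanistic constraint.
#'
#' @param data Measurement tibble (columns `R_um`, `phi`, `eta`).
#' @param mu Length-3 mean vector `(R, phi, eta)`.
#' @param Sigma 3x3 positive-definite covariance.
#' @return Scalar log-likelihood.
#' @export
loglik_mean <- function(data, mu, Sigma) {
  X <- obs_matrix(data)
  stopifnot(length(mu) == 3, all(dim(Sigma) == c(3, 3)))
  mvn_loglik(X, as.numeric(mu), Sigma)
}

#' Log-likelihood of the steady-state (mechanistic) model
#'
#' Substitutes the steady-state map for the mean, `mu = m(theta)` with
#' `theta = (Q, Rc, gamma)`, in the observation model. Parameter values with
#' no phase-3 steady state (or outside the valid domain) yield `-Inf` with
#' attribute `no_steady_state = TRUE`, so optimisers can recover.
#'
#' @param theta Numeric vector `(Q, Rc, gamma)`.
#' @inheritParams loglik_mean
#' @return Scalar log-likelihood.
#' @export
loglik_steady_state <- function(theta, data, Sigma) {
  if (!all(is.finite(theta)) || theta[1] <= 0 || theta[1] >= 1 ||
      theta[2] <= 0 || theta[3] <= 0) {
    out <- -Inf
    attr(out, "no_steady_state") <- TRUE
    return(out)
  }
  mu <- steady_state_mu(theta)
  if (is.null(mu)) {
    out <- -Inf
    attr(out, "no_steady_state") <- TRUE
    return(out)
  }
  mvn_loglik(obs_matrix(data), mu, Sigma)
}

#' Log-likelihood of the structural model at one observation time
#'
#' Parameters are `(R, Q, Rc)`: the mean outer radius plus the structural
#' parameters; the mean structure is `(R, phi(R), eta(R))` through the
#' structural model. Applies at any time point (no steady-state assumption),
#' so `gamma` does not enter.
#'
#' @param theta Numeric vector `(R, Q, Rc)`.
#' @inheritParams loglik_mean
#' @return Scalar log-likelihood.
#' @export
loglik_structural <- function(theta, data, Sigma) {
  if (!all(is.finite(theta)) || theta[1] <= 0 ||
      theta[2] <= 0 || theta[2] >= 1 || theta[3] <= 0) {
    return(-Inf)
  }
  st <- spheroid_structure(theta[1], theta[2], theta[3])
  mvn_loglik(obs_matrix(data), c(theta[1], st$phi, st$eta), Sigma)
}

#' Gradient of the steady-state log-likelihood in parameter space
#'
#' Chain rule through the steady-state map:
#' \eqn{\nabla_\theta \ell = J_m(\theta)^\top \nabla_\mu \ell(m(\theta))},
#' with the analytic implicit-differentiation Jacobian
#' ([steady_state_jacobian()]) and the closed-form mean-space gradient
#' \eqn{\nabla_\mu \ell = n \Sigma^{-1}(\bar x - \mu)}.
#'
#' @inheritParams loglik_steady_state
#' @return Length-3 gradient vector.
#' @export
grad_loglik_steady_state <- function(theta, data, Sigma) {
  J <- steady_state_jacobian(theta[1], theta[2], theta[3])
  mu <- steady_state_mu(theta)
  X <- obs_matrix(data)
  grad_mu <- nrow(X) * solve(Sigma, colMeans(X) - mu)
  as.numeric(t(J) %*% grad_mu)
}
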