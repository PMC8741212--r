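# Empirical linear model for phase-3 trajectories in (R, phi, eta) space:
#   x(tau) = (Rc_emp, phi_c, 0) + tau * qhat,   tau >= 0 at necrosis onset,
# fitted by total least squares with a latent progression variable tau per
# observation. With multivariate-normal noise of fixed covariance Sigma,
# profiling out the tau_i reduces the maximum-likelihood line to the
# principal axis of the Sigma-whitened centred data, de-whitened back.

#' Select phase-3 observations
#'
#' Phase-3 records are those with a detectable necrotic core. The selection
#' rule is a configurable threshold on the measured relative necrotic
#' radius.
#'
#' @param data Measurement tibble.
#' @param eta_min Threshold on `eta` (default 0.01).
#' @return The selected rows; errors if the selection is empty. The number
#'   selected is reported via a message.
#' @export
select_phase3 <- function(data, eta_min = 0.01) {
  out <- dplyr::filter(data, .data$eta > eta_min)
  if (nrow(out) == 0) abort("No phase-3 observations (all eta <= eta_min).")
  inform(sprintf("Selected %d of %d observations with eta > %g.",
                 nrow(out), nrow(data), eta_min))
  out
}

# Core TLS solve for fixed Sigma. Returns list(anchor, direction, tau,
# loglik, ...). Direction sign: eta component > 0 (tau grows with eta).
tls_line <- function(X, Sigma) {
  n <- nrow(X)
  L <- t(chol(Sigma))          # Sigma = L L'
  W <- forwardsolve(L, diag(3))  # whitener: z = W x has identity covariance noise
  Z <- X %*% t(W)
  zbar <- colMeans(Z)
  Zc <- sweep(Z, 2, zbar)
  sv <- svd(Zc)
  if (sv$d[1] < 1e-12 || (sv$d[1] - sv$d[2]) / max(sv$d[1], 1e-300) < 1e-9) {
    abort("Degenerate direction: data are isotropic after whitening.")
  }
  w <- sv$v[, 1]               # principal axis in whitened space
  # the whitened line z = zbar + t w maps back through x = L z
  q <- as.numeric(L %*% w)
  q <- q / sqrt(sum(q^2))
  if (q[3] < 0) q <- -q
  if (abs(q[3]) < 1e-10) {
    abort("Fitted direction has no eta component; anchor at eta = 0 is undefined.")
  }
  xbar <- as.numeric(L %*% zbar)
  # latent tau per observation: Sigma-metric projection onto the line
  Sinv_q <- solve(Sigma, q)
  denom <- sum(q * Sinv_q)
  t_from <- function(a) as.numeric((X - matrix(a, n, 3, byrow = TRUE)) %*% Sinv_q) / denom
  # anchor: the point on the line where the eta component is zero
  t0 <- -xbar[3] / q[3]
  anchor <- xbar + t0 * q
  tau <- t_from(anchor)
  resid <- X - (matrix(anchor, n, 3, byrow = TRUE) + tau %*% t(q))
  Zr <- resid %*% t(W)
  rss <- sum(Zr^2)             # whitened orthogonal residual sum of squares
  ll <- -0.5 * n * (3 * log(2 * pi) + 2 * sum(log(diag(L)))) - 0.5 * rss
  list(anchor = anchor, direction = q, tau = tau, loglik = ll,
       orth_rss = rss, resid = resid)
}

#' Fit the phase-3 linear trajectory by total least squares
#'
#' Maximises the likelihood of `x_i = a + tau_i q + eps_i`,
#' `eps_i ~ N(0, Sigma)`, jointly over the line and the latent progression
#' values `tau_i`. The anchor `a` is reported as the point on the fitted
#' line where the `eta` component is zero (the empirical structure at
#' necrosis onset) and `tau` increases with `eta`. Negative fitted `tau`
#' values are reported, not clipped: constraining them would bias the line.
#'
#' When `Sigma` is not supplied it is estimated from the data about the
#' fitted line (fit, residual covariance, refit), iterated `sigma_iter`
#' times starting from the sample covariance.
#'
#' @param data Phase-3 measurement tibble (>= 3 rows); see
#'   [select_phase3()].
#' @param Sigma Optional fixed 3x3 observation covariance.
#' @param sigma_iter Refit iterations used when estimating `Sigma`
#'   (default 2).
#' @return An object of class `phase3_fit`: `anchor` (named, `Rc_emp`,
#'   `phi_c`, 0), `direction` (unit vector), `tau`, `loglik`, `Sigma`, `n`,
#'   `data`.
#' @export
fit_phase3_line <- function(data, Sigma = NULL, sigma_iter = 2) {
  X <- obs_matrix(data)
  if (nrow(X) < 3) abort("Need at least 3 phase-3 observations.")
  estimated <- is.null(Sigma)
  if (estimated) {
    # Initial whitening must not use the full sample covariance: whitening
    # by the total (signal + noise) covariance makes the data exactly
    # isotropic and erases the line. Per-coordinate scaling is
    # unit-consistent and keeps the trajectory direction visible.
    Sigma <- diag(diag(stats::cov(X)))
    for (k in seq_len(sigma_iter)) {
      fit <- tls_line(X, Sigma)
      Sigma <- stats::cov(fit$resid) * (nrow(X) - 1) / max(1, nrow(X) - 2)
      # the residual covariance is rank-deficient along the fitted
      # direction; floor its null eigenvalue to stay positive definite
      ev <- eigen(Sigma, symmetric = TRUE)
      ev$values <- pmax(ev$values, 1e-3 * max(ev$values))
      Sigma <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
    }
    inform(sprintf("Sigma estimated about the fitted line (%d refit iterations).", sigma_iter))
  }
  fit <- tls_line(X, Sigma)
  structure(list(
    anchor = stats::setNames(fit$anchor, c("Rc_emp", "phi_c", "eta0")),
    direction = stats::setNames(fit$direction, c("R", "phi", "eta")),
    tau = fit$tau,
    loglik = fit$loglik,
    orth_rss = fit$orth_rss,
    Sigma = Sigma,
    sigma_estimated = estimated,
    n = nrow(X),
    data = data
  ), class = "phase3_fit")
}

#' @export
print.phase3_fit <- function(x, ...) {
  cat(sprintf("<phase3_fit: n = %d>\n", x$n))
  cat("anchor (necrosis onset): ", paste(signif(x$anchor, 4), collapse = ", "), "\n")
  cat("direction:               ", paste(signif(x$direction, 4), collapse = ", "), "\n")
  cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' Likelihood-ratio test for a shared phase-3 trajectory across groups
#'
#' Null: one line (anchor and direction) describes the phase-3 data of all
#' groups; alternative: group-specific lines. Latent `tau_i` are free per
#' observation under both hypotheses. The observation covariance is
#' estimated once on the pooled phase-3 selection and held fixed for every
#' fit, so the test compares line parameters only. Degrees of freedom:
#' 4 per extra group (2 anchor components in the `eta = 0` plane + 2 free
#' direction components on the unit sphere).
#'
#' @param data Measurement tibble containing all groups.
#' @param group Grouping column (unquoted).
#' @param eta_min Phase-3 selection threshold passed to [select_phase3()].
#' @param Sigma Optional fixed covariance (skips the pooled estimate).
#' @return A `spheroid_lrt` object.
#' @export
lrt_phase3_shared <- function(data, group, eta_min = 0.01, Sigma = NULL) {
  sel <- select_phase3(data, eta_min)
  groups <- split_groups(sel, {{ group }})
  if (is.null(Sigma)) {
    Sigma <- fit_phase3_line(sel)$Sigma
  }
  null_fit <- fit_phase3_line(sel, Sigma = Sigma)
  fits <- lapply(groups, function(g) {
    if (nrow(g) < 3) abort("A group has fewer than 3 phase-3 observations.")
    fit_phase3_line(g, Sigma = Sigma)
  })
  ll_alt <- sum(vapply(fits, function(f) f$loglik, numeric(1)))
  G <- length(groups)
  new_lrt(2 * (ll_alt - null_fit$loglik), 4 * (G - 1), NULL,
          fits = fits, null_fit = null_fit)
}
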