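# Independent oracles: brute-force / bracketed-solver implementations kept
# deliberately separate from the package's closed-form code paths.

# Root of the first phase-3 cubic by dense grid scan + bracketed refinement.
oracle_eta <- function(R, Rc) {
  f <- function(eta) 2 * R^2 * eta^3 - 3 * R^2 * eta^2 + R^2 - Rc^2
  grid <- seq(1e-9, 1 - 1e-9, length.out = 20001)
  v <- f(grid)
  i <- which(diff(sign(v)) != 0)[1]
  uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-14)$root
}

# Root of the second phase-3 cubic in (eta, 1) by bracketed solve.
oracle_phi <- function(R, eta, Q, Rc) {
  g <- function(phi) R^2 * phi^3 + (Q^2 * Rc^2 - R^2 * (1 + 2 * eta^3)) * phi +
    2 * eta^3 * R^2
  uniroot(g, c(eta + 1e-12, 1 - 1e-12), tol = 1e-14)$root
}

# Brute-force smallest-residual scan for phi over (eta, 1).
oracle_phi_scan <- function(R, eta, Q, Rc, n = 2e5) {
  g <- function(phi) R^2 * phi^3 + (Q^2 * Rc^2 - R^2 * (1 + 2 * eta^3)) * phi +
    2 * eta^3 * R^2
  grid <- seq(eta + 1e-9, 1 - 1e-9, length.out = n)
  grid[which.min(abs(g(grid)))]
}

# Full three-dimensional simultaneous solve of the steady-state system,
# independent of the rho reduction: minimise the squared residuals with a
# multivariate solver.
oracle_steady_3d <- function(Q, Rc, gamma, start = NULL) {
  F <- function(y) {
    R <- y[1]; phi <- y[2]; eta <- y[3]
    c(1 - phi^3 - gamma * eta^3,
      (R^2 * (2 * eta^3 - 3 * eta^2 + 1) - Rc^2) / Rc^2,
      (R^2 * phi^3 + (Q^2 * Rc^2 - R^2 * (1 + 2 * eta^3)) * phi +
         2 * eta^3 * R^2) / Rc^2)
  }
  start <- start %||% c(2 * Rc, 0.8, 0.6)
  sol <- pracma::fsolve(F, start, tol = 1e-12)
  sol$x
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Steady-state residuals of the two defining equations at a candidate state.
steady_residuals <- function(R, phi, eta, Q, Rc, gamma) {
  c(1 - phi^3 - gamma * eta^3,
    2 * R^2 * eta^3 - 3 * R^2 * eta^2 + R^2 - Rc^2,
    R^2 * phi^3 + (Q^2 * Rc^2 - R^2 * (1 + 2 * eta^3)) * phi + 2 * eta^3 * R^2)
}

# Small late-day cohort at a single seeding density (cross-sectional, day 21).
late_cohort <- function(seed = 1, n = 20, density = 2500, day = 21, ...) {
  cfg <- cohort_config(observation_days = day, n_per_condition = n,
                       seeding_densities = density, seed = seed, ...)
  suppressMessages(generate_cohort(cfg))
}

# Direct multivariate-normal draws about an exact steady state (no ODE),
# for simulation oracles that need many replicates cheaply.
mvn_about_steady <- function(n, Q = 0.75, Rc = 149, gamma = 0.737,
                             Sigma = diag(c(20, 0.02, 0.1)^2)) {
  mu <- unlist(steady_state(Q, Rc, gamma)[1, 1:3])
  L <- t(chol(Sigma))
  X <- t(mu + L %*% matrix(rnorm(3 * n), 3, n))
  tibble::tibble(R_um = X[, 1], phi = X[, 2], eta = X[, 3])
}

# Phase-3 line cohort: observations scattered about a known line.
line_cohort <- function(n, anchor = c(150, 0.62, 0), direction = c(200, 0.28, 0.75),
                        tau_max = 1, Sigma = diag(c(15, 0.02, 0.05)^2)) {
  q <- direction / sqrt(sum(direction^2))
  tau <- runif(n, 0, tau_max) * sqrt(sum(direction^2))
  L <- t(chol(Sigma))
  X <- t(vapply(tau, function(t) anchor + t * q + as.numeric(L %*% rnorm(3)),
                numeric(3)))
  tibble::tibble(R_um = X[, 1], phi = pmin(X[, 2], 0.999), eta = pmax(X[, 3], 1e-6))
}
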