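#' Limiting spheroid structure (steady state of the growth model)
#'
#' Growth stalls when proliferation in the cycling rim balances mass loss
#' from the necrotic core, i.e. \eqn{1 - \bar\phi^3 = \gamma\bar\eta^3}
#' jointly with the phase-3 structural system. Parameterising by the ratio
#' \eqn{\rho = \bar\eta/\bar\phi \in (0,1)} reduces the three-equation system
#' to one scalar equation: with \eqn{\bar\phi = (1+\gamma\rho^3)^{-1/3}} and
#' \eqn{\bar\eta = \rho\bar\phi},
#' \deqn{Q^2 (1-\bar\eta)^2 (1+2\bar\eta) =
#'       1 - \bar\phi^2 - 2\bar\eta^3(1-\bar\phi)/\bar\phi,}
#' after which \eqn{\bar R = R_c / ((1-\bar\eta)\sqrt{1+2\bar\eta})}. The
#' residual of the scalar equation has opposite signs at the ends of (0, 1)
#' for every valid parameter set, so a bracketed root always exists.
#'
#' @param Q,Rc,gamma Greenspan parameters (`0 < Q < 1`, `Rc > 0`, `gamma > 0`).
#' @param tol Argument tolerance for the bracketed root solve.
#' @param n_scan Size of the pre-scan grid used to bracket the root (and to
#'   detect multiple sign changes, which trigger a warning).
#' @return A one-row tibble with `R_bar` (µm), `phi_bar`, `eta_bar`, `rho`.
#'   Both steady-state residuals are below 1e-10 at the returned values and
#'   `R_bar > Rc`.
#' @export
#' @examples
#' steady_state(Q = 0.75, Rc = 149, gamma = 0.737)
steady_state <- function(Q, Rc, gamma, tol = 1e-12, n_scan = 1000) {
  check_structural(Q, Rc)
  check_positive(gamma, "gamma")
  resid <- function(rho) {
    phib <- (1 + gamma * rho^3)^(-1 / 3)
    etab <- rho * phib
    Q^2 * (1 - etab)^2 * (1 + 2 * etab) -
      (1 - phib^2 - 2 * etab^3 * (1 - phib) / phib)
  }
  grid <- seq(1e-10, 1 - 1e-10, length.out = n_scan)
  gv <- resid(grid)
  sc <- which(diff(sign(gv)) != 0)
  if (length(sc) == 0) {
    abort("No steady-state root in rho = (0, 1): no phase-3 steady state for these parameters.")
  }
  if (length(sc) > 1) {
    warn(sprintf(
      "Multiple sign changes in the steady-state residual (near rho = %s); taking the smallest root.",
      paste(signif(grid[sc], 4), collapse = ", ")
    ))
  }
  rho <- stats::uniroot(resid, c(grid[sc[1]], grid[sc[1] + 1]), tol = tol)$root
  phib <- (1 + gamma * rho^3)^(-1 / 3)
  etab <- rho * phib
  Rb <- Rc / ((1 - etab) * sqrt(1 + 2 * etab))
  tibble::tibble(R_bar = Rb, phi_bar = phib, eta_bar = etab, rho = rho)
}

# Steady state as a bare mean vector (R, phi, eta); NULL if the solve fails.
# Tibble-free hot path used inside likelihood optimisation loops; the
# residual has opposite signs at the ends of (0, 1) for every valid
# parameter set, so plain bracketed uniroot suffices here (the user-facing
# steady_state() additionally pre-scans for multiple roots).
steady_state_mu <- function(theta, tol = 1e-12) {
  Q <- theta[[1]]; Rc <- theta[[2]]; gamma <- theta[[3]]
  if (!is.finite(Q) || !is.finite(Rc) || !is.finite(gamma) ||
      Q <= 0 || Q >= 1 || Rc <= 0 || gamma <= 0) {
    return(NULL)
  }
  resid <- function(rho) {
    phib <- (1 + gamma * rho^3)^(-1 / 3)
    etab <- rho * phib
    Q^2 * (1 - etab)^2 * (1 + 2 * etab) -
      (1 - phib^2 - 2 * etab^3 * (1 - phib) / phib)
  }
  rho <- tryCatch(
    stats::uniroot(resid, c(1e-12, 1 - 1e-12), tol = tol)$root,
    error = function(e) NULL
  )
  if (is.null(rho)) return(NULL)
  phib <- (1 + gamma * rho^3)^(-1 / 3)
  etab <- rho * phib
  c(Rc / ((1 - etab) * sqrt(1 + 2 * etab)), phib, etab)
}

# Tibble-free, validation-free structural mean (R, phi, eta) at a single
# radius; hot path for ODE right-hand sides and likelihood loops. Same
# closed-form trigonometric cubic roots as the exported solvers.
structure_mu <- function(R, Q, Rc) {
  if (R <= Q * Rc) return(c(R, 0, 0))
  if (R <= Rc) return(c(R, sqrt(max(0, 1 - Q^2 * Rc^2 / R^2)), 0))
  cc <- (Rc / R)^2
  eta <- 0.5 + cos(acos(min(1, max(-1, 2 * cc - 1))) / 3 - 2 * pi / 3)
  h <- (1 - eta)^2 * (1 + 2 * eta) - cc
  eta <- eta - h / (6 * eta * (eta - 1))
  p <- Q^2 * cc - (1 + 2 * eta^3)
  q <- 2 * eta^3
  m <- 2 * sqrt(-p / 3)
  A <- acos(min(1, max(-1, 3 * q / (p * m))))
  phi <- m * cos(A / 3 - 2 * pi / 3)
  if (phi <= eta || phi >= 1) {
    cand <- m * cos(A / 3 - 2 * pi * c(0, 2) / 3)
    phi <- cand[cand > eta & cand < 1][1]
  }
  phi <- phi - (phi^3 + p * phi + q) / (3 * phi^2 + p)
  c(R, phi, eta)
}

#' Invert the limiting structure for the Greenspan parameters
#'
#' The steady-state map \eqn{m: (Q, R_c, \gamma) \to (\bar R, \bar\phi,
#' \bar\eta)} is a bijection onto its image with a closed-form inverse:
#' \deqn{R_c = \bar R\sqrt{(1-\bar\eta)^2(1+2\bar\eta)}, \quad
#'       \gamma = (1-\bar\phi^3)/\bar\eta^3, \quad
#'       Q^2 = \bar R^2\,[(1+2\bar\eta^3)\bar\phi - \bar\phi^3 -
#'             2\bar\eta^3] / (R_c^2 \bar\phi).}
#' This is why all three structure measurements are needed: observing only
#' `(R, eta)` leaves the parameters unidentifiable, and `eta = 0` makes
#' `gamma` unidentifiable.
#'
#' @param R Limiting outer radius (µm).
#' @param phi,eta Limiting relative inhibited and necrotic radii
#'   (`0 < eta < phi < 1`).
#' @return A one-row tibble with `Q`, `Rc`, `gamma`.
#' @export
#' @examples
#' invert_steady_state(340.0, 0.899, 0.719)
invert_steady_state <- function(R, phi, eta) {
  check_positive(R, "R")
  if (!(eta > 0 && phi > eta && phi < 1)) {
    abort("Require 0 < eta < phi < 1; eta = 0 leaves `gamma` unidentifiable.")
  }
  st <- invert_structure(R, phi, eta)
  tibble::tibble(Q = st$Q, Rc = st$Rc, gamma = (1 - phi^3) / eta^3)
}

#' Invert one phase-3 structure observation for (Q, Rc)
#'
#' Solves the phase-3 structural system for the two structural parameters
#' given a single observed triple `(R, phi, eta)`; applies at any phase-3
#' time point, not only at steady state.
#'
#' @inheritParams invert_steady_state
#' @return A one-row tibble with `Q`, `Rc`.
#' @export
#' @examples
#' invert_structure(353.0, 0.895, 0.716)
invert_structure <- function(R, phi, eta) {
  check_positive(R, "R")
  if (!(eta > 0 && phi > eta && phi < 1)) {
    abort("Require 0 < eta < phi < 1 for a phase-3 structural inversion.")
  }
  Rc <- R * sqrt((1 - eta)^2 * (1 + 2 * eta))
  Q2 <- R^2 * ((1 + 2 * eta^3) * phi - phi^3 - 2 * eta^3) / (Rc^2 * phi)
  if (!is.finite(Q2) || Q2 <= 0 || Q2 >= 1) {
    abort(sprintf("Inverted Q^2 = %.4g lies outside (0, 1): structure is not consistent with the model regime.", Q2))
  }
  tibble::tibble(Q = sqrt(Q2), Rc = Rc)
}

#' Sensitivity of the limiting structure to the Greenspan parameters
#'
#' The 3x3 Jacobian \eqn{\partial(\bar R,\bar\phi,\bar\eta) /
#' \partial(Q, R_c, \gamma)} by implicit differentiation of the steady-state
#' system \eqn{F(y; \theta) = 0} with analytic partial derivatives:
#' \eqn{J = -F_y^{-1} F_\theta}. Used to chain mean-space likelihood
#' gradients back to parameter space.
#'
#' @inheritParams steady_state
#' @return A 3x3 matrix with rows `(R_bar, phi_bar, eta_bar)` and columns
#'   `(Q, Rc, gamma)`.
#' @export
steady_state_jacobian <- function(Q, Rc, gamma) {
  ss <- steady_state(Q, Rc, gamma)
  R <- ss$R_bar; phi <- ss$phi_bar; eta <- ss$eta_bar
  # Residuals:
  # F1 = 1 - phi^3 - gamma eta^3
  # F2 = R^2 (2 eta^3 - 3 eta^2 + 1) - Rc^2
  # F3 = R^2 phi^3 + (Q^2 Rc^2 - R^2 (1 + 2 eta^3)) phi + 2 eta^3 R^2
  Fy <- rbind(
    c(0, -3 * phi^2, -3 * gamma * eta^2),
    c(2 * R * (2 * eta^3 - 3 * eta^2 + 1), 0, R^2 * (6 * eta^2 - 6 * eta)),
    c(2 * R * phi^3 - 2 * R * (1 + 2 * eta^3) * phi + 4 * eta^3 * R,
      3 * R^2 * phi^2 + Q^2 * Rc^2 - R^2 * (1 + 2 * eta^3),
      -6 * eta^2 * R^2 * phi + 6 * eta^2 * R^2)
  )
  Ft <- rbind(
    c(0, 0, -eta^3),
    c(0, -2 * Rc, 0),
    c(2 * Q * Rc^2 * phi, 2 * Q^2 * Rc * phi, 0)
  )
  kappa <- kappa(Fy, exact = FALSE)
  if (!is.finite(kappa) || kappa > 1e12) {
    abort(sprintf("Implicit steady-state system is numerically singular (condition number %.3g).", kappa))
  }
  J <- -solve(Fy, Ft)
  dimnames(J) <- list(c("R_bar", "phi_bar", "eta_bar"), c("Q", "Rc", "gamma"))
  J
}
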