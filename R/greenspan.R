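#' Compose the dimensionless nutrient/inhibitor balance Q
#'
#' Greenspan's model describes growth arrest through a diffusible inhibitor
#' (produced by live cells at rate `beta_prod`, diffusivity `beta_diff`,
#' arrest threshold `beta_crit`) and necrosis through nutrient starvation
#' (consumption `omega_cons`, diffusivity `omega_diff`, far-field
#' concentration `omega_inf`, death threshold `omega_crit`). Only the
#' dimensionless combination
#' \deqn{Q^2 = \frac{\omega_{cons}}{\omega_{diff}(\omega_\infty - \omega_{crit})}
#'       \times \frac{\beta_{crit}\beta_{diff}}{\beta_{prod}} < 1}
#' enters the structural model, so the seven dimensional rates are not
#' individually identifiable from structure data.
#'
#' @param beta_prod Inhibitor production rate (mol/d).
#' @param beta_diff Inhibitor diffusivity (µm²/d).
#' @param beta_crit Critical inhibitor concentration (mol/µm³).
#' @param omega_cons Nutrient consumption rate (mol/d).
#' @param omega_diff Nutrient diffusivity (µm²/d).
#' @param omega_inf Far-field nutrient concentration (mol/µm³).
#' @param omega_crit Critical nutrient concentration (mol/µm³).
#'
#' @return The dimensionless balance `Q` (strictly in (0, 1); the model
#'   regime requires the inhibited region to appear before the necrotic one).
#' @export
#' @examples
#' compose_Q(1, 1, 1, 1, 1, 5, 1) # = 0.5
compose_Q <- function(beta_prod, beta_diff, beta_crit,
                      omega_cons, omega_diff, omega_inf, omega_crit) {
  for (nm in c("beta_prod", "beta_diff", "beta_crit", "omega_cons",
               "omega_diff", "omega_inf", "omega_crit")) {
    check_positive(get(nm), nm)
  }
  if (omega_inf <= omega_crit) {
    abort("`omega_inf` must exceed `omega_crit`.")
  }
  Q2 <- omega_cons / (omega_diff * (omega_inf - omega_crit)) *
    beta_crit * beta_diff / beta_prod
  if (Q2 >= 1) {
    abort(sprintf(
      "Composed Q^2 = %.4g >= 1: outside the model regime (the inhibited region must form before the necrotic region).",
      Q2
    ))
  }
  sqrt(Q2)
}

#' Compose the loss-to-growth ratio gamma
#'
#' @param s Per-volume proliferation rate in the cycling region (1/d).
#' @param lambda_loss Per-volume rate at which necrotic debris is lost (1/d).
#'
#' @return `gamma = lambda_loss / s` (dimensionless, > 0). `gamma` sets the
#'   limiting structure: growth stalls when peripheral proliferation balances
#'   mass loss from the necrotic core.
#' @export
compose_gamma <- function(s, lambda_loss) {
  check_positive(s, "s")
  check_positive(lambda_loss, "lambda_loss")
  lambda_loss / s
}

# --- phase-3 cubic roots --------------------------------------------------
#
# Both phase-3 structural equations are depressed cubics with three real
# roots, so the trigonometric closed form is exact; one Newton step polishes
# to full double precision. Bracketed-solver oracles live in the test suite.

#' Relative necrotic radius during phase 3
#'
#' Solves the first phase-3 structural equation
#' \eqn{2R^2\eta^3 - 3R^2\eta^2 + R^2 - R_c^2 = 0}, equivalently
#' \eqn{(1-\eta)^2(1+2\eta) = R_c^2/R^2}, for the unique root in (0, 1).
#' The left-hand side is strictly decreasing on (0, 1), so the root is unique.
#'
#' @param R Outer radius (µm), vectorised; must exceed `Rc`.
#' @param Rc Critical radius at necrosis onset (µm).
#' @return `eta` in (0, 1).
#' @export
solve_eta_phase3 <- function(R, Rc) {
  check_positive(Rc, "Rc")
  check_positive(R, "R")
  if (any(R <= Rc)) abort("`R` must exceed `Rc` in phase 3.")
  cc <- (Rc / R)^2
  eta <- 0.5 + cos(acos(pmin(1, pmax(-1, 2 * cc - 1))) / 3 - 2 * pi / 3)
  # Newton polish on h(eta) = (1-eta)^2 (1+2eta) - c; h'(eta) = 6 eta (eta - 1)
  for (i in 1:2) {
    h <- (1 - eta)^2 * (1 + 2 * eta) - cc
    hp <- 6 * eta * (eta - 1)
    step <- ifelse(abs(hp) > 0, h / hp, 0)
    eta <- pmin(1 - 1e-15, pmax(1e-15, eta - step))
  }
  eta
}

#' Relative inhibited radius during phase 3
#'
#' Solves the second phase-3 structural equation
#' \eqn{R^2\phi^3 + (Q^2 R_c^2 - R^2(1+2\eta^3))\phi + 2\eta^3 R^2 = 0}
#' for its root in `(eta, 1)`. Writing the cubic `g`, the bracket is proven:
#' `g(eta) = eta * Rc^2 * (Q^2 - 1) < 0` and `g(1) = Q^2 Rc^2 > 0`.
#'
#' @param R Outer radius (µm), vectorised.
#' @param eta Relative necrotic radius from [solve_eta_phase3()].
#' @param Q,Rc Structural parameters.
#' @return `phi` in `(eta, 1)`.
#' @export
solve_phi_phase3 <- function(R, eta, Q, Rc) {
  check_structural(Q, Rc)
  if (any(R <= Rc)) abort("`R` must exceed `Rc` in phase 3.")
  cc <- (Rc / R)^2
  p <- Q^2 * cc - (1 + 2 * eta^3)  # < 0 since Q < 1, R > Rc
  q <- 2 * eta^3
  m <- 2 * sqrt(-p / 3)
  A <- acos(pmin(1, pmax(-1, 3 * q / (p * m))))
  # three real roots; the one in (eta, 1) is the middle root k = 2
  roots <- vapply(0:2, function(k) m * cos(A / 3 - 2 * pi * k / 3), numeric(length(R)))
  roots <- matrix(roots, nrow = length(R))
  phi <- vapply(seq_along(R), function(i) {
    cand <- roots[i, ]
    ok <- cand > eta[i] & cand < 1
    if (!any(ok)) {
      abort(sprintf(
        "No phi root in (eta, 1) at R = %.6g (bracket values g(eta) = %.3g, g(1) = %.3g): inconsistent inputs.",
        R[i], eta[i] * Rc^2 * (Q^2 - 1), Q^2 * Rc^2
      ))
    }
    cand[ok][1]
  }, numeric(1))
  # Newton polish on g(phi)/R^2 = phi^3 + p phi + q
  for (i in 1:2) {
    g <- phi^3 + p * phi + q
    gp <- 3 * phi^2 + p
    step <- ifelse(abs(gp) > 0, g / gp, 0)
    phi <- pmin(1 - 1e-15, pmax(eta + 1e-15, phi - step))
  }
  phi
}

#' Inner structure as a function of outer radius (the structural model)
#'
#' The distinguishing feature of Greenspan's model: the inner structure
#' `(phi, eta)` is a function of the outer radius `R` alone, through three
#' growth phases. For `R <= Q * Rc` the spheroid cycles throughout
#' (`phi = eta = 0`); for `Q * Rc < R <= Rc` an inhibited region exists but no
#' necrotic core (`phi = sqrt(1 - Q^2 Rc^2 / R^2)`, `eta = 0`); for `R > Rc`
#' both are positive and solve the phase-3 cubic system. The map is
#' continuous in `R` across both phase boundaries.
#'
#' @param R Outer radius (µm); vectorised.
#' @param Q,Rc Structural parameters (`0 < Q < 1`, `Rc > 0`).
#' @return A tibble with columns `R`, `phi`, `eta`, `phase` (integer 1-3).
#' @export
#' @examples
#' spheroid_structure(c(100, 200, 340), Q = 0.75, Rc = 149)
spheroid_structure <- function(R, Q, Rc) {
  check_structural(Q, Rc)
  check_positive(R, "R")
  phase <- ifelse(R <= Q * Rc, 1L, ifelse(R <= Rc, 2L, 3L))
  phi <- numeric(length(R))
  eta <- numeric(length(R))
  i2 <- phase == 2L
  if (any(i2)) phi[i2] <- sqrt(pmax(0, 1 - Q^2 * Rc^2 / R[i2]^2))
  i3 <- phase == 3L
  if (any(i3)) {
    eta[i3] <- solve_eta_phase3(R[i3], Rc)
    phi[i3] <- solve_phi_phase3(R[i3], eta[i3], Q, Rc)
  }
  tibble::tibble(R = R, phi = phi, eta = eta, phase = phase)
}

#' Radial growth rate of the spheroid
#'
#' Mass balance between exponential growth in the cycling rim and debris
#' loss from the necrotic core:
#' \deqn{dR/dt = (s/3)(1 - \phi^3) R - (s/3)\gamma\eta^3 R.}
#'
#' @param R Outer radius (µm).
#' @param phi,eta Relative inhibited and necrotic radii.
#' @param s Per-volume proliferation rate (1/d).
#' @param gamma Loss-to-growth ratio.
#' @return dR/dt in µm/d.
#' @export
growth_rate <- function(R, phi, eta, s, gamma) {
  check_positive(s, "s")
  check_positive(gamma, "gamma")
  (s / 3) * ((1 - phi^3) - gamma * eta^3) * R
}

#' Simulate spheroid growth through all three phases
#'
#' Integrates the growth ODE with the structural model re-solved at every
#' right-hand-side evaluation, so trajectories pass the phase boundaries
#' continuously. Uses an adaptive integrator (`deSolve::lsoda`) at relative
#' tolerance 1e-8.
#'
#' @param R0 Initial outer radius (µm) at `times[1]`.
#' @param Q,Rc,gamma Greenspan parameters.
#' @param s Per-volume proliferation rate (1/d).
#' @param times Increasing vector of observation times (days).
#' @return A tibble with columns `time`, `R`, `phi`, `eta`, `phase`.
#' @export
#' @examples
#' simulate_growth(50, Q = 0.75, Rc = 149, gamma = 0.737, s = 0.5,
#'                 times = seq(0, 21, by = 1))
simulate_growth <- function(R0, Q, Rc, gamma, s, times) {
  check_positive(R0, "R0")
  check_structural(Q, Rc)
  check_positive(gamma, "gamma")
  check_positive(s, "s")
  if (is.unsorted(times, strictly = TRUE)) abort("`times` must be strictly increasing.")
  rhs <- function(t, y, parms) {
    mu <- structure_mu(y[1], Q, Rc)
    list((s / 3) * ((1 - mu[2]^3) - gamma * mu[3]^3) * y[1])
  }
  sol <- deSolve::lsoda(c(R = R0), times, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-8)
  if (attr(sol, "istate")[1] < 0) {
    abort(sprintf("ODE integration failed; last state R = %.6g at t = %.4g.",
                  utils::tail(sol[, "R"], 1), utils::tail(sol[, "time"], 1)))
  }
  st <- spheroid_structure(sol[, "R"], Q, Rc)
  tibble::tibble(time = sol[, "time"], R = sol[, "R"],
                 phi = st$phi, eta = st$eta, phase = st$phase)
}
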