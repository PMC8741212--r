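# The structural model: dimensionless parameters, phase structure, and the
# closed-form phase-3 roots against bracketed/brute-force oracles.

test_that("Q composes from the dimensional rates and respects the regime bound", {
  expect_equal(compose_Q(1, 1, 1, 1, 1, 5, 1), 0.5)
  # boundary: the two ratios cancel exactly -> Q = 1, outside the regime
  expect_error(compose_Q(beta_prod = 2 * 3, beta_diff = 2, beta_crit = 3,
                         omega_cons = 4 * 1.5, omega_diff = 4,
                         omega_inf = 2.5, omega_crit = 1),
               "regime")
  expect_error(compose_Q(1, 1, 1, 1, 1, 1, 2), "omega_inf")
  expect_error(compose_Q(-1, 1, 1, 1, 1, 5, 1), "positive")
  # randomized: Q^2 equals the product of the two stated ratios
  set.seed(42)
  for (i in 1:25) {
    r <- runif(7, 0.1, 3)
    wi <- r[6] + r[7] # omega_inf > omega_crit
    Q2 <- r[4] / (r[5] * (wi - r[7])) * r[3] * r[2] / r[1]
    if (Q2 >= 1) next
    expect_equal(compose_Q(r[1], r[2], r[3], r[4], r[5], wi, r[7])^2, Q2,
                 tolerance = 1e-12)
  }
})

test_that("gamma is the loss-to-growth rate ratio", {
  expect_identical(compose_gamma(1, 0.737), 0.737)
  expect_identical(compose_gamma(2, 1), 0.5)
  expect_identical(compose_gamma(1.3, 1.3), 1)
  expect_error(compose_gamma(0, 1), "positive")
})

test_that("structure passes through the three phases continuously", {
  Q <- 0.75; Rc <- 149
  # phase-1/2 boundary: phi vanishes exactly at R = Q * Rc
  at_b1 <- spheroid_structure(Q * Rc, Q, Rc)
  expect_equal(at_b1$phi, 0)
  expect_equal(at_b1$eta, 0)
  # phase 2 closed form at R = Rc
  at_b2 <- spheroid_structure(Rc, Q, Rc)
  expect_equal(at_b2$phi, sqrt(1 - Q^2), tolerance = 1e-12)
  expect_equal(at_b2$eta, 0)
  # continuity across both boundaries
  eps <- 1e-7
  for (Rb in c(Q * Rc, Rc)) {
    lo <- spheroid_structure(Rb - eps, Q, Rc)
    hi <- spheroid_structure(Rb + eps, Q, Rc)
    expect_lt(abs(hi$phi - lo$phi), 1e-3)
    expect_lt(abs(hi$eta - lo$eta), 1e-3)
  }
  # reference-scale example: limiting means invert to these structure values
  st <- spheroid_structure(340, 0.75, 149)
  expect_equal(st$phi, 0.899, tolerance = 0.002)
  expect_equal(st$eta, 0.719, tolerance = 0.002)
})

test_that("phase-3 roots match bracketed and brute-force oracles", {
  # spot value, grid-scan oracle
  expect_equal(solve_eta_phase3(340, 149), oracle_eta(340, 149), tolerance = 1e-10)
  # constructed inverse: preset eta0 = 0.5
  eta0 <- 0.5
  R <- 200
  Rc <- R * sqrt((1 - eta0)^2 * (1 + 2 * eta0))
  expect_equal(solve_eta_phase3(R, Rc), 0.5, tolerance = 1e-10)
  # eta -> 0 as R -> Rc+
  expect_lt(solve_eta_phase3(149 * (1 + 1e-8), 149), 1e-3)
  set.seed(7)
  for (i in 1:40) {
    Q <- runif(1, 0.15, 0.95)
    Rc <- runif(1, 40, 250)
    R <- Rc * runif(1, 1.001, 4)
    eta <- solve_eta_phase3(R, Rc)
    expect_equal(eta, oracle_eta(R, Rc), tolerance = 1e-8)
    phi <- solve_phi_phase3(R, eta, Q, Rc)
    expect_equal(phi, oracle_phi(R, eta, Q, Rc), tolerance = 1e-8)
    expect_equal(phi, oracle_phi_scan(R, eta, Q, Rc), tolerance = 1e-4)
    # defining property: residual of the cubic at the returned root
    g <- R^2 * phi^3 + (Q^2 * Rc^2 - R^2 * (1 + 2 * eta^3)) * phi + 2 * eta^3 * R^2
    expect_lt(abs(g) / R^2, 1e-10)
  }
  expect_error(solve_eta_phase3(100, 149), "exceed")
})

test_that("ordering, bounds and monotonicity hold across a randomized sweep", {
  set.seed(11)
  for (i in 1:30) {
    Q <- runif(1, 0.1, 0.95)
    Rc <- runif(1, 30, 300)
    Rgrid <- seq(0.2 * Q * Rc, 4 * Rc, length.out = 80)
    st <- spheroid_structure(Rgrid, Q, Rc)
    expect_true(all(st$eta >= 0 & st$eta <= st$phi & st$phi < 1))
    expect_true(all(diff(st$phi) >= -1e-10))
    expect_true(all(diff(st$eta) >= -1e-10))
  }
})

test_that("growth rate balances proliferation against necrotic loss", {
  s <- 1.2
  # no inhibition: pure exponential phase
  expect_equal(growth_rate(100, 0, 0, s, 0.7), s * 100 / 3)
  # steady-state identity: 1 - phi^3 = gamma * eta^3 gives zero growth
  gamma <- 0.9; eta <- 0.6
  phi <- (1 - gamma * eta^3)^(1 / 3)
  expect_equal(growth_rate(250, phi, eta, s, gamma), 0, tolerance = 1e-12)
  # reference MLEs form a steady state up to rounding
  expect_lt(abs(growth_rate(340, 0.899, 0.719, 1, 0.737)), 0.15)
})
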