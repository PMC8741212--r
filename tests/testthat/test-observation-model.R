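# Moments, pooled covariance, and the multivariate-normal likelihood layer.

obs_tbl <- function(X) tibble::tibble(R_um = X[, 1], phi = X[, 2], eta = X[, 3])
obs_matrix_test <- function(d) as.matrix(d[, c("R_um", "phi", "eta")])

test_that("sample moments are the componentwise mean and unbiased covariance", {
  X <- rbind(c(300, 0.9, 0.7), c(320, 0.88, 0.74))
  m <- sample_moments(obs_tbl(X))
  expect_equal(m$mu[[1]], colMeans(X), ignore_attr = TRUE)
  expect_equal(m$n, 2)
  # identical observations: zero covariance
  m0 <- sample_moments(obs_tbl(rbind(c(300, .9, .7), c(300, .9, .7), c(300, .9, .7))))
  expect_equal(max(abs(m0$Sigma[[1]])), 0)
  expect_error(sample_moments(obs_tbl(X[1, , drop = FALSE])), "2 observations")
  # moments converge to the generating values at rate 1/sqrt(n)
  set.seed(21)
  mu <- c(340, 0.9, 0.72)
  S <- diag(c(20, 0.02, 0.1)^2)
  errs <- replicate(400, {
    d <- mvn_about_steady(20)
    max(abs(colMeans(obs_matrix_test(d)) - unlist(steady_state(0.75, 149, 0.737)[1, 1:3])) /
          c(20, 0.02, 0.1))
  })
  expect_lt(mean(errs), 2.5 / sqrt(20)) # standardized mean error ~ 1/sqrt(n)
})

test_that("pooled covariance is the dof-weighted average", {
  set.seed(8)
  X1 <- matrix(rnorm(30), 10, 3); X2 <- matrix(rnorm(60), 20, 3)
  m <- dplyr::bind_rows(
    sample_moments(obs_tbl(X1)),
    sample_moments(obs_tbl(X2))
  )
  Sp <- pooled_covariance(m)
  # oracle: recompute from concatenated centred residuals
  Rsd <- rbind(sweep(X1, 2, colMeans(X1)), sweep(X2, 2, colMeans(X2)))
  expect_equal(Sp, t(Rsd) %*% Rsd / (9 + 19), ignore_attr = TRUE)
  # single group: identity operation
  expect_equal(pooled_covariance(m[1, ]), m$Sigma[[1]])
  # identical groups: pooled equals each
  expect_equal(pooled_covariance(dplyr::bind_rows(m[1, ], m[1, ])), m$Sigma[[1]])
})

test_that("the trivariate normal log-likelihood matches closed forms", {
  mu <- c(300, 0.9, 0.7)
  d1 <- obs_tbl(matrix(mu, 1))
  expect_equal(loglik_mean(d1, mu, diag(3)), -1.5 * log(2 * pi))
  # diagonal covariance: product of univariate densities
  set.seed(9)
  X <- matrix(rnorm(45, mean = rep(mu, each = 15), sd = 0.3), 15, 3, byrow = FALSE)
  S <- diag(c(0.5, 0.2, 0.1)^2)
  ll <- loglik_mean(obs_tbl(X), mu, S)
  oracle <- sum(vapply(1:3, function(j) {
    sum(dnorm(X[, j], mu[j], sqrt(S[j, j]), log = TRUE))
  }, numeric(1)))
  expect_equal(ll, oracle, tolerance = 1e-10)
  # invariant to observation ordering
  expect_equal(loglik_mean(obs_tbl(X[sample(15), ]), mu, S), ll)
  # maximised over mu by the sample mean
  xbar <- colMeans(X)
  expect_gt(loglik_mean(obs_tbl(X), xbar, S),
            loglik_mean(obs_tbl(X), xbar + c(0.01, 0, 0), S))
  expect_error(loglik_mean(obs_tbl(X), mu, tcrossprod(c(1, 0.5, 0.2))), "positive definite")
})

test_that("zero-variance coordinates are dropped with a warning", {
  X <- cbind(rnorm(10, 200, 5), 0, 0)
  S <- diag(c(25, 0, 0))
  expect_warning(ll <- loglik_mean(obs_tbl(X), c(200, 0, 0), S), "zero-variance")
  expect_equal(ll, sum(dnorm(X[, 1], 200, 5, log = TRUE)))
})

test_that("the mechanistic likelihood composes the steady-state map", {
  set.seed(10)
  d <- mvn_about_steady(25)
  S <- diag(c(20, 0.02, 0.1)^2)
  th <- c(0.75, 149, 0.737)
  mu <- unlist(steady_state(th[1], th[2], th[3])[1, 1:3])
  expect_equal(loglik_steady_state(th, d, S), loglik_mean(d, mu, S))
  # invalid parameters: -Inf with a recoverable flag
  bad <- loglik_steady_state(c(1.5, 149, 0.7), d, S)
  expect_identical(as.numeric(bad), -Inf)
  expect_true(attr(bad, "no_steady_state"))
  # saturated model: inversion of the sample mean attains the maximum
  xbar <- colMeans(obs_matrix_test(d))
  th_hat <- invert_steady_state(xbar[1], xbar[2], xbar[3])
  ll_hat <- loglik_steady_state(c(th_hat$Q, th_hat$Rc, th_hat$gamma), d, S)
  for (i in 1:5) {
    pert <- c(th_hat$Q, th_hat$Rc, th_hat$gamma) * (1 + runif(3, -0.03, 0.03))
    expect_lte(loglik_steady_state(pert, d, S), ll_hat + 1e-9)
  }
})

test_that("the chain-rule gradient matches finite differences and scales with n", {
  set.seed(12)
  d <- mvn_about_steady(15)
  S <- diag(c(20, 0.02, 0.1)^2)
  th <- c(0.7, 140, 0.8)
  g <- grad_loglik_steady_state(th, d, S)
  gfd <- pracma::grad(function(t) loglik_steady_state(t, d, S), th)
  expect_lt(max(abs(g - gfd) / (abs(gfd) + 1e-4)), 1e-4)
  # sum structure: doubling identical observations doubles the gradient
  d2 <- dplyr::bind_rows(d, d)
  expect_equal(grad_loglik_steady_state(th, d2, S), 2 * g, tolerance = 1e-10)
  # stationarity at the mechanistic MLE
  xbar <- colMeans(obs_matrix_test(d))
  th_hat <- invert_steady_state(xbar[1], xbar[2], xbar[3])
  g0 <- grad_loglik_steady_state(c(th_hat$Q, th_hat$Rc, th_hat$gamma), d, S)
  expect_lt(max(abs(g0)), 1e-4)
})
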