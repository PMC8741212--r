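# Total-least-squares phase-3 line: selection, latent-variable fit, and the
# shared-trajectory equivalence test.

test_that("phase-3 selection filters on the necrotic threshold", {
  d <- tibble::tibble(R_um = c(100, 200, 300), phi = c(0, 0.8, 0.9),
                      eta = c(0, 0.005, 0.4))
  expect_error(select_phase3(d[1:2, ], eta_min = 0.01), "No phase-3")
  sel <- suppressMessages(select_phase3(d, eta_min = 0.01))
  expect_equal(nrow(sel), 1)
  expect_equal(sel$eta, 0.4)
  # label-aware synthetic cohort: recall of model-phase-3 observations
  coh <- suppressMessages(generate_cohort(
    cohort_config(observation_days = c(10, 14, 18, 21), n_per_condition = 10, seed = 51)
  ))
  # under the generating parameters every observation day >= 10 is phase 3
  truth <- spheroid_structure(200, 0.75, 149) # radius at day 10 exceeds Rc
  sel <- suppressMessages(select_phase3(coh))
  recall <- nrow(sel) / nrow(coh)
  expect_gte(recall, 0.95)
})

test_that("noiseless collinear points are recovered exactly", {
  anchor <- c(150, 0.62, 0)
  q <- c(200, 0.28, 0.75); q <- q / sqrt(sum(q^2))
  tau <- seq(10, 120, length.out = 15)
  X <- t(vapply(tau, function(t) anchor + t * q, numeric(3)))
  d <- tibble::tibble(R_um = X[, 1], phi = X[, 2], eta = X[, 3])
  fit <- fit_phase3_line(d, Sigma = diag(c(10, 0.01, 0.03)^2))
  expect_equal(unname(fit$anchor), anchor, tolerance = 1e-8)
  expect_equal(abs(sum(fit$direction * q)), 1, tolerance = 1e-10)
  expect_lt(fit$orth_rss, 1e-12)
  expect_equal(fit$tau, tau, tolerance = 1e-8)
})

test_that("identity covariance reduces to the principal-component line", {
  set.seed(52)
  d <- line_cohort(80, Sigma = diag(3) * 1e-4)
  fit <- fit_phase3_line(d, Sigma = diag(3))
  pc <- prcomp(as.matrix(d[, c("R_um", "phi", "eta")]))$rotation[, 1]
  expect_equal(abs(sum(fit$direction * pc)), 1, tolerance = 1e-8)
})

test_that("the fitted line maximises the latent-variable likelihood", {
  set.seed(53)
  S <- diag(c(15, 0.02, 0.05)^2)
  d <- line_cohort(60, Sigma = S)
  fit <- fit_phase3_line(d, Sigma = S)
  # flipping the direction is canonicalised to eta-increasing
  expect_gt(fit$direction[["eta"]], 0)
  # reordering observations changes nothing
  fit2 <- fit_phase3_line(d[sample(nrow(d)), ], Sigma = S)
  expect_equal(unname(fit$anchor), unname(fit2$anchor), tolerance = 1e-10)
  # no perturbed line improves the whitened orthogonal residual
  X <- as.matrix(d[, c("R_um", "phi", "eta")])
  W <- solve(t(chol(S)))
  rss_of <- function(a, q) {
    q <- q / sqrt(sum(q^2))
    Z <- X %*% t(W); za <- as.numeric(W %*% a); zq <- as.numeric(W %*% q)
    zq <- zq / sqrt(sum(zq^2))
    Zc <- sweep(Z, 2, za)
    sum(Zc^2) - sum((Zc %*% zq)^2)
  }
  base <- rss_of(fit$anchor, fit$direction)
  for (i in 1:100) {
    eps_a <- rnorm(3) * c(1, 1e-3, 1e-3)
    eps_q <- rnorm(3) * 1e-2
    expect_gte(rss_of(fit$anchor + eps_a, fit$direction + eps_q), base - 1e-9)
  }
})

test_that("direction recovery matches a brute-force angular scan on a subsample", {
  set.seed(54)
  S <- diag(c(15, 0.02, 0.05)^2)
  d <- line_cohort(10, Sigma = S)
  fit <- fit_phase3_line(d, Sigma = S)
  # oracle: grid over spherical angles of the whitened direction
  X <- as.matrix(d[, c("R_um", "phi", "eta")])
  L <- t(chol(S)); W <- solve(L)
  Z <- X %*% t(W); Zc <- sweep(Z, 2, colMeans(Z))
  best <- NULL; best_rss <- Inf
  for (th in seq(0, pi, length.out = 120)) for (ph in seq(0, pi, length.out = 120)) {
    w <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    rss <- sum(Zc^2) - sum((Zc %*% w)^2)
    if (rss < best_rss) { best_rss <- rss; best <- w }
  }
  q_oracle <- as.numeric(L %*% best); q_oracle <- q_oracle / sqrt(sum(q_oracle^2))
  cosim <- abs(sum(q_oracle * fit$direction))
  expect_gt(cosim, cos(pi / 60)) # within the angular grid resolution
})

test_that("the shared-trajectory test is null for identical groups", {
  set.seed(55)
  d <- line_cohort(40)
  two <- dplyr::bind_rows(
    dplyr::mutate(d, seeding_density = 2500),
    dplyr::mutate(d, seeding_density = 5000)
  )
  lt <- suppressMessages(lrt_phase3_shared(two, seeding_density, eta_min = 0))
  expect_equal(lt$statistic, 0, tolerance = 1e-8)
  expect_equal(lt$p.value, 1, tolerance = 1e-6)
  expect_equal(lt$df, 4)
})

test_that("different anchor structures are detected more often than the null rate", {
  set.seed(56)
  reps <- 60
  pn <- pa <- numeric(reps)
  S <- diag(c(15, 0.02, 0.05)^2)
  for (i in seq_len(reps)) {
    g1 <- dplyr::mutate(line_cohort(30, Sigma = S), seeding_density = 2500)
    g2n <- dplyr::mutate(line_cohort(30, Sigma = S), seeding_density = 5000)
    g2a <- dplyr::mutate(line_cohort(30, anchor = c(150, 0.55, 0), Sigma = S),
                         seeding_density = 5000)
    pn[i] <- suppressMessages(lrt_phase3_shared(dplyr::bind_rows(g1, g2n),
                                                seeding_density, eta_min = 0, Sigma = S))$p.value
    pa[i] <- suppressMessages(lrt_phase3_shared(dplyr::bind_rows(g1, g2a),
                                                seeding_density, eta_min = 0, Sigma = S))$p.value
  }
  expect_gt(mean(pa < 0.05), mean(pn < 0.05)) # power exceeds the type-I rate
})
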