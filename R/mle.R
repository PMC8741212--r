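#' Multi-start maximum-likelihood optimisation
#'
#' Maximises an arbitrary log-likelihood objective with a derivative-free
#' simplex search from multiple Latin-hypercube start points within bounds,
#' followed (when a gradient is supplied) by a quasi-Newton polish. Returns
#' the best local maximiser across starts.
#'
#' @param objective Function `theta -> log-likelihood` (scalar; may return
#'   `-Inf` outside the feasible set).
#' @param lower,upper Finite bounds defining the start-point box (and used to
#'   clamp iterates).
#' @param theta0 Optional extra start point (tried first); the objective must
#'   be finite there.
#' @param n_starts Number of Latin-hypercube starts (default 10).
#' @param gradient Optional gradient function for the polish step.
#' @param reltol Convergence tolerance for the simplex search.
#' @return A list of class `mle_result`: `theta_hat`, `loglik_hat`,
#'   `converged`, `n_restarts_used`, and per-start diagnostics.
#' @export
maximize_likelihood <- function(objective, lower, upper, theta0 = NULL,
                                n_starts = 10, gradient = NULL,
                                reltol = 1e-12) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower), all(is.finite(lower)),
            all(is.finite(upper)))
  clamp <- function(x) pmin(upper - 1e-12, pmax(lower + 1e-12, x))
  neg <- function(x) {
    v <- objective(clamp(x))
    if (!is.finite(v)) 1e15 else -v
  }
  starts <- list()
  if (!is.null(theta0)) {
    if (!is.finite(objective(theta0))) abort("`objective` must be finite at `theta0`.")
    starts <- list(theta0)
  }
  if (n_starts > 0) {
    H <- lhs::randomLHS(n_starts, d)
    starts <- c(starts, lapply(seq_len(n_starts), function(i) {
      lower + H[i, ] * (upper - lower)
    }))
  }
  results <- lapply(starts, function(s) {
    tryCatch(
      stats::optim(clamp(s), neg, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = reltol,
                                  parscale = pmax(abs(clamp(s)), 1e-3))),
      error = function(e) NULL
    )
  })
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) {
    abort(paste0("All optimisation starts failed. Start points tried: ",
                 length(starts)))
  }
  results <- results[ok]
  values <- vapply(results, function(r) -r$value, numeric(1))
  best <- results[[which.max(values)]]
  theta <- clamp(best$par)
  # gradient polish
  if (!is.null(gradient)) {
    pol <- tryCatch(
      stats::optim(theta, neg, gr = function(x) -gradient(clamp(x)),
                   method = "BFGS",
                   control = list(maxit = 500, reltol = reltol,
                                  parscale = pmax(abs(theta), 1e-3))),
      error = function(e) NULL
    )
    if (!is.null(pol) && -pol$value > -best$value) {
      theta <- clamp(pol$par)
      best <- pol
    }
  }
  structure(list(
    theta_hat = theta,
    loglik_hat = objective(theta),
    converged = best$convergence == 0,
    n_restarts_used = length(starts),
    start_values = values
  ), class = "mle_result")
}

#' Fit a spheroid structure model by maximum likelihood
#'
#' Fits one of three models to a set of structure observations with a
#' plug-in covariance:
#' * `"statistical"` — free mean `(R, phi, eta)`; MLE is the sample mean.
#' * `"steady_state"` — mean constrained to the steady-state map
#'   `m(Q, Rc, gamma)`; the MLE is the closed-form inversion of the sample
#'   mean whenever that inversion lands in the valid parameter region
#'   (the model is a saturated 3-to-3 reparameterisation), otherwise a
#'   numeric multi-start search.
#' * `"structural"` — mean `(R, phi(R; Q, Rc), eta(R; Q, Rc))` at a single
#'   observation time; same closed-form shortcut.
#'
#' @param data Measurement tibble (columns `R_um`, `phi`, `eta`).
#' @param model One of `"statistical"`, `"steady_state"`, `"structural"`.
#' @param Sigma Optional fixed 3x3 covariance; defaults to the sample
#'   covariance of `data` (pass a pooled covariance for steady-state
#'   analyses across seeding densities).
#' @param method `"auto"` (closed form when feasible, else numeric),
#'   `"closed_form"`, or `"numeric"`.
#' @param n_starts Multi-start count for the numeric path.
#' @return An object of class `spheroid_fit`: list with `model`, `theta_hat`
#'   (named), `loglik`, `Sigma`, `n`, `data`, `objective` (closure over data
#'   and Sigma), `converged`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(observation_days = 21,
#'                                         n_per_condition = 10))
#' fit <- fit_spheroid_model(cohort, "steady_state")
#' tidy(fit)
fit_spheroid_model <- function(data, model = c("statistical", "steady_state", "structural"),
                               Sigma = NULL, method = c("auto", "closed_form", "numeric"),
                               n_starts = 10) {
  model <- match.arg(model)
  method <- match.arg(method)
  spec <- model_spec(model)
  Sigma <- resolve_sigma(data, Sigma)
  X <- obs_matrix(data)
  objective <- make_objective(model, data, Sigma)
  xbar <- colMeans(X)
  theta <- NULL
  converged <- TRUE
  if (method != "numeric") {
    theta <- spec$closed_mle(xbar)
    if (is.null(theta) && method == "closed_form") {
      abort("Closed-form MLE infeasible: sample mean is outside the model's image.")
    }
  }
  if (is.null(theta)) {
    b <- spec$default_bounds(data)
    gradient <- NULL
    if (model == "steady_state") {
      xbar <- colMeans(X)
      n_obs <- nrow(X)
      gradient <- function(th) {
        mu <- steady_state_mu(th)
        if (is.null(mu)) return(rep(0, 3))
        J <- steady_state_jacobian(th[1], th[2], th[3])
        as.numeric(t(J) %*% (n_obs * solve(Sigma, xbar - mu)))
      }
    }
    res <- maximize_likelihood(objective, b$lower, b$upper, n_starts = n_starts,
                               gradient = gradient)
    theta <- res$theta_hat
    converged <- res$converged
  }
  theta <- stats::setNames(as.numeric(theta), spec$par_names)
  structure(list(
    model = model,
    theta_hat = theta,
    loglik = objective(theta),
    Sigma = Sigma,
    n = nrow(X),
    data = data,
    objective = objective,
    spec = spec,
    converged = converged
  ), class = "spheroid_fit")
}

#' @export
print.spheroid_fit <- function(x, ...) {
  cat(sprintf("<spheroid_fit: %s model, n = %d>\n", x$model, x$n))
  print(round(x$theta_hat, 4))
  cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' @export
logLik.spheroid_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta_hat), class = "logLik")
}
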