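#' Group-wise sample moments of spheroid structure measurements
#'
#' Computes the mean vector and unbiased (n - 1 denominator) sample
#' covariance of the observation triple `(R_um, phi, eta)` within each group.
#' These are the plug-in quantities of the observation model: the covariance
#' estimated here is treated as fixed and known during likelihood
#' optimisation.
#'
#' @param data A measurement tibble with columns `R_um`, `phi`, `eta` (see
#'   [read_measurements()] for the full schema).
#' @param ... Grouping columns (tidy-select), e.g. `seeding_density, day`.
#'   With no grouping the whole table forms one group.
#' @return A tibble with one row per group: the grouping columns, `n`, and
#'   list-columns `mu` (length-3 named vector) and `Sigma` (3x3 matrix).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(observation_days = c(14, 21),
#'                                         n_per_condition = 5))
#' sample_moments(cohort, seeding_density, day)
sample_moments <- function(data, ...) {
  grps <- rlang::enquos(...)
  grouped <- dplyr::group_by(data, !!!grps, .add = TRUE)
  out <- dplyr::group_modify(grouped, function(d, key) {
    X <- obs_matrix(d)
    if (any(!is.finite(X))) abort("Non-finite values in observation columns.")
    if (nrow(X) < 2) abort("At least 2 observations per group are required for a covariance.")
    mu <- colMeans(X)
    tibble::tibble(n = nrow(X), mu = list(mu), Sigma = list(stats::cov(X)))
  })
  dplyr::ungroup(out)
}

#' Pooled sample covariance across groups
#'
#' Degrees-of-freedom weighted average of group covariances,
#' \eqn{\Sigma_{pool} = \sum_g (n_g-1)\Sigma_g / \sum_g (n_g-1)}. Used for
#' steady-state analyses, where the covariance is pooled across seeding
#' densities.
#'
#' @param moments A moments tibble from [sample_moments()] (columns `n`,
#'   `Sigma`).
#' @return A 3x3 covariance matrix.
#' @export
pooled_covariance <- function(moments) {
  if (nrow(moments) == 0) abort("Empty group list.")
  w <- moments$n - 1
  if (any(w < 1)) abort("Each group needs n >= 2.")
  Reduce(`+`, purrr::map2(moments$Sigma, w, `*`)) / sum(w)
}
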