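# Measurement-table I/O and the end-to-end analysis pipeline.
#
# Canonical schema (CSV): spheroid_id, cell_line, seeding_density, day,
# R_um, phi, eta. Radii may alternatively be supplied as absolute Ri_um /
# Rn_um columns; these are converted to the dimensionless phi = Ri/R and
# eta = Rn/R on read. All lengths in µm, times in days.

measurement_schema <- c("spheroid_id", "cell_line", "seeding_density", "day",
                        "R_um", "phi", "eta")

#' Read a spheroid measurement table
#'
#' Reads and validates the canonical CSV schema. Rows violating the
#' structural invariants (`R_um > 0`, `0 <= eta <= phi <= 1`) are rejected
#' with their row numbers; `phi = 1` is tolerated as a measurement artefact
#' but flagged with a warning. Absolute inner radii (`Ri_um`, `Rn_um`) are
#' accepted in place of `phi`, `eta` and converted on read.
#'
#' @param path CSV file path.
#' @return A validated measurement tibble (attributes: `source`,
#'   `schema_version`).
#' @export
read_measurements <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"phi" %in% names(raw) && "Ri_um" %in% names(raw)) {
    raw$phi <- raw$Ri_um / raw$R_um
  }
  if (!"eta" %in% names(raw) && "Rn_um" %in% names(raw)) {
    raw$eta <- raw$Rn_um / raw$R_um
  }
  missing <- setdiff(measurement_schema, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  data <- raw[, measurement_schema]
  for (col in c("seeding_density", "day", "R_um", "phi", "eta")) {
    if (!is.numeric(data[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[col]]))))
      abort(sprintf("Non-numeric values in column `%s` (row %s).", col,
                    paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  if (anyNA(data)) {
    bad <- which(rowSums(is.na(data)) > 0)
    abort(sprintf("Missing values in row(s) %s.", paste(utils::head(bad, 5), collapse = ", ")))
  }
  validate_rows(data)
  dup <- duplicated(data[, c("spheroid_id", "day")])
  if (any(dup)) {
    abort(sprintf("Duplicate (spheroid_id, day) key in row(s) %s.",
                  paste(utils::head(which(dup), 5), collapse = ", ")))
  }
  attr(data, "source") <- path
  attr(data, "schema_version") <- "1.0"
  data
}

validate_rows <- function(data) {
  bad_R <- which(data$R_um <= 0)
  if (length(bad_R)) abort(sprintf("R_um must be positive (row %s).",
                                   paste(utils::head(bad_R, 5), collapse = ", ")))
  bad_ord <- which(data$eta < 0 | data$phi < data$eta | data$phi > 1)
  if (length(bad_ord)) {
    abort(sprintf("Invariant 0 <= eta <= phi <= 1 violated (row %s).",
                  paste(utils::head(bad_ord, 5), collapse = ", ")))
  }
  flag <- which(data$phi == 1)
  if (length(flag)) {
    warn(sprintf("phi = 1 in row(s) %s: tolerated as a measurement artefact.",
                 paste(utils::head(flag, 5), collapse = ", ")))
  }
  invisible(data)
}

#' Write a measurement table to CSV
#'
#' @param data Measurement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  readr::write_csv(data[, measurement_schema], path)
  invisible(path)
}

#' Analysis configuration for the spheroid pipeline
#'
#' @param model One of `"statistical"`, `"steady_state"`, `"structural"`.
#' @param alpha Confidence level for intervals and regions.
#' @param covariance `"per_group"` or `"pooled"` plug-in covariance.
#' @param group Name of the grouping column (default `"seeding_density"`).
#' @param days Optional day filter (observations kept if `day %in% days`).
#' @param profiles Compute profile-likelihood confidence intervals.
#' @param regions Trace 2-parameter confidence-region slices.
#' @param phase3 Fit the phase-3 linear model and its equivalence test.
#' @param eta_min Phase-3 selection threshold.
#' @param n_grid Profile grid size.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(model = "steady_state", alpha = 0.95,
                            covariance = c("pooled", "per_group"),
                            group = "seeding_density", days = NULL,
                            profiles = TRUE, regions = FALSE, phase3 = FALSE,
                            eta_min = 0.01, n_grid = 41) {
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must lie in (0, 1).")
  covariance <- match.arg(covariance)
  structure(list(model = model, alpha = alpha, covariance = covariance,
                 group = group, days = days, profiles = profiles,
                 regions = regions, phase3 = phase3, eta_min = eta_min,
                 n_grid = n_grid),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file with any of the [analysis_config()] fields.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' Run the full structure-inference pipeline
#'
#' Per-group moments, maximum-likelihood fits, profile-likelihood confidence
#' intervals, pairwise and joint likelihood-ratio equivalence tests, and
#' (optionally) the phase-3 linear-model fit and test — in one report.
#'
#' @param data Measurement tibble (from [read_measurements()] or
#'   [generate_cohort()]).
#' @param config An [analysis_config()].
#' @return A list of class `spheroid_report` with elements `moments`,
#'   `fits` (tidy tibble of per-group estimates and CIs), `lrt_joint`,
#'   `lrt_pairwise`, optionally `phase3`, and `meta`.
#' @export
run_pipeline <- function(data, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.null(config$days)) data <- dplyr::filter(data, .data$day %in% config$days)
  gvar <- rlang::sym(config$group)
  moments <- sample_moments(data, !!gvar)
  Sigma_fixed <- if (config$covariance == "pooled") pooled_covariance(moments) else NULL
  groups <- split_groups(data, !!gvar)
  sigmas <- group_sigmas(groups, Sigma_fixed, "per_group")

  fit_rows <- purrr::map2(groups, sigmas, function(g, S) {
    fit <- fit_spheroid_model(g, config$model, Sigma = S)
    row <- tidy(fit)
    if (config$profiles) {
      cis <- purrr::map(seq_along(fit$theta_hat), function(i) {
        pr <- profile_likelihood(fit, i, alpha = config$alpha, n_grid = config$n_grid)
        tibble::tibble(term = pr$term, conf.low = pr$ci[1], conf.high = pr$ci[2])
      })
      row <- dplyr::left_join(row, dplyr::bind_rows(cis), by = "term")
    }
    row$group <- as.character(dplyr::pull(g, !!gvar)[1])
    row$loglik <- fit$loglik
    row
  })
  fits <- dplyr::bind_rows(fit_rows)

  lrt_joint <- lrt_equivalence(data, !!gvar, model = config$model,
                               Sigma = Sigma_fixed)
  labels <- names(groups)
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  lrt_pairwise <- purrr::map(pairs, function(p) {
    sub <- dplyr::filter(data, as.character(!!gvar) %in% p)
    t <- lrt_equivalence(sub, !!gvar, model = config$model, Sigma = Sigma_fixed)
    tibble::tibble(group1 = p[1], group2 = p[2],
                   statistic = t$statistic, df = t$df, p.value = t$p.value)
  })
  lrt_pairwise <- dplyr::bind_rows(lrt_pairwise)

  phase3 <- NULL
  if (isTRUE(config$phase3)) {
    phase3 <- list(
      fit = fit_phase3_line(select_phase3(data, config$eta_min)),
      lrt = lrt_phase3_shared(data, !!gvar, eta_min = config$eta_min)
    )
  }

  structure(list(
    moments = moments,
    fits = fits,
    lrt_joint = lrt_joint,
    lrt_pairwise = lrt_pairwise,
    phase3 = phase3,
    meta = list(
      package_version = as.character(utils::packageVersion("spheroidstruct")),
      model = config$model,
      alpha = config$alpha,
      covariance = config$covariance,
      n_obs = nrow(data),
      input_seed = attr(data, "seed"),
      config_hash = rlang::hash(unclass(config)),
      input_hash = rlang::hash(as.data.frame(data))
    )
  ), class = "spheroid_report")
}

#' @export
print.spheroid_report <- function(x, ...) {
  cat(sprintf("<spheroid_report: %s model, %d observations>\n",
              x$meta$model, x$meta$n_obs))
  print(x$fits)
  cat(sprintf("joint equivalence: T = %.3g, df = %d, p = %.3g\n",
              x$lrt_joint$statistic, x$lrt_joint$df, x$lrt_joint$p.value))
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' @param report A `spheroid_report` (or any list of results built from
#'   tidy tibbles, matrices and scalars).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  to_plain <- function(x) {
    if (inherits(x, "spheroid_lrt")) {
      return(list(statistic = x$statistic, df = x$df, p.value = x$p.value))
    }
    if (inherits(x, "phase3_fit")) {
      return(list(anchor = as.list(x$anchor), direction = as.list(x$direction),
                  loglik = x$loglik, n = x$n))
    }
    if (inherits(x, "spheroid_region")) {
      return(list(level = x$level, closed = x$closed,
                  boundary = as.data.frame(x$boundary)))
    }
    if (is.matrix(x)) return(unclass(x))
    if (is.data.frame(x)) {
      listcols <- vapply(x, is.list, logical(1))
      return(as.data.frame(x[, !listcols, drop = FALSE]))
    }
    if (is.list(x)) return(lapply(x, to_plain))
    x
  }
  jsonlite::write_json(to_plain(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
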