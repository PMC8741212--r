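# Internal helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn inform
NULL

# Scalar positivity / range checks with a consistent error style.
check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive and finite.", name))
  }
  invisible(x)
}

check_unit_interval <- function(x, name, open_left = TRUE, open_right = TRUE) {
  lo <- if (open_left) x > 0 else x >= 0
  hi <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || any(!is.finite(x)) || any(!lo) || any(!hi)) {
    abort(sprintf(
      "`%s` must lie in %s0, 1%s.", name,
      if (open_left) "(" else "[", if (open_right) ")" else "]"
    ))
  }
  invisible(x)
}

check_structural <- function(Q, Rc) {
  check_unit_interval(Q, "Q")
  check_positive(Rc, "Rc")
  invisible(NULL)
}

# Deterministic 31-bit substream seed from a base seed and condition labels,
# so per-condition output does not depend on cohort composition.
mix_seed <- function(seed, density, day, replicate) {
  m <- 2147483647
  h <- (seed %% m)
  h <- (h * 48271 + density) %% m
  h <- (h * 48271 + round(day * 8)) %% m
  h <- (h * 48271 + replicate) %% m
  as.integer(h)
}

obs_cols <- c("R_um", "phi", "eta")

# Extract the (R, phi, eta) observation matrix from a measurement tibble.
obs_matrix <- function(data) {
  missing <- setdiff(obs_cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing observation columns: ", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(data[, obs_cols])
  storage.mode(X) <- "double"
  X
}
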