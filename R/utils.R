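#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards
# so seeded generators never perturb the global stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Trapezoidal mean of values sampled on a unit-spaced grid: the continuous
# average of the piecewise-linear profile through them.
trapz_mean <- function(v) {
  n <- length(v)
  if (n <= 1) return(v[1])
  (0.5 * v[1] + sum(v[-c(1, n)]) + 0.5 * v[n]) / (n - 1)
}

# Shelf domain label from bottom depth (m): inner < 50, middle 50-100,
# outer 100-200.
shelf_domain <- function(bottom_depth) {
  ifelse(bottom_depth < 50, "inner",
         ifelse(bottom_depth < 100, "middle", "outer"))
}
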