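#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join across n
#' @importFrom stats median sd var rnorm runif rbeta predict setNames quantile
#' @importFrom utils head tail
NULL

# Ordinary least squares y ~ a*t + b via the normal equations.
# Returns list(slope, intercept, n). NA slope when degenerate (all t equal).
ols_fit <- function(t, y) {
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  n <- length(t)
  if (n < 2L || isTRUE(all.equal(stats::var(t), 0)) || stats::var(t) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, n = n))
  }
  tm <- mean(t); ym <- mean(y)
  a <- sum((t - tm) * (y - ym)) / sum((t - tm)^2)
  list(slope = a, intercept = ym - a * tm, n = n)
}

# Population variance (divide by n); returns 0 for a single value.
pop_var <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a child seed below 2^31 from a root seed and an index.
child_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 104729) %% 2147483647
}

# Linear interpolation of columns of a path (t, x, y, ...) at new times.
interp_cols <- function(t, values, t_out) {
  vapply(seq_len(ncol(values)), function(j) {
    stats::approx(t, values[, j], xout = t_out, rule = 2)$y
  }, numeric(length(t_out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
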