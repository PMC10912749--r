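# Independent oracles, coded against the definitions rather than the
# package's implementation paths.

# Normal-equations OLS via base lm().
ols_oracle <- function(t, y) {
  fit <- stats::lm(y ~ t)
  list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]))
}

# Maximum number of disjoint adjacent opposite-side pairs in the valid-tap
# side sequence, by exhaustive dynamic programming.
pair_oracle <- function(sides) {
  n <- length(sides)
  if (n < 2L) return(0L)
  best <- function(i) {
    if (i > n - 1L) return(0L)
    skip <- best(i + 1L)
    take <- if (sides[i] != sides[i + 1L]) 1L + best(i + 2L) else 0L
    max(skip, take)
  }
  best(1L)
}

# Brute-force peak counter: strict local maxima whose prominence (computed
# by scanning the whole signal) reaches the threshold.
peak_oracle <- function(x, min_prominence) {
  n <- length(x)
  count <- 0L
  for (i in seq(2L, n - 1L)) {
    if (!(x[i] > x[i - 1L] && x[i] > x[i + 1L])) next
    lhigher <- which(x[seq_len(i - 1L)] > x[i])
    lmin <- if (length(lhigher)) min(x[(max(lhigher) ):(i - 1L)]) else min(x[seq_len(i - 1L)])
    rhigher <- which(x[(i + 1L):n] > x[i]) + i
    rmin <- if (length(rhigher)) min(x[(i + 1L):(min(rhigher))]) else min(x[(i + 1L):n])
    if (x[i] - max(lmin, rmin) >= min_prominence) count <- count + 1L
  }
  count
}

# Confusion-matrix metrics computed with explicit loops.
metrics_oracle <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- sort(unique(c(truth, pred)))
  acc <- sum(truth == pred) / length(truth)
  prec <- rec <- f1 <- w <- numeric(length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    tp <- sum(truth == cl & pred == cl)
    p_denom <- sum(pred == cl); r_denom <- sum(truth == cl)
    prec[k] <- if (p_denom > 0) tp / p_denom else 0
    rec[k] <- if (r_denom > 0) tp / r_denom else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
    w[k] <- r_denom
  }
  list(accuracy = acc,
       precision = sum(w * prec) / sum(w),
       recall = sum(w * rec) / sum(w),
       f1 = sum(w * f1) / sum(w))
}

# O(n^2) in-band spectral centroid via explicit DFT sums.
dft_centroid_oracle <- function(axes, rate, band) {
  n <- length(axes[[1]])
  freqs <- (seq_len(n) - 1L) * rate / n
  power <- numeric(n)
  for (x in axes) {
    x <- x - mean(x)
    for (k in seq_len(n)) {
      ang <- -2 * pi * (k - 1L) * (seq_len(n) - 1L) / n
      re <- sum(x * cos(ang)); im <- sum(x * sin(ang))
      power[k] <- power[k] + re^2 + im^2
    }
  }
  sel <- freqs <= rate / 2 & freqs >= band[1] & freqs <= band[2]
  sum(freqs[sel] * power[sel]) / sum(power[sel])
}

# Magnitude computed independently of the package's helper.
accel_magnitude_oracle <- function(stream) {
  with(stream$samples, sqrt(ax * ax + ay * ay + az * az))
}
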