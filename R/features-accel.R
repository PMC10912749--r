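accel_magnitude <- function(samples) {
  sqrt(samples$ax^2 + samples$ay^2 + samples$az^2)
}

# Local maxima of x with prominence >= min_prominence, then greedy
# enforcement of min_separation (in samples), keeping higher peaks first.
find_peaks <- function(x, min_prominence, min_sep_samples) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1L }
    if (j < 1L) lmin <- min(lmin, min(x[1:i]))
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1L }
    if (j > n) rmin <- min(rmin, min(x[i:n]))
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  ord <- keep[order(-x[keep], keep)]
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) || all(abs(sel - i) >= min_sep_samples)) sel <- c(sel, i)
  }
  sort(sel)
}

#' Count acceleration peaks
#'
#' Counts local maxima of the acceleration magnitude whose topographic
#' prominence exceeds a threshold and that are separated by at least a
#' minimum time; used to count foot taps and gait steps. The default
#' prominence threshold adapts to the stream: twice the median absolute
#' deviation of the magnitude.
#'
#' @param stream Accelerometer list (`rate`, `samples`).
#' @param min_prominence Prominence threshold (m/s^2); `NULL` for the
#'   adaptive default: the larger of twice the median absolute deviation of
#'   the magnitude (noise floor) and a quarter of its maximum excursion
#'   above the median (so baseline chatter never outvotes real events).
#' @param min_separation Minimum peak separation in seconds.
#' @return Integer peak count.
#' @export
count_acceleration_peaks <- function(stream, min_prominence = NULL,
                                     min_separation = 0.25) {
  length(acceleration_peak_indices(stream, min_prominence, min_separation))
}

# Indices (not just count) of detected peaks; shared with gait timing.
acceleration_peak_indices <- function(stream, min_prominence = NULL,
                                      min_separation = 0.25) {
  m <- accel_magnitude(stream$samples)
  if (is.null(min_prominence)) {
    min_prominence <- max(2 * stats::mad(m),
                          0.25 * (max(m) - stats::median(m)), 1e-6)
  }
  find_peaks(m, min_prominence, min_separation * stream$rate)
}

#' Tremor summary features
#'
#' Per-axis standard deviation and root-mean-square of acceleration,
#' standard deviation of each Euler angle (rotation), and the tremor
#' frequency: the power-weighted mean frequency \eqn{\sum f P(f) / \sum
#' P(f)} of the discrete Fourier spectrum within the analysis band. By
#' default the spectrum is the sum of the periodograms of the mean-removed
#' acceleration axes, which keeps a pure oscillation on one axis at its true
#' frequency; the rectified-magnitude spectrum is available as an option.
#'
#' @param stream Accelerometer list (`rate`, `samples`).
#' @param band Analysis band `c(f_lo, f_hi)` in Hz (default 1--12 Hz,
#'   bracketing the classical 4--6 Hz parkinsonian tremor band).
#' @param spectrum `"per_axis"` (default) or `"magnitude"`.
#' @return List: `accel_sd_{x,y,z}`, `accel_rms_{x,y,z}`,
#'   `rot_sd_{roll,pitch,yaw}`, `tremor_freq` (Hz; `NA` when the band holds
#'   no power).
#' @export
tremor_features <- function(stream, band = c(1, 12),
                            spectrum = c("per_axis", "magnitude")) {
  spectrum <- match.arg(spectrum)
  s <- stream$samples
  rate <- stream$rate
  if (nrow(s) < 2L || diff(range(s$t)) < 2) {
    abort("tremor features require at least 2 s of uniformly sampled data")
  }
  if (rate <= 2 * band[2]) {
    abort(sprintf("sample rate %.1f Hz is below Nyquist for a %.1f Hz band edge",
                  rate, band[2]))
  }
  n <- nrow(s)
  freqs <- (seq_len(n) - 1L) * rate / n
  half <- freqs <= rate / 2
  pgram <- function(x) Mod(stats::fft(x - mean(x)))^2
  power <- if (spectrum == "per_axis") {
    pgram(s$ax) + pgram(s$ay) + pgram(s$az)
  } else {
    pgram(accel_magnitude(s))
  }
  inband <- half & freqs >= band[1] & freqs <= band[2]
  total <- sum(power[inband])
  tremor_freq <- if (total <= 1e-12) NA_real_ else {
    sum(freqs[inband] * power[inband]) / total
  }
  rms <- function(x) sqrt(mean(x^2))
  list(accel_sd_x = stats::sd(s$ax), accel_sd_y = stats::sd(s$ay),
       accel_sd_z = stats::sd(s$az),
       accel_rms_x = rms(s$ax - mean(s$ax)), accel_rms_y = rms(s$ay - mean(s$ay)),
       accel_rms_z = rms(s$az - mean(s$az)),
       rot_sd_roll = stats::sd(s$roll), rot_sd_pitch = stats::sd(s$pitch),
       rot_sd_yaw = stats::sd(s$yaw),
       tremor_freq = tremor_freq)
}

#' Gait features
#'
#' Steps are acceleration-magnitude peaks; the walking time is the span
#' between the first and last detected step peak, and the walking velocity
#' is the course length (3 m out + 3 m back = 6 m) divided by that time.
#'
#' @param stream Accelerometer list (`rate`, `samples`).
#' @param distance Course length in metres.
#' @param min_separation Minimum step separation in seconds.
#' @return List with `walking_velocity` (m/s) and `total_steps`; `NA` when
#'   fewer than two peaks are found.
#' @export
gait_features <- function(stream, distance = 6, min_separation = 0.4) {
  idx <- acceleration_peak_indices(stream, min_separation = min_separation)
  if (length(idx) < 2L) {
    return(list(walking_velocity = NA_real_, total_steps = length(idx)))
  }
  tt <- stream$samples$t[idx]
  list(walking_velocity = distance / (max(tt) - min(tt)),
       total_steps = length(idx))
}
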