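#' Detect taps in a touch stream
#'
#' A tap is one `down` event. Each tap is classified as valid when it falls
#' inside (or exactly on the boundary of) any of the task's target circles,
#' and is assigned the circle whose centre is nearest.
#'
#' @param stream Touch tibble (`t, x, y, pointer, event`).
#' @param spec Task specification with a `circles` tibble (`cx, cy, r`).
#' @return Tibble of tap events: `t, x, y, target, dist` (distance to the
#'   nearest circle centre) and `valid`.
#' @export
detect_taps <- function(stream, spec) {
  circles <- spec$circles
  stopifnot(!is.null(circles), nrow(circles) >= 1L)
  downs <- dplyr::filter(stream, .data$event == "down")
  if (nrow(downs) == 0L) {
    return(tibble(t = numeric(0), x = numeric(0), y = numeric(0),
                  target = integer(0), dist = numeric(0), valid = logical(0)))
  }
  d <- vapply(seq_len(nrow(circles)), function(j) {
    sqrt((downs$x - circles$cx[j])^2 + (downs$y - circles$cy[j])^2)
  }, numeric(nrow(downs)))
  d <- matrix(d, nrow = nrow(downs))
  target <- max.col(-d, ties.method = "first")
  dist <- d[cbind(seq_len(nrow(downs)), target)]
  tibble(t = downs$t, x = downs$x, y = downs$y,
         target = target, dist = dist,
         valid = dist <= circles$r[target])
}

#' Count paired taps in the alternating tapping task
#'
#' A pair is a completed left-right (or right-left) sequence of valid
#' in-circle taps in correct alternating order. Taps outside both circles
#' and taps breaking alternation do not count toward pairs. Invalid taps are
#' skipped: they neither pair nor reset the alternation state. A pair
#' completes whenever the next valid tap lands on the opposite circle from
#' the previous unpaired valid tap, so each maximal alternating run of the
#' valid-tap subsequence contributes `floor(length / 2)` pairs.
#'
#' @param taps Tap events from [detect_taps()].
#' @param spec Task specification; must have exactly two circles.
#' @return Integer pair count.
#' @export
count_paired_taps <- function(taps, spec) {
  if (is.null(spec$circles) || nrow(spec$circles) != 2L) {
    abort("paired taps require a task specification with exactly two circles")
  }
  v <- dplyr::arrange(dplyr::filter(taps, .data$valid), .data$t)
  pending <- NA_integer_
  pairs <- 0L
  for (side in v$target) {
    if (is.na(pending)) {
      pending <- side
    } else if (side != pending) {
      pairs <- pairs + 1L
      pending <- NA_integer_
    } else {
      pending <- side
    }
  }
  pairs
}

#' Tapping bias
#'
#' Sum over all taps (valid and missed) of the Euclidean distance between
#' the tap location and the nearest target-circle centroid; 0 for an empty
#' tap list. Smaller values indicate more precise tapping.
#'
#' @param taps Tap events from [detect_taps()].
#' @param spec Task specification (unused beyond having defined the targets;
#'   distances were computed at detection).
#' @return Non-negative total distance in screen points.
#' @export
tap_bias <- function(taps, spec = NULL) {
  if (nrow(taps) == 0L) return(0)
  sum(taps$dist)
}

#' Inter-tap interval statistics
#'
#' Mean and population variance (divide by n) of successive tap time
#' differences. With fewer than two taps both are `NA` (flagged missing and
#' imputed downstream).
#'
#' @param taps Tap events from [detect_taps()].
#' @return List with `mean` (s) and `var` (s^2).
#' @export
interval_stats <- function(taps) {
  if (nrow(taps) < 2L) return(list(mean = NA_real_, var = NA_real_))
  iv <- diff(sort(taps$t))
  list(mean = mean(iv), var = pop_var(iv))
}

#' Tapping-frequency declining slope
#'
#' Partitions the session into consecutive non-overlapping windows (1 s by
#' default, complete windows only), counts taps per window to form a
#' frequency series, and fits ordinary least squares of frequency on window
#' mid-time. A negative slope reflects declining tapping frequency, an
#' indicative sign of bradykinesia and fatigue.
#'
#' @param taps Tap events from [detect_taps()].
#' @param window Window length in seconds.
#' @return List with `slope` (taps/s^2), `intercept`, `n_windows`; slope is
#'   `NA` when fewer than two complete windows exist.
#' @export
frequency_slope <- function(taps, window = 1) {
  if (nrow(taps) == 0L) return(list(slope = NA_real_, intercept = NA_real_, n_windows = 0L))
  t_last <- max(taps$t)
  n_win <- floor(t_last / window + 1e-9)
  if (n_win < 2L) return(list(slope = NA_real_, intercept = NA_real_, n_windows = n_win))
  idx <- floor(taps$t / window) + 1L
  counts <- tabulate(idx[idx <= n_win], nbins = n_win)
  freq <- counts / window
  mid <- (seq_len(n_win) - 0.5) * window
  fit <- ols_fit(mid, freq)
  list(slope = fit$slope, intercept = fit$intercept, n_windows = n_win)
}

# Resample move samples of a touch stream to a fixed rate (linear interp).
resample_positions <- function(stream, rate = 3) {
  mv <- dplyr::filter(stream, .data$event %in% c("move", "down"))
  if (nrow(mv) < 2L) return(mv[, c("t", "x", "y")])
  t_out <- seq(min(mv$t), max(mv$t), by = 1 / rate)
  tibble(t = t_out,
         x = stats::approx(mv$t, mv$x, xout = t_out, ties = mean)$y,
         y = stats::approx(mv$t, mv$y, xout = t_out, ties = mean)$y)
}

#' Slope of the finger-to-centroid distance
#'
#' Resamples finger positions to a fixed rate (3 Hz by default, matching
#' the position tracking used for tracing features), records the distance
#' series \eqn{r_1, r_2, \ldots, r_n} to the centroid, and fits the linear
#' model \eqn{r = a t + b}. A negative slope captures the shrinking radius
#' characteristic of micrographia.
#'
#' @param stream Touch tibble.
#' @param centroid Numeric `c(x, y)`; defaults to the mean drawn position.
#' @param rate Resampling rate in Hz.
#' @return List with `slope` (points/s), `intercept`, `n_points`.
#' @export
centroid_distance_slope <- function(stream, centroid = NULL, rate = 3) {
  pos <- resample_positions(stream, rate)
  if (nrow(pos) < 2L) return(list(slope = NA_real_, intercept = NA_real_, n_points = nrow(pos)))
  if (is.null(centroid)) centroid <- c(mean(pos$x), mean(pos$y))
  r <- sqrt((pos$x - centroid[1])^2 + (pos$y - centroid[2])^2)
  fit <- ols_fit(pos$t, r)
  list(slope = fit$slope, intercept = fit$intercept, n_points = nrow(pos))
}

#' Tracing velocity features
#'
#' Instantaneous speed from consecutive move samples. The average velocity
#' is total path length divided by elapsed time; the declining slope is the
#' OLS fit of speed against segment mid-times.
#'
#' @param stream Touch tibble with move samples.
#' @return List with `mean` (points/s) and `slope` (points/s^2); `NA` when
#'   fewer than three move samples exist.
#' @export
trace_velocity_features <- function(stream) {
  mv <- dplyr::filter(stream, .data$event == "move")
  if (nrow(mv) < 3L) return(list(mean = NA_real_, slope = NA_real_))
  dt <- diff(mv$t); dd <- sqrt(diff(mv$x)^2 + diff(mv$y)^2)
  keep <- dt > 0
  if (sum(keep) < 2L) return(list(mean = NA_real_, slope = NA_real_))
  speed <- dd[keep] / dt[keep]
  mid <- (mv$t[-1][keep] + mv$t[-nrow(mv)][keep]) / 2
  elapsed <- max(mv$t) - min(mv$t)
  fit <- ols_fit(mid, speed)
  list(mean = sum(dd) / elapsed, slope = fit$slope)
}

#' Trail bias
#'
#' Mean distance from each drawn sample to the nearest reference-trail
#' point. The per-sample mean (rather than a sum) makes the feature
#' invariant to the stream sampling rate.
#'
#' @param stream Touch tibble with move samples.
#' @param trail Reference trail tibble (`x, y`).
#' @return Mean distance in screen points; `NA` for an empty stream.
#' @export
trail_bias <- function(stream, trail) {
  stopifnot(nrow(trail) > 0L)
  mv <- dplyr::filter(stream, .data$event == "move")
  if (nrow(mv) == 0L) return(NA_real_)
  d2 <- outer(mv$x, trail$x, "-")^2 + outer(mv$y, trail$y, "-")^2
  mean(sqrt(apply(d2, 1L, min)))
}

#' Angular-velocity features of circle drawing
#'
#' Computes the polar angle of each drawn sample about the drawing centroid,
#' unwraps it so full revolutions accumulate, resamples it on a fixed
#' interval grid (0.3 s by default) and differentiates to angular velocity.
#' Returns the mean angular velocity (bradykinesia indicator) and its OLS
#' slope over time (fatigue indicator).
#'
#' @param stream Touch tibble with move samples.
#' @param interval Angular-velocity sampling interval in seconds.
#' @return List with `mean` (rad/s) and `slope` (rad/s^2).
#' @export
circle_drawing_angular <- function(stream, interval = 0.3) {
  mv <- dplyr::filter(stream, .data$event == "move")
  if (nrow(mv) < 3L || diff(range(mv$t)) < 3 * interval) {
    return(list(mean = NA_real_, slope = NA_real_))
  }
  cx <- mean(mv$x); cy <- mean(mv$y)
  r <- sqrt((mv$x - cx)^2 + (mv$y - cy)^2)
  if (max(r) < 1e-9) return(list(mean = NA_real_, slope = NA_real_))
  theta <- atan2(mv$y - cy, mv$x - cx)
  dtheta <- diff(theta)
  dtheta <- ((dtheta + pi) %% (2 * pi)) - pi   # unwrap
  theta_u <- c(theta[1], theta[1] + cumsum(dtheta))
  tg <- seq(min(mv$t), max(mv$t), by = interval)
  th <- stats::approx(mv$t, theta_u, xout = tg, ties = mean)$y
  omega <- abs(diff(th)) / interval
  mid <- (tg[-1] + tg[-length(tg)]) / 2
  fit <- ols_fit(mid, omega)
  list(mean = mean(omega), slope = fit$slope)
}

#' Bimanual coordination features
#'
#' Per-hand trail bias and velocity features via [trail_bias()] and
#' [trace_velocity_features()], plus: `lr_coordination`, the mean distance
#' between the left-hand position and the mirror image (across the screen's
#' vertical midline) of the time-matched right-hand position — the two
#' displayed trails are mirror-symmetric, so for perfectly synchronised
#' tracing this is 0 and it grows with lag or asymmetry; and
#' `passed_points`, the number of reference trail points (both trails) with
#' at least one drawn sample within tolerance `eps`.
#'
#' @param stream Touch tibble with `pointer` in `{"left", "right"}`.
#' @param spec Task specification with `trails$left`, `trails$right` and
#'   `screen_width`.
#' @param eps Passed-point tolerance in screen points.
#' @return List with `bias_L`, `bias_R`, `velocity_mean_L`, `velocity_mean_R`,
#'   `velocity_slope_L`, `velocity_slope_R`, `lr_coordination`,
#'   `passed_points`. Coordination entries are `NA` when a hand is missing.
#' @export
coordination_features <- function(stream, spec, eps = 20) {
  left <- dplyr::filter(stream, .data$pointer == "left")
  right <- dplyr::filter(stream, .data$pointer == "right")
  vl <- trace_velocity_features(left)
  vr <- trace_velocity_features(right)
  out <- list(
    bias_L = if (nrow(left)) trail_bias(left, spec$trails$left) else NA_real_,
    bias_R = if (nrow(right)) trail_bias(right, spec$trails$right) else NA_real_,
    velocity_mean_L = vl$mean, velocity_mean_R = vr$mean,
    velocity_slope_L = vl$slope, velocity_slope_R = vr$slope,
    lr_coordination = NA_real_, passed_points = NA_real_
  )
  if (nrow(left) == 0L || nrow(right) == 0L) return(out)
  rx <- stats::approx(right$t, right$x, xout = left$t, rule = 2, ties = mean)$y
  ry <- stats::approx(right$t, right$y, xout = left$t, rule = 2, ties = mean)$y
  mx <- spec$screen_width - rx
  out$lr_coordination <- mean(sqrt((left$x - mx)^2 + (left$y - ry)^2))
  passed <- function(trail, drawn) {
    if (nrow(drawn) == 0L) return(0L)
    d2 <- outer(trail$x, drawn$x, "-")^2 + outer(trail$y, drawn$y, "-")^2
    sum(sqrt(apply(d2, 1L, min)) <= eps)
  }
  out$passed_points <- passed(spec$trails$left, left) +
    passed(spec$trails$right, right)
  out
}
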