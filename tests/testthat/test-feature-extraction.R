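test_that("taps are detected and classified by circle membership", {
  spec <- one_circle_spec(0, 0, 50)
  st <- tap_stream(c(1, 2, 3), c(0, 10, -20), c(0, 5, 10))
  taps <- detect_taps(st, spec)
  expect_equal(nrow(taps), 3L)
  expect_true(all(taps$valid))

  # the boundary counts as inside
  st_b <- tap_stream(1, 50, 0)
  expect_true(detect_taps(st_b, spec)$valid)

  st5 <- tap_stream(1:5, c(0, 10, 200, 20, -300), c(0, 0, 0, 0, 0))
  taps5 <- detect_taps(st5, spec)
  expect_equal(sum(taps5$valid), 3L)
  expect_equal(sum(!taps5$valid), 2L)

  # an empty stream yields an empty tap list, not an error
  expect_equal(nrow(detect_taps(tap_stream(numeric(0), numeric(0), numeric(0)),
                                spec)), 0L)

  # up/move events never count as taps
  st_mix <- dplyr::bind_rows(tap_stream(1, 0, 0),
                             move_stream(1.5, 1, 1))
  expect_equal(nrow(detect_taps(st_mix, spec)), 1L)
})

test_that("paired-tap counting applies the alternation rule", {
  spec <- two_circle_spec()
  mk <- function(sides) {
    # L -> left circle centre, R -> right, M -> miss (outside both)
    x <- c(L = -100, R = 100, M = 0)[sides]
    detect_taps(tap_stream(seq_along(sides), x, 0), spec)
  }
  expect_equal(count_paired_taps(mk(c("L", "R", "L", "R", "L", "R")), spec), 3L)
  expect_equal(count_paired_taps(mk(c("L", "L", "R")), spec), 1L)
  expect_equal(count_paired_taps(mk(c("L", "M", "R")), spec), 1L)
  expect_equal(count_paired_taps(mk(character(0))[0, ], spec), 0L)
  expect_error(count_paired_taps(mk(c("L", "R")), one_circle_spec()),
               "two circles")

  # exhaustive agreement with a brute-force pairing oracle, all sequences
  # of length <= 6 over {left, right, miss}
  for (len in 1:6) {
    grids <- do.call(expand.grid, rep(list(c("L", "R", "M")), len))
    for (i in seq_len(nrow(grids))) {
      sides <- as.character(unlist(grids[i, ]))
      taps <- mk(sides)
      valid_sides <- taps$target[taps$valid]
      expect_equal(count_paired_taps(taps, spec), pair_oracle(valid_sides),
                   info = paste(sides, collapse = ""))
    }
  }
})

test_that("tap bias is the summed distance to the nearest centroid", {
  spec <- one_circle_spec(0, 0, 50)
  expect_equal(tap_bias(detect_taps(tap_stream(1:2, c(3, 0), c(4, 5)), spec)), 10)
  expect_equal(tap_bias(detect_taps(tap_stream(1, 0, 0), spec)), 0)
  expect_equal(tap_bias(detect_taps(tap_stream(numeric(0), numeric(0),
                                               numeric(0)), spec)), 0)

  # two-circle case against an independent distance-sum oracle
  spec2 <- two_circle_spec()
  set.seed(4)
  for (rep in 1:20) {
    st <- tap_stream(1:10, runif(10, -200, 200), runif(10, -100, 100))
    taps <- detect_taps(st, spec2)
    d_oracle <- sum(pmin(sqrt((st$x + 100)^2 + st$y^2),
                         sqrt((st$x - 100)^2 + st$y^2)))
    expect_equal(tap_bias(taps), d_oracle, tolerance = 1e-12)
  }
})

test_that("interval statistics use the population variance convention", {
  spec <- one_circle_spec()
  iv <- interval_stats(detect_taps(tap_stream(c(0, 0.5, 1, 1.5), 0, 0), spec))
  expect_equal(iv$mean, 0.5)
  expect_equal(iv$var, 0)

  iv2 <- interval_stats(detect_taps(tap_stream(c(0, 1, 3), 0, 0), spec))
  expect_equal(iv2$mean, 1.5)
  expect_equal(iv2$var, 0.25)

  expect_true(is.na(interval_stats(detect_taps(tap_stream(1, 0, 0), spec))$mean))

  # two-pass oracle on random streams
  set.seed(9)
  for (rep in 1:25) {
    tt <- sort(runif(sample(2:30, 1), 0, 10))
    iv3 <- interval_stats(detect_taps(tap_stream(tt, 0, 0), spec))
    d <- diff(tt)
    expect_equal(iv3$mean, sum(d) / length(d), tolerance = 1e-12)
    expect_equal(iv3$var, sum((d - mean(d))^2) / length(d), tolerance = 1e-12)
  }
})

test_that("tapping-frequency slope matches closed-form OLS", {
  spec <- one_circle_spec()
  # constant 2 Hz tapping -> exactly zero slope
  st <- tap_stream(seq(0, 9.5, by = 0.5), 0, 0)
  expect_equal(frequency_slope(detect_taps(st, spec))$slope, 0)

  # window counts 4, 3, 2, 1 at mid-times 0.5..3.5 -> slope -1
  tt <- c(0, 0.2, 0.4, 0.6,  1.0, 1.3, 1.6,  2.0, 2.5,  3.0, 4.0)
  fs <- frequency_slope(detect_taps(tap_stream(tt, 0, 0), spec))
  expect_equal(fs$n_windows, 4L)
  expect_equal(fs$slope, -1)

  # fewer than two complete windows -> flagged missing
  expect_true(is.na(frequency_slope(detect_taps(tap_stream(c(0.1, 0.9), 0, 0),
                                                spec))$slope))

  # normal-equations oracle on random tap streams
  set.seed(11)
  for (rep in 1:20) {
    tt <- sort(runif(40, 0, 8 + runif(1)))
    taps <- detect_taps(tap_stream(tt, 0, 0), spec)
    fs <- frequency_slope(taps)
    n_win <- floor(max(tt))
    counts <- vapply(seq_len(n_win), function(k) sum(tt >= k - 1 & tt < k),
                     numeric(1))
    o <- ols_oracle(seq_len(n_win) - 0.5, counts)
    expect_equal(fs$slope, o$slope, tolerance = 1e-10)
  }
})

test_that("centroid-distance slope recovers exact linear decay", {
  # r(t) = 100 - 2t sampled for 5 s
  tt <- seq(0, 5, by = 1 / 3)
  st <- move_stream(tt, 100 - 2 * tt, 0)
  fit <- centroid_distance_slope(st, centroid = c(0, 0))
  expect_equal(fit$slope, -2, tolerance = 1e-9)

  # constant-radius circle tracing -> slope 0
  th <- seq(0, 4 * pi, length.out = 60)
  st2 <- move_stream(seq(0, 10, length.out = 60), 120 * cos(th), 120 * sin(th))
  expect_equal(centroid_distance_slope(st2, centroid = c(0, 0))$slope, 0,
               tolerance = 1e-9)

  # random-walk radius: equals OLS oracle on the resampled series
  set.seed(3)
  tt <- seq(0, 6, by = 0.05)
  r <- 80 + cumsum(rnorm(length(tt)))
  st3 <- move_stream(tt, r, 0)
  fit3 <- centroid_distance_slope(st3, centroid = c(0, 0))
  t3 <- seq(0, 6, by = 1 / 3)
  r3 <- stats::approx(tt, r, xout = t3)$y
  expect_equal(fit3$slope, ols_oracle(t3, abs(r3))$slope, tolerance = 1e-10)

  expect_true(is.na(centroid_distance_slope(move_stream(0.1, 5, 5))$slope))
})

test_that("tracing velocity features match their closed forms", {
  # uniform motion at 10 units/s
  tt <- seq(0, 5, by = 0.1)
  st <- move_stream(tt, 10 * tt, 0)
  v <- trace_velocity_features(st)
  expect_equal(v$mean, 10, tolerance = 1e-9)
  expect_equal(v$slope, 0, tolerance = 1e-9)

  # segment speeds 10, 8, 6, 4 at unit-spaced times -> slope -2
  x <- cumsum(c(0, 10, 8, 6, 4))
  v2 <- trace_velocity_features(move_stream(0:4, x, 0))
  expect_equal(v2$slope, -2, tolerance = 1e-10)
  expect_equal(v2$mean, 28 / 4, tolerance = 1e-10)

  # path length equals the sum-of-segments oracle
  set.seed(21)
  tt <- sort(runif(50, 0, 10))
  xx <- rnorm(50, 0, 30); yy <- rnorm(50, 0, 30)
  v3 <- trace_velocity_features(move_stream(tt, xx, yy))
  path <- sum(sqrt(diff(xx)^2 + diff(yy)^2))
  expect_equal(v3$mean, path / (max(tt) - min(tt)), tolerance = 1e-10)

  expect_true(is.na(trace_velocity_features(move_stream(1:2, 1:2, 1:2))$mean))
})

test_that("trail bias measures deviation from the reference trail", {
  th <- seq(0, 2 * pi, length.out = 400)
  trail <- tibble::tibble(x = 100 * cos(th), y = 100 * sin(th))
  drawn <- move_stream(seq_along(th) / 10, trail$x, trail$y)
  expect_equal(trail_bias(drawn, trail), 0)

  # a rigid shift perpendicular to a dense straight trail shows up as the
  # shift magnitude
  u <- seq(0, 1, length.out = 500)
  straight <- tibble::tibble(x = 400 * u * 4 / 5, y = -400 * u * 3 / 5)
  drawn_s <- move_stream(u * 10, straight$x + 3, straight$y + 4)
  expect_equal(trail_bias(drawn_s, straight), 5, tolerance = 0.01)

  # brute-force nearest-point oracle on random trails
  set.seed(6)
  trail2 <- tibble::tibble(x = rnorm(40, 0, 50), y = rnorm(40, 0, 50))
  drawn2 <- move_stream(1:25, rnorm(25, 0, 50), rnorm(25, 0, 50))
  oracle <- mean(vapply(seq_len(25), function(i) {
    min(sqrt((drawn2$x[i] - trail2$x)^2 + (drawn2$y[i] - trail2$y)^2))
  }, numeric(1)))
  expect_equal(trail_bias(drawn2, trail2), oracle, tolerance = 1e-12)
})

test_that("angular velocity features unwrap and fit as specified", {
  # uniform circular motion at 2*pi rad/s
  tt <- seq(0, 3, by = 0.01)
  st <- move_stream(tt, 100 * cos(2 * pi * tt), 100 * sin(2 * pi * tt))
  ang <- circle_drawing_angular(st)
  expect_equal(ang$mean, 2 * pi, tolerance = 1e-2)
  expect_equal(ang$slope, 0, tolerance = 1e-2)

  # angular speed decaying linearly from 2*pi to pi over 3 s -> slope -pi/3
  om <- function(t) 2 * pi - (pi / 3) * t
  th <- 2 * pi * tt - (pi / 6) * tt^2
  st2 <- move_stream(tt, 100 * cos(th), 100 * sin(th))
  # tolerance reflects the estimator discretization: the drawing centroid is
  # estimated from unevenly covered revolutions
  ang2 <- circle_drawing_angular(st2)
  expect_equal(ang2$slope, -pi / 3, tolerance = 0.05)

  # a full revolution accumulates 2*pi rather than cancelling to zero
  tt3 <- seq(0, 1, by = 0.02)
  st3 <- move_stream(tt3, cos(2 * pi * tt3) * 50, sin(2 * pi * tt3) * 50)
  expect_equal(circle_drawing_angular(st3, interval = 0.25)$mean, 2 * pi,
               tolerance = 0.05)

  # degenerate point cloud is flagged missing
  st4 <- move_stream(seq(0, 2, by = 0.1), 0, 0)
  expect_true(is.na(circle_drawing_angular(st4)$mean))
})

test_that("coordination features capture mirroring, lag and coverage", {
  spec <- task_specs()$task9
  trail_l <- spec$trails$left
  n <- nrow(trail_l)
  tt <- seq(0, 10, length.out = n)
  left <- move_stream(tt, trail_l$x, trail_l$y, pointer = "left")
  mirror_right <- move_stream(tt, spec$screen_width - trail_l$x, trail_l$y,
                              pointer = "right")
  st <- dplyr::bind_rows(left, mirror_right)
  feats <- coordination_features(st, spec)
  expect_equal(feats$lr_coordination, 0, tolerance = 1e-9)
  expect_equal(feats$bias_L, 0, tolerance = 1e-9)
  expect_equal(feats$passed_points, 2L * n)

  # coordination error grows monotonically with right-hand lag
  lag_coord <- function(lag) {
    shifted <- stats::approx(tt, seq_len(n), xout = tt - lag, rule = 2)$y
    rx <- stats::approx(seq_len(n), spec$screen_width - trail_l$x,
                        xout = shifted)$y
    ry <- stats::approx(seq_len(n), trail_l$y, xout = shifted)$y
    st_l <- dplyr::bind_rows(left, move_stream(tt, rx, ry, pointer = "right"))
    coordination_features(st_l, spec)$lr_coordination
  }
  vals <- vapply(c(0, 0.1, 0.2, 0.4), lag_coord, numeric(1))
  expect_true(all(diff(vals) > 0))

  # a missing hand flags the coordination features
  miss <- coordination_features(left, spec)
  expect_true(is.na(miss$lr_coordination))
  expect_true(is.na(miss$passed_points))
})

test_that("tremor frequency is the in-band spectral centroid", {
  # pure 5 Hz sinusoid on one axis, 50 Hz sampling, 10 s of integer periods
  tt <- seq(0, 10 - 1 / 50, by = 1 / 50)
  st <- accel_stream(tt, ax = 2 * sin(2 * pi * 5 * tt), rate = 50)
  tf <- tremor_features(st)
  expect_equal(tf$tremor_freq, 5, tolerance = 1e-9)
  expect_equal(tf$accel_rms_x, 2 / sqrt(2), tolerance = 1e-3)

  # constant stream has no in-band power
  st_dc <- accel_stream(tt, ax = 1, az = 9.81, rate = 50)
  expect_true(is.na(tremor_features(st_dc)$tremor_freq))

  # white noise: weighted frequency matches an explicit O(n^2) DFT oracle
  set.seed(12)
  tt2 <- seq(0, 4 - 1 / 40, by = 1 / 40)
  ax <- rnorm(length(tt2)); ay <- rnorm(length(tt2)); az <- rnorm(length(tt2))
  st2 <- accel_stream(tt2, ax = ax, ay = ay, az = az, rate = 40)
  expect_equal(tremor_features(st2)$tremor_freq,
               dft_centroid_oracle(list(ax, ay, az), 40, c(1, 12)),
               tolerance = 1e-8)

  # sampling below Nyquist for the band is an error
  st3 <- accel_stream(seq(0, 10, by = 1 / 20), ax = 1, rate = 20)
  expect_error(tremor_features(st3, band = c(1, 12)), "Nyquist")
})

test_that("acceleration peak counting matches a brute-force oracle", {
  rate <- 50
  tt <- seq(0, 12 - 1 / rate, by = 1 / rate)
  bump <- function(centres, amp = 3, width = 0.05) {
    rowSums(vapply(centres, function(m) amp * exp(-0.5 * ((tt - m) / width)^2),
                   numeric(length(tt))))
  }
  st <- accel_stream(tt, az = 9.81 + bump(seq(0.5, 11.5, by = 1)), rate = rate)
  expect_equal(count_acceleration_peaks(st, min_prominence = 1,
                                        min_separation = 0.3), 12L)

  flat <- accel_stream(tt, az = 9.81, rate = rate)
  expect_equal(count_acceleration_peaks(flat, min_prominence = 0.5), 0L)

  # 100 random signals, separation disabled so the oracle semantics match
  set.seed(31)
  for (rep in 1:100) {
    x <- cumsum(rnorm(150))
    st_r <- accel_stream(seq_along(x) / rate, az = x, rate = rate)
    thr <- runif(1, 0.5, 3)
    expect_equal(count_acceleration_peaks(st_r, min_prominence = thr,
                                          min_separation = 0),
                 peak_oracle(accel_magnitude_oracle(st_r), thr))
  }
})

test_that("gait features derive velocity from the step-peak span", {
  rate <- 50
  tt <- seq(0, 10 - 1 / rate, by = 1 / rate)
  bump <- function(centres) {
    rowSums(vapply(centres, function(m) 3 * exp(-0.5 * ((tt - m) / 0.05)^2),
                   numeric(length(tt))))
  }
  st <- accel_stream(tt, az = 9.81 + bump(seq(1, 7, by = 1)), rate = rate)
  g <- gait_features(st)
  expect_equal(g$walking_velocity, 1, tolerance = 1e-6)
  expect_equal(g$total_steps, 7L)

  # doubling cadence at a fixed span doubles steps, not velocity
  st2 <- accel_stream(tt, az = 9.81 + bump(seq(1, 7, by = 0.5)), rate = rate)
  g2 <- gait_features(st2)
  expect_equal(g2$walking_velocity, 1, tolerance = 1e-6)
  expect_equal(g2$total_steps, 13L)

  flat <- accel_stream(tt, az = 9.81, rate = rate)
  expect_true(is.na(gait_features(flat)$walking_velocity))
})

test_that("walking velocity is recovered across the severity range", {
  cfg <- generator_config()
  spec <- task_specs()$task11
  set.seed(14)
  for (rep in 1:50) {
    s <- runif(1)
    st <- pdmotor:::sim_gait(spec, s, cfg)
    v_true <- cfg$gait_v0 * (1 - cfg$gait_beta * s)
    v_est <- gait_features(st)$walking_velocity
    expect_equal(v_est, v_true, tolerance = 0.05)
  }
})

test_that("the extracted feature vector is complete and deterministic", {
  cfg <- generator_config(n_pd = 1, n_hc = 1, seed = 5)
  rec <- simulate_subject("P", "PD", 0.5, config = cfg, seed = 5)
  f1 <- extract_subject_features(rec)
  f2 <- extract_subject_features(rec)
  expect_identical(f1, f2)
  expect_equal(length(f1), nrow(feature_registry()))
  expect_named(f1, feature_registry()$feature)

  # noiseless zero-severity subject: all slope features 0, tap biases 0
  rec0 <- simulate_subject("Z", "HC", 0,
                           config = generator_config(noise_scale = 0),
                           seed = 1)
  f0 <- extract_subject_features(rec0)
  expect_equal(unname(f0["task1_bias_L"]), 0)
  expect_equal(unname(f0["task2_bias_R"]), 0)
  # stationary noiseless streams: no declining trend anywhere (the spiral
  # trail's radius grows outward by design, so its radius slope is excluded)
  slopes <- f0[c(grep("freq_slope|velocity_slope|angvel_slope", names(f0),
                      value = TRUE),
                 sprintf("task%d_radius_slope_%s", rep(c(6, 8), each = 2),
                         c("L", "R")))]
  expect_true(all(abs(slopes) < 0.3))
})

test_that("feature tables have no missing values and flag imputations", {
  cohort <- simulate_cohort(generator_config(n_pd = 3, n_hc = 2, seed = 8))
  # drop one subject's left-hand tapping session to force imputation
  cohort$sessions[[1]]$task1_L <- NULL
  tab <- extract_features(cohort)
  expect_false(anyNA(tab))
  imp <- attr(tab, "imputed")
  expect_true(all(grepl("^task1_.*_L$", imp$feature[imp$subject_id ==
                                                      cohort$subject_id[1]])))
  expect_equal(setdiff(names(tab), pdmotor:::label_columns()),
               feature_registry()$feature)
})
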