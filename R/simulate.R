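#' Generator configuration for synthetic cohorts
#'
#' Defines the cohort composition and the effect-size block that maps a
#' single latent severity \eqn{s \in [0,1]} to the generative parameters of
#' every task stream. Each derived parameter is monotone in severity:
#' inter-tap intervals inflate by a factor \eqn{1 + \alpha s} and drift
#' upward within a session (bradykinesia and fatigue), tap placement noise
#' inflates, alternation errors and outside-circle taps become more likely,
#' a 4--6 Hz tremor oscillation grows in amplitude, traced/drawn radii
#' shrink (micrographia), angular velocity decays, the non-dominant hand in
#' the coordination task lags, and gait slows.
#'
#' @param n_pd,n_hc Cohort sizes; defaults mirror a 50 PD / 29 HC clinic
#'   sample.
#' @param seed Root seed; fully determines the cohort. Per-subject child
#'   streams are derived deterministically from it.
#' @param severity_pd,severity_hc Beta shape parameters for the latent
#'   severity of each group (PD centred near mid-scale, HC near zero).
#' @param severity_pd_min Lower bound of PD severity: PD severities are
#'   drawn as `severity_pd_min + (1 - severity_pd_min) * Beta`. Anchored to
#'   the minimum motor score a diagnosed PD cohort presents (about 8 of
#'   68), so diagnosed patients are never generated indistinguishable from
#'   the healthiest controls.
#' @param mu0 Base inter-tap interval (s) at severity 0.
#' @param alpha Interval inflation: mean interval is `mu0 * (1 + alpha * s)`.
#' @param fatigue_drift Fractional within-session interval growth per second
#'   at `s = 1` (drives negative tapping-frequency slopes).
#' @param interval_cv Multiplicative coefficient of variation of intervals.
#' @param sigma0,sigma_inflation Tap placement noise SD (points):
#'   `sigma0 * (1 + sigma_inflation * s)`.
#' @param alt_error_slope Probability at `s = 1` of repeating the same side
#'   in the alternating tapping task (breaks pairs).
#' @param miss_base,miss_slope Probability `miss_base + miss_slope * s` of a
#'   tap landing outside the target circle.
#' @param target_interval_factor Interval multiplier for the nose-to-screen
#'   target task (longer reach).
#' @param tremor_gain Tremor acceleration amplitude (m/s^2) at `s = 1`.
#' @param tremor_prevalence Probability that a PD subject expresses overt
#'   rest/postural tremor; non-tremor-dominant patients (akinetic-rigid
#'   phenotype) oscillate at a small fraction of the full amplitude, and
#'   controls carry baseline sensor noise only.
#' @param tremor_band Frequency band (Hz) the tremor frequency is drawn from
#'   uniformly; classical PD rest tremor occupies 4--6 Hz.
#' @param accel_noise_sd Baseline accelerometer noise SD (m/s^2).
#' @param angle_gain,angle_noise_sd Euler-angle oscillation amplitude at
#'   `s = 1` and baseline angle noise (radians).
#' @param trace_speed0 Base tracing speed (points/s).
#' @param trace_slow Fractional tracing-speed reduction at `s = 1`.
#' @param vel_decay Fractional within-session speed decay at `s = 1`.
#' @param radius_decay Drawn-radius shrink rate (points/s) at `s = 1`.
#' @param angvel_decay Angular-velocity decay rate (rad/s^2) at `s = 1`.
#' @param trail_noise0,trail_noise_slope Tracing positional noise SD
#'   (points): `trail_noise0 + trail_noise_slope * s`.
#' @param lag_slope Bimanual lag (s) of the right hand at `s = 1`.
#' @param gait_v0,gait_beta Walking speed `gait_v0 * (1 - gait_beta * s)`
#'   (m/s) over the fixed 3 m out + 3 m back course.
#' @param cadence0,cadence_beta Step cadence `cadence0 * (1 - cadence_beta *
#'   s)` (steps/s).
#' @param foot_rate0,foot_beta Foot-tapping rate (taps/s) and its reduction.
#' @param label_noise_sd SD of the Gaussian noise added to the severity ->
#'   MDS-UPDRS III score map (score units).
#' @param hy_breaks Monotone severity cut points binning PD severity into
#'   Hoehn & Yahr stages 1--5.
#' @param hand_asymmetry Relative severity offset between hands (PD motor
#'   signs are typically asymmetric).
#' @param severity_tasks Integer vector of tasks whose generative parameters
#'   respond to severity; tasks outside the set are generated at effective
#'   severity 0 (noise only). Used for planted-signal scenarios.
#' @param noise_scale Global multiplier on every noise SD, jitter and error
#'   probability; 0 gives fully deterministic noiseless streams.
#' @param accel_rate Accelerometer sampling rate (Hz).
#' @return A `pd_generator_config` list.
#' @export
generator_config <- function(n_pd = 50, n_hc = 29, seed = 1,
                             severity_pd = c(2, 2.3),
                             severity_hc = c(1.5, 9.5),
                             severity_pd_min = 0.12,
                             mu0 = 0.35, alpha = 0.8, fatigue_drift = 0.05,
                             interval_cv = 0.1,
                             sigma0 = 6, sigma_inflation = 2,
                             alt_error_slope = 0.25,
                             miss_base = 0.02, miss_slope = 0.25,
                             target_interval_factor = 2.5,
                             tremor_gain = 1.5, tremor_band = c(4, 6),
                             tremor_prevalence = 0.75,
                             accel_noise_sd = 0.08,
                             angle_gain = 0.15, angle_noise_sd = 0.01,
                             trace_speed0 = 80, trace_slow = 0.35,
                             vel_decay = 0.3,
                             radius_decay = 6, angvel_decay = 0.25,
                             trail_noise0 = 2, trail_noise_slope = 8,
                             lag_slope = 0.4,
                             gait_v0 = 1.2, gait_beta = 0.5,
                             cadence0 = 1.8, cadence_beta = 0.3,
                             foot_rate0 = 3, foot_beta = 0.5,
                             label_noise_sd = 4,
                             hy_breaks = c(0.35, 0.6, 0.8, 0.92),
                             hand_asymmetry = 0.15,
                             severity_tasks = 1:11,
                             noise_scale = 1,
                             accel_rate = 50) {
  cfg <- as.list(environment())
  num <- cfg[!names(cfg) %in% c("severity_tasks")]
  if (any(unlist(num) < 0, na.rm = TRUE)) {
    abort("all generator rates, amplitudes and sizes must be >= 0")
  }
  structure(cfg, class = "pd_generator_config")
}

#' Assign clinical labels from latent severity
#'
#' Maps severity to an MDS-UPDRS Part III total as
#' `round(clip(68 * s + e, 0, 68))` with Gaussian label noise `e` (the scale
#' spans 0--68 in this cohort design), and to a Hoehn & Yahr stage by a fixed
#' monotone binning of severity for PD; healthy controls are assigned stage 0.
#'
#' @param s Latent severity in \[0, 1\] (vectorised).
#' @param group `"PD"` or `"HC"` (recycled).
#' @param config A [generator_config()].
#' @return Tibble with columns `group`, `updrs3_score`, `hy_stage`.
#' @export
assign_labels <- function(s, group, config = generator_config()) {
  stopifnot(all(s >= 0 & s <= 1))
  n <- length(s)
  group <- rep_len(group, n)
  eps <- rnorm(n, 0, config$label_noise_sd * config$noise_scale)
  score <- as.integer(round(clip(68 * s + eps, 0, 68)))
  stage <- ifelse(group == "HC", 0L,
                  1L + findInterval(s, config$hy_breaks))
  tibble(group = group, updrs3_score = score, hy_stage = as.integer(stage))
}

# Effective severity for a task given the severity_tasks mask.
task_severity <- function(s, task_id, config) {
  if (task_id %in% config$severity_tasks) s else 0
}

# ---- per-task stream generators ------------------------------------------

sim_tapping <- function(spec, s, cfg) {
  ns <- cfg$noise_scale
  mu <- cfg$mu0 * (1 + cfg$alpha * s)
  if (spec$task_id == 5L) mu <- mu * cfg$target_interval_factor
  sigma <- cfg$sigma0 * (1 + cfg$sigma_inflation * s) * ns
  p_alt <- clip(cfg$alt_error_slope * s * ns, 0, 0.9)
  p_miss <- clip((cfg$miss_base + cfg$miss_slope * s) * ns, 0, 0.9)
  D <- spec$duration
  circles <- spec$circles

  t <- 0; times <- numeric(0); sides <- integer(0)
  side <- 1L
  repeat {
    dt <- mu * (1 + cfg$fatigue_drift * s * t) *
      (1 + rnorm(1, 0, cfg$interval_cv * ns))
    dt <- max(dt, 0.05)
    t <- t + dt
    if (t > D) break
    if (nrow(circles) == 2L && length(times) > 0L) {
      side <- if (runif(1) < p_alt) side else 3L - side
    } else if (nrow(circles) == 2L) {
      side <- 1L
    } else side <- 1L
    times <- c(times, t); sides <- c(sides, side)
  }
  n <- length(times)
  if (n == 0L) {
    return(tibble(t = numeric(0), x = numeric(0), y = numeric(0),
                  pointer = character(0), event = character(0)))
  }
  cx <- circles$cx[sides]; cy <- circles$cy[sides]; r <- circles$r[sides]
  x <- cx + rnorm(n, 0, sigma)
  y <- cy + rnorm(n, 0, sigma)
  miss <- runif(n) < p_miss
  if (any(miss)) {
    k <- sum(miss)
    dist <- r[miss] * (1.05 + stats::rexp(k, rate = 2.5))
    ang <- runif(k, 0, 2 * pi)
    x[miss] <- cx[miss] + dist * cos(ang)
    y[miss] <- cy[miss] + dist * sin(ang)
  }
  pointer <- if (nrow(circles) == 2L) c("left", "right")[sides] else "only"
  down <- tibble(t = times, x = x, y = y, pointer = pointer, event = "down")
  up <- dplyr::mutate(down, t = .data$t + 0.04, event = "up")
  dplyr::arrange(dplyr::bind_rows(down, up), .data$t)
}

# Follow a polyline trail at a (possibly decaying) speed, shrinking radially
# toward the trail centroid; returns move samples at `rate` Hz.
sim_trace <- function(spec, s, cfg, rate = 15) {
  ns <- cfg$noise_scale
  D <- spec$duration
  trail <- spec$trail
  centroid <- c(mean(trail$x), mean(trail$y))
  if (spec$task_id == 6L) trail <- trail[c(seq_len(nrow(trail)), 1L), ]  # close the loop
  seg <- sqrt(diff(trail$x)^2 + diff(trail$y)^2)
  cumlen <- c(0, cumsum(seg))
  total <- max(cumlen)

  tt <- seq(0, D, by = 1 / rate)
  v0 <- cfg$trace_speed0 / (1 + cfg$trace_slow * s)
  v <- v0 * (1 - cfg$vel_decay * s * tt / D)
  dgrid <- c(0, cumsum(v[-length(v)] / rate))
  if (spec$task_id == 6L) {
    dgrid <- dgrid %% total   # circle: keep looping
  } else {
    dgrid <- pmin(dgrid, total)
  }
  x <- stats::approx(cumlen, trail$x, xout = dgrid, rule = 2)$y
  y <- stats::approx(cumlen, trail$y, xout = dgrid, rule = 2)$y
  mean_r <- mean(sqrt((trail$x - centroid[1])^2 + (trail$y - centroid[2])^2))
  shrink <- pmax(1 - cfg$radius_decay * s * tt / mean_r, 0.3)
  noise_sd <- (cfg$trail_noise0 + cfg$trail_noise_slope * s) * ns
  x <- centroid[1] + (x - centroid[1]) * shrink + rnorm(length(tt), 0, noise_sd)
  y <- centroid[2] + (y - centroid[2]) * shrink + rnorm(length(tt), 0, noise_sd)
  tibble(t = tt, x = x, y = y, pointer = "only", event = "move")
}

sim_draw <- function(spec, s, cfg, rate = 15) {
  ns <- cfg$noise_scale
  D <- spec$duration
  cx <- spec$screen_width / 2; cy <- spec$screen_height / 2
  tt <- seq(0, D, by = 1 / rate)
  omega0 <- 3.5 * (1 - 0.2 * s)
  omega <- pmax(omega0 - cfg$angvel_decay * s * tt, 0.8)
  theta <- c(0, cumsum(omega[-length(omega)] / rate))
  R0 <- 150 * (1 - 0.25 * s)
  R <- pmax(R0 - cfg$radius_decay * s * tt, 40)
  noise_sd <- (2 + 4 * s) * ns
  tibble(t = tt,
         x = cx + R * cos(theta) + rnorm(length(tt), 0, noise_sd),
         y = cy + R * sin(theta) + rnorm(length(tt), 0, noise_sd),
         pointer = "only", event = "move")
}

sim_coord <- function(spec, s, cfg, rate = 15) {
  ns <- cfg$noise_scale
  D <- spec$duration
  left <- spec$trails$left
  W <- spec$screen_width
  seg <- sqrt(diff(left$x)^2 + diff(left$y)^2)
  cumlen <- c(0, cumsum(seg)); total <- max(cumlen)
  tt <- seq(0, D, by = 1 / rate)
  frac <- clip(tt / D, 0, 1)
  pos_at <- function(f) {
    d <- f * total
    cbind(stats::approx(cumlen, left$x, xout = d, rule = 2)$y,
          stats::approx(cumlen, left$y, xout = d, rule = 2)$y)
  }
  noise_sd <- (1 + 5 * s) * ns
  lp <- pos_at(frac)
  lx <- lp[, 1] + rnorm(length(tt), 0, noise_sd * 0.5)
  ly <- lp[, 2] + rnorm(length(tt), 0, noise_sd * 0.5)
  tau <- cfg$lag_slope * s
  rp <- pos_at(clip((tt - tau) / D, 0, 1))
  rx <- (W - rp[, 1]) + rnorm(length(tt), 0, noise_sd)
  ry <- rp[, 2] + rnorm(length(tt), 0, noise_sd)
  out <- dplyr::bind_rows(
    tibble(t = tt, x = lx, y = ly, pointer = "left", event = "move"),
    tibble(t = tt, x = rx, y = ry, pointer = "right", event = "move")
  )
  dplyr::arrange(out, .data$t, .data$pointer)
}

sim_tremor <- function(spec, s, cfg, tremor_factor = 1) {
  ns <- cfg$noise_scale
  rate <- cfg$accel_rate
  tt <- seq(0, spec$duration - 1 / rate, by = 1 / rate)
  n <- length(tt)
  f <- runif(1, cfg$tremor_band[1], cfg$tremor_band[2])
  amp <- cfg$tremor_gain * s * tremor_factor
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  phase <- runif(1, 0, 2 * pi)
  osc <- sin(2 * pi * f * tt + phase)
  noise <- cfg$accel_noise_sd * ns
  a_amp <- cfg$angle_gain * s
  a_noise <- cfg$angle_noise_sd * ns
  samples <- tibble(
    t = tt,
    ax = amp * dir[1] * osc + rnorm(n, 0, noise),
    ay = amp * dir[2] * osc + rnorm(n, 0, noise),
    az = 9.81 + amp * dir[3] * osc + rnorm(n, 0, noise),
    roll = a_amp * 0.8 * sin(2 * pi * f * tt + phase + 0.5) + rnorm(n, 0, a_noise),
    pitch = a_amp * 0.6 * sin(2 * pi * f * tt + phase + 1.1) + rnorm(n, 0, a_noise),
    yaw = a_amp * 0.3 * sin(2 * pi * f * tt + phase + 2.0) + rnorm(n, 0, a_noise)
  )
  list(rate = rate, samples = samples)
}

# Gaussian acceleration bumps at given event times on a noisy baseline.
peak_train_stream <- function(event_times, duration, amp, cfg, width = 0.05) {
  ns <- cfg$noise_scale
  rate <- cfg$accel_rate
  tt <- seq(0, duration - 1 / rate, by = 1 / rate)
  n <- length(tt)
  az <- rep(9.81, n)
  for (et in event_times) {
    az <- az + amp * exp(-0.5 * ((tt - et) / width)^2)
  }
  noise <- cfg$accel_noise_sd * ns
  samples <- tibble(
    t = tt,
    ax = rnorm(n, 0, noise), ay = rnorm(n, 0, noise),
    az = az + rnorm(n, 0, noise),
    roll = rnorm(n, 0, cfg$angle_noise_sd * ns),
    pitch = rnorm(n, 0, cfg$angle_noise_sd * ns),
    yaw = rnorm(n, 0, cfg$angle_noise_sd * ns)
  )
  list(rate = rate, samples = samples)
}

sim_foot <- function(spec, s, cfg) {
  ns <- cfg$noise_scale
  rate_taps <- cfg$foot_rate0 * (1 - cfg$foot_beta * s)
  D <- spec$duration
  times <- seq(0.5, D - 0.5, by = 1 / rate_taps)
  if (length(times) > 2L) {
    jit <- rnorm(length(times) - 2L, 0, 0.02 * (1 + s) * ns)
    times[-c(1L, length(times))] <- times[-c(1L, length(times))] + jit
    times <- sort(times)
  }
  peak_train_stream(times, D, amp = 2.5 * (1 - 0.3 * s), cfg)
}

sim_gait <- function(spec, s, cfg) {
  ns <- cfg$noise_scale
  v <- cfg$gait_v0 * (1 - cfg$gait_beta * s)
  walk_time <- 6 / v
  cadence <- cfg$cadence0 * (1 - cfg$cadence_beta * s)
  n_steps <- max(4L, as.integer(round(walk_time * cadence)) + 1L)
  times <- seq(1, 1 + walk_time, length.out = n_steps)
  if (n_steps > 2L) {
    jit <- rnorm(n_steps - 2L, 0, 0.015 * ns)
    times[-c(1L, n_steps)] <- sort(times[-c(1L, n_steps)] + jit)
  }
  peak_train_stream(times, duration = walk_time + 3, amp = 3, cfg)
}

#' Simulate one subject's full task battery
#'
#' Generates raw streams for all eleven tasks (hand-specific tasks once per
#' hand) from a latent severity. Severity effects are mildly asymmetric
#' between hands, mirroring the typical lateralisation of PD motor signs.
#'
#' @param subject_id Identifier.
#' @param group `"PD"` or `"HC"`.
#' @param s Latent severity in \[0, 1\].
#' @param labels Optional list/row with `updrs3_score`, `hy_stage`, `moca`,
#'   `age`, `gender`; drawn from the severity map when omitted.
#' @param config A [generator_config()].
#' @param specs Task battery from [task_specs()].
#' @param seed Seed for this subject's streams; the same seed reproduces an
#'   identical record.
#' @return A `pd_subject`.
#' @export
simulate_subject <- function(subject_id, group, s,
                             labels = NULL,
                             config = generator_config(),
                             specs = task_specs(),
                             seed = 1) {
  stopifnot(s >= 0, s <= 1)
  set.seed(seed)
  if (is.null(labels)) {
    lab <- assign_labels(s, group, config)
    labels <- list(updrs3_score = lab$updrs3_score, hy_stage = lab$hy_stage,
                   moca = as.integer(round(clip(rnorm(1, 26, 2.5), 16, 30))),
                   age = round(clip(rnorm(1, 68, 8.5), 43, 88)),
                   gender = sample(c("F", "M"), 1))
  }
  # rest/postural tremor in the 4-6 Hz band is a parkinsonian sign: controls
  # carry baseline sensor noise only, however slow their voluntary movements,
  # and a minority of PD patients are non-tremor-dominant
  tremor_factor <- if (group == "PD") {
    if (runif(1) < config$tremor_prevalence) 1 else 0.15
  } else 0
  sessions <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    s_task <- task_severity(s, spec$task_id, config)
    for (hand in spec$hands) {
      s_eff <- s_task
      if (hand == "L") s_eff <- clip(s_task * (1 + config$hand_asymmetry), 0, 1)
      if (hand == "R") s_eff <- clip(s_task * (1 - config$hand_asymmetry), 0, 1)
      ses <- list(task_id = spec$task_id, hand = hand)
      if (spec$kind == "tap") {
        ses$touch <- sim_tapping(spec, s_eff, config)
      } else if (spec$kind == "trace") {
        ses$touch <- sim_trace(spec, s_eff, config)
      } else if (spec$kind == "draw") {
        ses$touch <- sim_draw(spec, s_eff, config)
      } else if (spec$kind == "coord") {
        ses$touch <- sim_coord(spec, s_eff, config)
      } else if (spec$task_id %in% c(3L, 4L)) {
        ses$accel <- sim_tremor(spec, s_eff, config, tremor_factor)
      } else if (spec$task_id == 10L) {
        ses$accel <- sim_foot(spec, s_eff, config)
      } else if (spec$task_id == 11L) {
        ses$accel <- sim_gait(spec, s_eff, config)
      }
      key <- if (hand %in% c("L", "R")) sprintf("task%d_%s", spec$task_id, hand)
             else sprintf("task%d", spec$task_id)
      sessions[[key]] <- ses
    }
  }
  subject_record(subject_id, group, labels$updrs3_score, labels$hy_stage,
                 moca = labels$moca %||% NA_integer_,
                 age = labels$age %||% NA_real_,
                 gender = labels$gender %||% NA_character_,
                 sessions = sessions)
}

#' Simulate a synthetic cohort
#'
#' Draws per-group latent severities, assigns clinical labels from the
#' severity map, and simulates the full task battery for every subject.
#' One root seed determines the whole cohort; each subject's streams come
#' from a deterministically derived child seed, so cohorts are reproducible.
#'
#' @param config A [generator_config()].
#' @param specs Task battery from [task_specs()].
#' @return A `pd_cohort` tibble (one row per subject, `sessions` list-column).
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_config(n_pd = 3, n_hc = 2, seed = 1))
#' cohort_manifest(cohort)
simulate_cohort <- function(config = generator_config(), specs = task_specs()) {
  n_pd <- config$n_pd; n_hc <- config$n_hc
  if (n_pd + n_hc == 0) abort("cohort must contain at least one subject")
  set.seed(config$seed)
  s_pd <- config$severity_pd_min +
    (1 - config$severity_pd_min) * rbeta(n_pd, config$severity_pd[1],
                                         config$severity_pd[2])
  s_hc <- rbeta(n_hc, config$severity_hc[1], config$severity_hc[2])
  s_all <- c(s_pd, s_hc)
  groups <- c(rep("PD", n_pd), rep("HC", n_hc))
  ids <- c(sprintf("PD%03d", seq_len(n_pd)), sprintf("HC%03d", seq_len(n_hc)))
  records <- purrr::map(seq_along(s_all), function(i) {
    simulate_subject(ids[i], groups[i], s_all[i], labels = NULL,
                     config = config, specs = specs,
                     seed = child_seed(config$seed, i))
  })
  cohort <- as_cohort(records)
  attr(cohort, "severity") <- s_all
  cohort
}
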