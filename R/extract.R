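#' Extraction configuration
#'
#' Tunable parameters of the feature extraction layer.
#'
#' @param freq_window Tapping-frequency window length (s).
#' @param trace_rate Position resampling rate for centroid-distance series
#'   (Hz).
#' @param angular_interval Angular-velocity sampling interval (s).
#' @param tremor_band Tremor spectral analysis band (Hz).
#' @param tremor_spectrum `"per_axis"` or `"magnitude"`.
#' @param pass_eps Passed-trail-point tolerance (points).
#' @param foot_separation,gait_separation Minimum peak separation (s) for
#'   foot taps and gait steps.
#' @param gait_distance Gait course length (m).
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(freq_window = 1, trace_rate = 3,
                              angular_interval = 0.3,
                              tremor_band = c(1, 12),
                              tremor_spectrum = "per_axis",
                              pass_eps = 10,
                              foot_separation = 0.25,
                              gait_separation = 0.4,
                              gait_distance = 6) {
  structure(as.list(environment()), class = "extraction_config")
}

#' Feature registry
#'
#' The full named feature set produced by the extraction layer, with the
#' task each feature belongs to. Hand-specific tasks contribute `_L`/`_R`
#' suffixed columns. Feature names have the form `task{k}_{feature}[_{L|R}]`.
#'
#' @return Tibble with columns `feature` and `task`.
#' @export
feature_registry <- function() {
  per_hand <- function(task, feats) {
    tibble(feature = c(sprintf("task%d_%s_L", task, feats),
                       sprintf("task%d_%s_R", task, feats)),
           task = task)
  }
  plain <- function(task, feats) {
    tibble(feature = sprintf("task%d_%s", task, feats), task = task)
  }
  tap1 <- c("total_taps", "valid_taps", "missed", "bias",
            "interval_mean", "interval_var", "freq_slope")
  tremor <- c("accel_sd_x", "accel_sd_y", "accel_sd_z",
              "accel_rms_x", "accel_rms_y", "accel_rms_z",
              "rot_sd_roll", "rot_sd_pitch", "rot_sd_yaw", "tremor_freq")
  trace <- c("bias", "velocity_mean", "velocity_slope", "radius_slope")
  dplyr::bind_rows(
    per_hand(1L, tap1),
    per_hand(2L, c(tap1, "paired_taps")),
    plain(3L, tremor),
    plain(4L, tremor),
    per_hand(5L, c("duration", "total_taps", "valid_taps",
                   "interval_mean", "interval_var", "freq_slope")),
    per_hand(6L, trace),
    per_hand(7L, trace),
    per_hand(8L, c(trace, "angvel_mean", "angvel_slope")),
    plain(9L, c("bias_L", "bias_R", "velocity_mean_L", "velocity_mean_R",
                "velocity_slope_L", "velocity_slope_R",
                "lr_coordination", "passed_points")),
    plain(10L, "tapped"),
    plain(11L, c("walking_velocity", "total_steps"))
  )
}

# Extract the features of a single session; returns a named numeric list.
extract_session_features <- function(ses, spec, config) {
  tid <- spec$task_id
  if (spec$kind == "tap") {
    taps <- detect_taps(ses$touch, spec)
    iv <- interval_stats(taps)
    fs <- frequency_slope(taps, config$freq_window)
    out <- list(total_taps = as.numeric(nrow(taps)),
                valid_taps = as.numeric(sum(taps$valid)),
                missed = as.numeric(sum(!taps$valid)),
                bias = tap_bias(taps, spec),
                interval_mean = iv$mean, interval_var = iv$var,
                freq_slope = fs$slope)
    if (tid == 2L) out$paired_taps <- as.numeric(count_paired_taps(taps, spec))
    if (tid == 5L) {
      out$duration <- if (nrow(taps) >= 2L) max(taps$t) - min(taps$t) else NA_real_
      out$bias <- NULL; out$missed <- NULL
    }
    return(out)
  }
  if (spec$kind == "trace") {
    centroid <- c(mean(spec$trail$x), mean(spec$trail$y))
    vel <- trace_velocity_features(ses$touch)
    rad <- centroid_distance_slope(ses$touch, centroid, config$trace_rate)
    return(list(bias = trail_bias(ses$touch, spec$trail),
                velocity_mean = vel$mean, velocity_slope = vel$slope,
                radius_slope = rad$slope))
  }
  if (spec$kind == "draw") {
    vel <- trace_velocity_features(ses$touch)
    rad <- centroid_distance_slope(ses$touch, NULL, config$trace_rate)
    ang <- circle_drawing_angular(ses$touch, config$angular_interval)
    mv <- dplyr::filter(ses$touch, .data$event == "move")
    bias <- if (nrow(mv) < 2L) NA_real_ else {
      cx <- mean(mv$x); cy <- mean(mv$y)
      r <- sqrt((mv$x - cx)^2 + (mv$y - cy)^2)
      mean(abs(r - mean(r)))
    }
    return(list(bias = bias, velocity_mean = vel$mean,
                velocity_slope = vel$slope, radius_slope = rad$slope,
                angvel_mean = ang$mean, angvel_slope = ang$slope))
  }
  if (spec$kind == "coord") {
    return(coordination_features(ses$touch, spec, config$pass_eps))
  }
  if (tid %in% c(3L, 4L)) {
    return(tremor_features(ses$accel, config$tremor_band,
                           config$tremor_spectrum))
  }
  if (tid == 10L) {
    return(list(tapped = as.numeric(
      count_acceleration_peaks(ses$accel, min_separation = config$foot_separation))))
  }
  if (tid == 11L) {
    g <- gait_features(ses$accel, config$gait_distance, config$gait_separation)
    return(list(walking_velocity = g$walking_velocity,
                total_steps = as.numeric(g$total_steps)))
  }
  list()
}

#' Extract the full feature vector for one subject
#'
#' Runs every extractor on every available session. Hand-specific features
#' are suffixed `_L`/`_R`; features from absent sessions or degenerate
#' streams are `NA` (flagged, then imputed at the cohort level).
#'
#' @param rec A `pd_subject`.
#' @param specs Task battery from [task_specs()].
#' @param config An [extraction_config()].
#' @return A named numeric vector covering the whole [feature_registry()].
#' @export
extract_subject_features <- function(rec, specs = task_specs(),
                                     config = extraction_config()) {
  reg <- feature_registry()
  out <- setNames(rep(NA_real_, nrow(reg)), reg$feature)
  for (key in names(rec$sessions)) {
    ses <- rec$sessions[[key]]
    spec <- specs[[sprintf("task%d", ses$task_id)]]
    if (is.null(spec)) next
    feats <- extract_session_features(ses, spec, config)
    hand <- ses$hand %||% "only"
    for (fn in names(feats)) {
      name <- if (hand %in% c("L", "R")) {
        sprintf("task%d_%s_%s", ses$task_id, fn, hand)
      } else sprintf("task%d_%s", ses$task_id, fn)
      if (name %in% names(out)) {
        out[name] <- if (is.null(feats[[fn]])) NA_real_ else as.numeric(feats[[fn]])
      }
    }
  }
  out
}

#' Extract the cohort feature table
#'
#' Applies [extract_subject_features()] to every subject and assembles the
#' subjects-by-features table with the label columns in front. Missing
#' values (absent hand sessions, degenerate streams) are imputed with the
#' column median and recorded in the `imputed` attribute; columns that are
#' entirely missing are imputed with 0.
#'
#' @param cohort A `pd_cohort` tibble.
#' @param specs Task battery from [task_specs()].
#' @param config An [extraction_config()].
#' @return A tibble of class `pd_features`: `subject_id`, `group`,
#'   `updrs3_score`, `hy_stage`, then one column per registry feature.
#'   Attribute `imputed` is a tibble (`subject_id`, `feature`) of imputed
#'   cells.
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_config(n_pd = 2, n_hc = 2, seed = 7))
#' feats <- extract_features(cohort)
#' dim(feats)
extract_features <- function(cohort, specs = task_specs(),
                             config = extraction_config()) {
  reg <- feature_registry()
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    extract_subject_features(cohort_row_record(cohort, i), specs, config)
  })
  mat <- do.call(rbind, rows)
  imputed <- tibble(subject_id = character(0), feature = character(0))
  for (j in seq_len(ncol(mat))) {
    nas <- is.na(mat[, j])
    if (any(nas)) {
      imputed <- dplyr::bind_rows(imputed, tibble(
        subject_id = cohort$subject_id[nas], feature = colnames(mat)[j]))
      fill <- stats::median(mat[!nas, j])
      if (!is.finite(fill)) fill <- 0
      mat[nas, j] <- fill
    }
  }
  out <- dplyr::bind_cols(
    tibble(subject_id = cohort$subject_id, group = cohort$group,
           updrs3_score = cohort$updrs3_score, hy_stage = cohort$hy_stage),
    as_tibble(mat)
  )
  stopifnot(identical(colnames(mat), reg$feature), !anyNA(mat))
  attr(out, "imputed") <- imputed
  class(out) <- c("pd_features", class(out))
  out
}

# Names of the non-feature (label/id) columns of a feature table.
label_columns <- function() c("subject_id", "group", "updrs3_score", "hy_stage")

# Feature columns of a feature table, in registry order where possible.
feature_columns <- function(table) setdiff(names(table), label_columns())

# Map feature names to task ids via the task{k}_ prefix.
feature_task_map <- function(features) {
  pos <- regexpr("^task([0-9]+)_", features)
  if (any(pos == -1L)) {
    abort(sprintf("feature(s) not mapped to a task: %s",
                  paste(features[pos == -1L], collapse = ", ")))
  }
  as.integer(sub("^task([0-9]+)_.*$", "\\1", features))
}
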