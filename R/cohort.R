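#' Task battery geometry
#'
#' Returns the specification of the eleven-task motor battery: target circle
#' geometry for the tapping tasks, reference trails for the tracing and
#' coordination tasks, nominal session durations, which tasks are performed
#' once per hand, and the kind of raw stream each task records. Coordinates
#' use the mobile convention: origin at the top-left of the screen, x
#' rightward, y downward, units are screen points.
#'
#' The battery comprises: 1 single tapping, 2 alternating two-circle tapping,
#' 3 rest tremor, 4 postural tremor, 5 target (nose-to-screen) tapping,
#' 6 circle tracing, 7 spiral tracing, 8 free circle drawing, 9 bimanual
#' coordination (two mirror-symmetric trails), 10 foot tapping, 11 gait.
#'
#' @param screen_width,screen_height Screen dimensions in points.
#' @return A named list of task specifications (names `"task1"` ... `"task11"`),
#'   each a list with `task_id`, `name`, `kind` (`"tap"`, `"trace"`, `"draw"`,
#'   `"coord"`, `"accel"`), `hands`, `duration` (seconds), and where relevant
#'   `circles` (tibble `cx, cy, r`), `trail` / `trails` (tibbles `x, y`), and
#'   `screen_width`.
#' @export
#' @examples
#' specs <- task_specs()
#' specs$task2$circles
task_specs <- function(screen_width = 400, screen_height = 600) {
  cx <- screen_width / 2
  cy <- screen_height / 2

  circle_trail <- function(r, n = 120) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    tibble(x = cx + r * cos(th), y = cy + r * sin(th))
  }
  spiral_trail <- function(n = 180) {
    th <- seq(0, 6 * pi, length.out = n)
    r <- 10 + (130 - 10) * th / (6 * pi)
    tibble(x = cx + r * cos(th), y = cy + r * sin(th))
  }
  coord_trail_left <- function(n = 80) {
    y <- seq(100, screen_height - 100, length.out = n)
    x <- screen_width * 0.25 + 40 * sin(2 * pi * (y - 100) / (screen_height - 200))
    tibble(x = x, y = y)
  }

  left <- coord_trail_left()
  spec <- list(
    task1 = list(task_id = 1L, name = "single tapping", kind = "tap",
                 hands = c("L", "R"), duration = 10,
                 circles = tibble(cx = cx, cy = cy, r = 50)),
    task2 = list(task_id = 2L, name = "alternating tapping", kind = "tap",
                 hands = c("L", "R"), duration = 10,
                 circles = tibble(cx = c(cx - 80, cx + 80), cy = cy, r = 50)),
    task3 = list(task_id = 3L, name = "rest tremor", kind = "accel",
                 hands = "only", duration = 10),
    task4 = list(task_id = 4L, name = "postural tremor", kind = "accel",
                 hands = "only", duration = 10),
    task5 = list(task_id = 5L, name = "target tapping", kind = "tap",
                 hands = c("L", "R"), duration = 15,
                 circles = tibble(cx = cx, cy = cy, r = 60)),
    task6 = list(task_id = 6L, name = "circle tracing", kind = "trace",
                 hands = c("L", "R"), duration = 10, trail = circle_trail(120)),
    task7 = list(task_id = 7L, name = "spiral tracing", kind = "trace",
                 hands = c("L", "R"), duration = 10, trail = spiral_trail()),
    task8 = list(task_id = 8L, name = "circle drawing", kind = "draw",
                 hands = c("L", "R"), duration = 10),
    task9 = list(task_id = 9L, name = "coordination", kind = "coord",
                 hands = "only", duration = 10,
                 trails = list(
                   left = left,
                   right = tibble(x = screen_width - left$x, y = left$y)
                 ),
                 screen_width = screen_width),
    task10 = list(task_id = 10L, name = "foot tapping", kind = "accel",
                  hands = "only", duration = 10),
    task11 = list(task_id = 11L, name = "gait", kind = "accel",
                  hands = "only", duration = NA_real_)
  )
  for (k in seq_along(spec)) {
    spec[[k]]$screen_width <- screen_width
    spec[[k]]$screen_height <- screen_height
  }
  spec
}

hand_tasks <- function() c(1L, 2L, 5L, 6L, 7L, 8L)

#' Construct a subject record
#'
#' A subject record bundles one participant's metadata, clinical labels and
#' the raw session streams for each completed task. Healthy controls carry
#' Hoehn & Yahr stage 0 by convention; the MDS-UPDRS Part III score is
#' recorded for both groups.
#'
#' @param subject_id Character identifier.
#' @param group `"PD"` or `"HC"`.
#' @param updrs3_score Non-negative integer MDS-UPDRS Part III total.
#' @param hy_stage Integer 0--5; must be 0 for HC and 1--5 for PD.
#' @param moca MoCA score, 0--30.
#' @param age Age in years.
#' @param gender `"F"` or `"M"`.
#' @param sessions Named list of task sessions (names like `"task1_L"`,
#'   `"task9"`), each a list with `task_id`, `hand`, and a `touch` tibble
#'   (`t, x, y, pointer, event`) and/or an `accel` list
#'   (`rate`, `samples` tibble `t, ax, ay, az, roll, pitch, yaw`).
#' @return A validated object of class `pd_subject`.
#' @export
subject_record <- function(subject_id, group, updrs3_score, hy_stage,
                           moca = NA_integer_, age = NA_real_,
                           gender = NA_character_, sessions = list()) {
  rec <- structure(
    list(subject_id = as.character(subject_id), group = group,
         updrs3_score = as.integer(updrs3_score),
         hy_stage = as.integer(hy_stage), moca = as.integer(moca),
         age = as.numeric(age), gender = gender, sessions = sessions),
    class = "pd_subject"
  )
  validate_subject_record(rec)
  rec
}

#' Validate a subject record
#'
#' Checks group/label consistency (HC implies Hoehn & Yahr stage 0, PD
#' implies stage 1--5), task identifiers, and every stream invariant:
#' non-decreasing touch timestamps, strictly increasing accelerometer
#' timestamps, and near-uniform accelerometer sampling.
#'
#' @param rec A `pd_subject`.
#' @return The record, invisibly; errors describe the offending task.
#' @export
validate_subject_record <- function(rec) {
  if (!rec$group %in% c("PD", "HC")) {
    abort(sprintf("group must be 'PD' or 'HC', got '%s'", rec$group))
  }
  if (is.na(rec$updrs3_score) || rec$updrs3_score < 0L) {
    abort("updrs3_score must be a non-negative integer")
  }
  if (rec$group == "HC" && rec$hy_stage != 0L) {
    abort(sprintf("subject %s: HC subjects must have hy_stage 0 (got %d)",
                  rec$subject_id, rec$hy_stage))
  }
  if (rec$group == "PD" && !(rec$hy_stage %in% 1:5)) {
    abort(sprintf("subject %s: PD subjects must have hy_stage in 1..5 (got %d)",
                  rec$subject_id, rec$hy_stage))
  }
  for (nm in names(rec$sessions)) {
    ses <- rec$sessions[[nm]]
    if (!ses$task_id %in% 1:11) {
      abort(sprintf("session %s: task_id must be in 1..11", nm))
    }
    if (!is.null(ses$touch) && nrow(ses$touch) > 1L) {
      if (any(diff(ses$touch$t) < 0)) {
        abort(sprintf("task %d: touch timestamps must be non-decreasing",
                      ses$task_id))
      }
    }
    if (!is.null(ses$accel)) {
      ts <- ses$accel$samples$t
      if (length(ts) > 1L) {
        dt <- diff(ts)
        if (any(dt <= 0)) {
          abort(sprintf("task %d: accelerometer timestamps must be strictly increasing",
                        ses$task_id))
        }
        if (max(abs(dt - mean(dt))) > 0.01 * mean(dt) + 1e-9) {
          abort(sprintf("task %d: accelerometer sampling jitter exceeds 1%%; resample first",
                        ses$task_id))
        }
      }
    }
  }
  invisible(rec)
}

#' @export
print.pd_subject <- function(x, ...) {
  cat(sprintf("<pd_subject %s: %s, UPDRS-III %d, H&Y %d, %d session(s)>\n",
              x$subject_id, x$group, x$updrs3_score, x$hy_stage,
              length(x$sessions)))
  invisible(x)
}

#' Assemble a cohort tibble from subject records
#'
#' A cohort is a tibble with one row per subject: the metadata and label
#' columns plus a `sessions` list-column holding each subject's raw streams.
#' This is the container every downstream stage (feature extraction,
#' classification, importance analysis) consumes.
#'
#' @param records List of `pd_subject` objects.
#' @return A tibble of class `pd_cohort`.
#' @export
as_cohort <- function(records) {
  stopifnot(length(records) > 0L)
  out <- purrr::map_dfr(records, function(r) {
    tibble(subject_id = r$subject_id, group = r$group,
           updrs3_score = r$updrs3_score, hy_stage = r$hy_stage,
           moca = r$moca, age = r$age, gender = r$gender,
           sessions = list(r$sessions))
  })
  class(out) <- c("pd_cohort", class(out))
  out
}

# One cohort row back to a pd_subject (no re-validation; rows come validated).
cohort_row_record <- function(cohort, i) {
  structure(
    list(subject_id = cohort$subject_id[i], group = cohort$group[i],
         updrs3_score = cohort$updrs3_score[i], hy_stage = cohort$hy_stage[i],
         moca = cohort$moca[i], age = cohort$age[i], gender = cohort$gender[i],
         sessions = cohort$sessions[[i]]),
    class = "pd_subject"
  )
}

#' Cohort manifest
#'
#' @param cohort A `pd_cohort` tibble.
#' @return Tibble with `subject_id`, `group`, `updrs3_score`, `hy_stage`.
#' @export
cohort_manifest <- function(cohort) {
  dplyr::select(as_tibble(cohort), "subject_id", "group",
                "updrs3_score", "hy_stage")
}
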