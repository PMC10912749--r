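#' Write a subject session file
#'
#' Serialises one subject record — metadata, labels and all raw task streams —
#' to a single JSON file. Touch samples are stored as `[t, x, y, pointer,
#' event]` rows and accelerometer samples as `[t, ax, ay, az, roll, pitch,
#' yaw]` rows, so ragged per-task streams round-trip exactly.
#'
#' @param rec A `pd_subject`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_file <- function(rec, path) {
  validate_subject_record(rec)
  sessions <- purrr::imap(rec$sessions, function(ses, nm) {
    out <- list(task_id = ses$task_id, hand = ses$hand %||% "only")
    if (!is.null(ses$spec)) {
      sp <- list()
      if (!is.null(ses$spec$circles)) {
        sp$circles <- purrr::pmap(ses$spec$circles,
                                  function(cx, cy, r) list(cx = cx, cy = cy, r = r))
      }
      if (!is.null(ses$spec$trail)) {
        sp$trail <- unname(as.matrix(ses$spec$trail))
      }
      out$task_spec <- sp
    }
    if (!is.null(ses$touch) && nrow(ses$touch) > 0L) {
      out$touch <- unname(purrr::pmap(ses$touch, function(t, x, y, pointer, event) {
        list(t, x, y, pointer, event)
      }))
    }
    if (!is.null(ses$accel)) {
      out$accel <- list(rate = ses$accel$rate,
                        samples = unname(as.matrix(ses$accel$samples)))
    }
    out
  })
  obj <- list(subject_id = rec$subject_id, group = rec$group,
              updrs3_score = rec$updrs3_score, hy_stage = rec$hy_stage,
              moca = rec$moca, age = rec$age, gender = rec$gender,
              sessions = unname(sessions))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a subject session file
#'
#' Parses a session JSON file written by [write_session_file()] (or produced
#' externally in the same schema) into a validated subject record. Stream
#' invariants (monotone touch time, strictly increasing uniformly sampled
#' accelerometer time, label consistency) are checked on read.
#'
#' @param path Path to a session JSON file.
#' @return A `pd_subject`.
#' @export
read_session_file <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) abort(sprintf("malformed session JSON '%s': %s",
                                                    path, conditionMessage(e))))
  req <- c("subject_id", "group", "updrs3_score", "hy_stage", "sessions")
  missing <- setdiff(req, names(obj))
  if (length(missing)) {
    abort(sprintf("session file '%s' lacks field(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  sessions <- list()
  for (ses in obj$sessions) {
    task_id <- as.integer(ses$task_id)
    hand <- ses$hand %||% "only"
    parsed <- list(task_id = task_id, hand = hand)
    if (!is.null(ses$task_spec)) {
      sp <- list()
      if (!is.null(ses$task_spec$circles)) {
        sp$circles <- purrr::map_dfr(ses$task_spec$circles, as_tibble)
      }
      if (!is.null(ses$task_spec$trail)) {
        m <- do.call(rbind, purrr::map(ses$task_spec$trail, unlist))
        sp$trail <- tibble(x = m[, 1], y = m[, 2])
      }
      parsed$spec <- sp
    }
    if (!is.null(ses$touch)) {
      rows <- purrr::map(ses$touch, unlist)
      parsed$touch <- tibble(
        t = as.numeric(purrr::map_chr(rows, 1)),
        x = as.numeric(purrr::map_chr(rows, 2)),
        y = as.numeric(purrr::map_chr(rows, 3)),
        pointer = purrr::map_chr(rows, 4),
        event = purrr::map_chr(rows, 5)
      )
    }
    if (!is.null(ses$accel)) {
      m <- do.call(rbind, purrr::map(ses$accel$samples, unlist))
      parsed$accel <- list(
        rate = as.numeric(ses$accel$rate),
        samples = tibble(t = m[, 1], ax = m[, 2], ay = m[, 3], az = m[, 4],
                         roll = m[, 5], pitch = m[, 6], yaw = m[, 7])
      )
    }
    key <- if (hand %in% c("L", "R")) sprintf("task%d_%s", task_id, hand)
           else sprintf("task%d", task_id)
    sessions[[key]] <- parsed
  }
  subject_record(obj$subject_id, obj$group, obj$updrs3_score, obj$hy_stage,
                 moca = obj$moca %||% NA_integer_, age = obj$age %||% NA_real_,
                 gender = obj$gender %||% NA_character_, sessions = sessions)
}

#' Write a feature table to CSV
#'
#' Columns are `subject_id`, the label columns (`group`, `updrs3_score`,
#' `hy_stage`), then the feature columns in registry order; UTF-8, "."
#' decimal separator, header mandatory.
#'
#' @param table Feature-table tibble from [extract_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (anyDuplicated(names(table))) {
    abort("feature table has duplicated column names")
  }
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Tibble with label columns and numeric feature columns.
#' @export
read_feature_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (anyDuplicated(names(out))) {
    abort("feature table has duplicated column names")
  }
  out
}
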