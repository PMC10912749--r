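# Stream and spec builders used across test files.

tap_stream <- function(t, x, y, pointer = "only") {
  tibble::tibble(t = t, x = x, y = y, pointer = pointer, event = "down")
}

move_stream <- function(t, x, y, pointer = "only") {
  tibble::tibble(t = t, x = x, y = y, pointer = pointer, event = "move")
}

one_circle_spec <- function(cx = 0, cy = 0, r = 50) {
  list(task_id = 1L, kind = "tap", circles = tibble::tibble(cx = cx, cy = cy, r = r),
       screen_width = 400, screen_height = 600)
}

two_circle_spec <- function() {
  list(task_id = 2L, kind = "tap",
       circles = tibble::tibble(cx = c(-100, 100), cy = c(0, 0), r = c(50, 50)),
       screen_width = 400, screen_height = 600)
}

accel_stream <- function(t, ax = 0, ay = 0, az = 0, roll = 0, pitch = 0,
                         yaw = 0, rate = NULL) {
  n <- length(t)
  if (is.null(rate)) rate <- 1 / stats::median(diff(t))
  list(rate = rate,
       samples = tibble::tibble(t = t, ax = rep_len(ax, n), ay = rep_len(ay, n),
                                az = rep_len(az, n), roll = rep_len(roll, n),
                                pitch = rep_len(pitch, n), yaw = rep_len(yaw, n)))
}

# A small feature table with task-prefixed gaussian columns; `effect` shifts
# the listed columns for the PD group.
toy_feature_table <- function(n_pd = 20, n_hc = 20, p = 6, effect = 2,
                              signal_cols = 1, seed = 1,
                              tasks = rep(1:2, length.out = p)) {
  set.seed(seed)
  n <- n_pd + n_hc
  group <- c(rep("PD", n_pd), rep("HC", n_hc))
  X <- matrix(rnorm(n * p), n, p)
  for (j in signal_cols) X[group == "PD", j] <- X[group == "PD", j] + effect
  colnames(X) <- sprintf("task%d_f%d", tasks, seq_len(p))
  score <- ifelse(group == "PD", 30L + round(X[, signal_cols[1]] * 3), 8L)
  tab <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)), group = group,
                   updrs3_score = pmax(0L, as.integer(score)),
                   hy_stage = ifelse(group == "PD", 2L, 0L)),
    tibble::as_tibble(X)
  )
  class(tab) <- c("pd_features", class(tab))
  tab
}
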