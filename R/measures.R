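#' Trial duration
#'
#' Duration in seconds is the difference between a window's stop and start
#' times.
#'
#' @param window A list or one-row data frame with `start_s` and `stop_s`.
#' @return Duration in seconds.
#' @export
compute_duration <- function(window) {
  d <- window$stop_s - window$start_s
  if (any(d <= 0)) stop("window stop must be after start", call. = FALSE)
  d
}

window_index <- function(stream, window) {
  # half-open [start, stop): a sample exactly at stop is excluded
  which(stream$t >= window$start_s & stream$t < window$stop_s)
}

#' Average total angular velocity of a trial
#'
#' Arithmetic mean over the in-window samples of `|Vx| + |Vy| + |Vz|`
#' (degrees/s). Equals the sum of the three per-axis means of absolute
#' angular velocity.
#'
#' @param rect A [rectify()]ed stream.
#' @param window A window with `start_s`, `stop_s`.
#' @return Mean total angular velocity, degrees/s.
#' @export
compute_avg_total_angular_velocity <- function(rect, window) {
  if (!inherits(rect, "rectified_stream")) rect <- rectify(rect)
  idx <- window_index(rect, window)
  if (length(idx) < 2L) stop("window contains fewer than 2 samples", call. = FALSE)
  mean(rect$v_total[idx])
}

#' Total standard deviation of acceleration of a trial
#'
#' Sum over the three accelerometer axes of the within-window sample
#' standard deviation (n-1 normalization). By default the SD is taken on
#' the signed acceleration channels: the variation-in-movement-forces
#' interpretation concerns the signed signal, and on a gravity-dominated
#' axis the SD of the rectified channel coincides with the signed SD only
#' when the axis never crosses zero. The rectified alternative is available
#' via `method = "rectified"`, and reports record which was used.
#'
#' @param stream A raw `sensor_stream` (signed channels).
#' @param window A window with `start_s`, `stop_s`.
#' @param method `"signed"` (default) or `"rectified"`.
#' @return Total SD of acceleration, m/s^2.
#' @export
compute_total_sd_acceleration <- function(stream, window,
                                          method = c("signed", "rectified")) {
  method <- match.arg(method)
  idx <- window_index(stream, window)
  if (length(idx) < 2L) stop("window contains fewer than 2 samples", call. = FALSE)
  acc <- as.matrix(stream[idx, c("accel_x", "accel_y", "accel_z")])
  if (method == "rectified") acc <- abs(acc)
  sum(apply(acc, 2L, stats::sd))
}

#' Per-channel summaries of a trial
#'
#' The average, standard deviation, max and min of each of the six rectified
#' channels (absolute angular velocity in degrees/s and absolute
#' acceleration in m/s^2) over the window.
#'
#' @param stream A `sensor_stream` (raw or rectified).
#' @param window A window with `start_s`, `stop_s`.
#' @return A one-row data frame with 24 columns named
#'   `<channel>_<stat>` for `stat` in `avg`, `sd`, `max`, `min`.
#' @export
compute_channel_summary <- function(stream, window) {
  rect <- if (inherits(stream, "rectified_stream")) stream else rectify(stream)
  idx <- window_index(rect, window)
  if (length(idx) < 2L) stop("window contains fewer than 2 samples", call. = FALSE)
  out <- list()
  for (ch in stream_channels) {
    x <- rect[[ch]][idx]
    out[[paste0(ch, "_avg")]] <- mean(x)
    out[[paste0(ch, "_sd")]] <- stats::sd(x)
    out[[paste0(ch, "_max")]] <- max(x)
    out[[paste0(ch, "_min")]] <- min(x)
  }
  as.data.frame(out)
}

#' All measures for one trial window
#'
#' Computes the three outcome measures — duration, average total angular
#' velocity, total SD of acceleration — plus the 24 per-channel summary
#' statistics for a single window.
#'
#' @param stream Raw `sensor_stream` for the session.
#' @param window A window with `start_s`, `stop_s`.
#' @param rect Optional pre-computed [rectify()]ed stream (recomputed when
#'   `NULL`).
#' @param accel_sd Method for the acceleration SD, `"signed"` (default) or
#'   `"rectified"`; see [compute_total_sd_acceleration()].
#' @return A one-row data frame: `duration_s`, `avg_total_ang_vel_dps`,
#'   `total_sd_accel_ms2`, then the per-channel summaries.
#' @export
trial_measures <- function(stream, window, rect = NULL,
                           accel_sd = c("signed", "rectified")) {
  accel_sd <- match.arg(accel_sd)
  if (is.null(rect)) rect <- rectify(stream)
  cbind(
    data.frame(
      duration_s = compute_duration(window),
      avg_total_ang_vel_dps = compute_avg_total_angular_velocity(rect, window),
      total_sd_accel_ms2 = compute_total_sd_acceleration(stream, window,
                                                         accel_sd)
    ),
    compute_channel_summary(rect, window)
  )
}

#' Measure table for a labeled session
#'
#' Computes [trial_measures()] for every unflagged labeled window of a
#' session and returns the long-format rows the statistical layer consumes.
#' Flagged windows are skipped (excluded trials); callers accumulate the
#' exclusion counts across sessions.
#'
#' @param stream Raw `sensor_stream` for the session.
#' @param labeled Labeled windows from [assign_conditions()].
#' @param accel_sd Passed to [trial_measures()].
#' @return A data frame with `participant`, `task`, `condition`,
#'   `trial_index`, the three measures, and the 24 per-channel summary
#'   columns. Zero rows if every window is flagged.
#' @export
compute_measure_table <- function(stream, labeled,
                                  accel_sd = c("signed", "rectified")) {
  accel_sd <- match.arg(accel_sd)
  rect <- rectify(stream)
  rows <- list()
  for (i in seq_len(nrow(labeled))) {
    if (isTRUE(labeled$flagged[i])) next
    m <- trial_measures(stream, labeled[i, ], rect = rect, accel_sd = accel_sd)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(participant = labeled$participant[i],
                 task = labeled$task[i], condition = labeled$condition[i],
                 trial_index = i),
      m
    )
  }
  if (!length(rows)) {
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
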