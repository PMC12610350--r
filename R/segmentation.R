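#' Segmentation configuration
#'
#' Parameters of the automated start/stop detector, which replaces visual
#' identification of rest-to-activity transitions with baseline-relative
#' thresholds on the smoothed total angular velocity.
#'
#' The baseline is estimated from the quietest part of the stream itself:
#' the stream is cut into 1-s chunks, chunks are ranked by their median raw
#' total angular velocity, and the lowest decile is pooled; the enter
#' threshold is `median(pool) + k_mad * mad(pool)`. The exit threshold
#' applies the hysteresis factor to the margin above baseline,
#' `median(pool) + hysteresis * k_mad * mad(pool)`, so that it stays above
#' the rest-noise floor while remaining strictly below the enter threshold.
#' Both thresholds scale with the data, making detection invariant to
#' uniform amplitude scaling.
#'
#' @param smooth_s Moving-average smoothing window, seconds. Default 0.5.
#' @param k_mad Threshold rule multiplier: enter at baseline + `k_mad` MADs.
#'   Default 5.
#' @param hysteresis Fraction of the enter margin at which a window closes,
#'   in (0, 1]. Default 0.5.
#' @param min_activity_s Minimum time above the enter threshold for a window
#'   to count as a trial, seconds. Default 2.
#' @param min_rest_s Minimum continuous time below the exit threshold that
#'   closes a window (shorter pauses are absorbed into the trial), seconds.
#'   Default 5.
#' @param contrast_floor Minimum ratio of in-window to flanking-rest median
#'   smoothed total angular velocity below which a window is flagged as
#'   ambiguous. Default 3.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(smooth_s = 0.5, k_mad = 5, hysteresis = 0.5,
                                min_activity_s = 2, min_rest_s = 5,
                                contrast_floor = 3) {
  stopifnot(smooth_s > 0, k_mad > 0, min_activity_s > 0, min_rest_s > 0,
            contrast_floor > 0)
  if (hysteresis <= 0 || hysteresis > 1) {
    stop("hysteresis must be in (0, 1]", call. = FALSE)
  }
  structure(list(smooth_s = smooth_s, k_mad = k_mad, hysteresis = hysteresis,
                 min_activity_s = min_activity_s, min_rest_s = min_rest_s,
                 contrast_floor = contrast_floor),
            class = "segmentation_config")
}

## centred moving average with edges padded by the nearest interior value
smooth_total_velocity <- function(v, w) {
  if (w <= 1L) return(v)
  sm <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  first <- which(!is.na(sm))[1L]
  last <- max(which(!is.na(sm)))
  sm[seq_len(first - 1L)] <- sm[first]
  if (last < length(sm)) sm[(last + 1L):length(sm)] <- sm[last]
  sm
}

segmentation_thresholds <- function(rect, config) {
  t <- rect$t
  v <- rect$v_total
  chunk <- floor(t - t[1L])  # 1-s chunks
  med_by_chunk <- tapply(v, chunk, stats::median)
  n_low <- max(1L, ceiling(length(med_by_chunk) / 10))
  low_chunks <- names(sort(med_by_chunk))[seq_len(n_low)]
  pool <- v[as.character(chunk) %in% low_chunks]
  base <- stats::median(pool)
  spread <- stats::mad(pool)
  list(baseline = base, spread = spread,
       enter = base + config$k_mad * spread,
       exit = base + config$hysteresis * config$k_mad * spread)
}

#' Detect trial windows in a rectified stream
#'
#' Finds rest-to-activity transitions on the smoothed total angular velocity
#' using the baseline-relative enter/exit thresholds of
#' [segmentation_config()]. A window opens when the smoothed signal first
#' exceeds the enter threshold, absorbs dips shorter than `min_rest_s`, and
#' closes at the start of the first below-exit run that persists for
#' `min_rest_s` (or the end of the stream). Windows with less than
#' `min_activity_s` above the enter threshold are discarded.
#'
#' Boundaries are then refined: the enter-threshold crossing is re-located
#' on a lightly smoothed (0.1 s) trace, which removes the half-window
#' widening of the coarse moving average, and each boundary is walked
#' outward (bounded by one coarse smoothing window) to where the trace
#' returns to the rest level (baseline + 1 MAD) — the point a visual
#' analyst would call the transition between rest and activity. Boundaries
#' are snapped to sample timestamps; windows are half-open `[start, stop)`.
#'
#' @param rect A [rectify()]ed stream (must pass [validate_stream()]).
#' @param config A [segmentation_config()].
#' @return A data frame of class `trial_windows` with columns `start_s`,
#'   `stop_s`, `contrast`, `flagged`, `reason`, and attributes `thresholds`
#'   and `config`.
#' @export
detect_trials <- function(rect, config = segmentation_config()) {
  if (!inherits(rect, "rectified_stream")) {
    stop("`rect` must be a rectified stream (see rectify())", call. = FALSE)
  }
  t <- rect$t
  rate <- 1 / stats::median(diff(t))
  w <- round(config$smooth_s * rate)
  if (w %% 2 == 0) w <- w + 1L
  if (nrow(rect) <= w) {
    stop("stream shorter than the smoothing window", call. = FALSE)
  }
  sm <- smooth_total_velocity(rect$v_total, w)
  thr <- segmentation_thresholds(rect, config)

  n <- length(sm)
  dt <- c(diff(t), 1 / rate)
  windows <- list()
  state <- "idle"
  start_i <- NA_integer_
  below_start <- NA_integer_
  for (i in seq_len(n)) {
    if (state == "idle") {
      if (sm[i] > thr$enter) {
        state <- "active"
        start_i <- i
        below_start <- NA_integer_
      }
    } else {
      if (sm[i] <= thr$exit) {
        if (is.na(below_start)) below_start <- i
        if (t[i] - t[below_start] >= config$min_rest_s) {
          windows[[length(windows) + 1L]] <- c(start_i, below_start)
          state <- "idle"
          below_start <- NA_integer_
        }
      } else {
        below_start <- NA_integer_  # rose back above exit: rest run broken
      }
    }
  }
  if (state == "active") {
    stop_i <- if (!is.na(below_start)) below_start else n + 1L
    windows[[length(windows) + 1L]] <- c(start_i, stop_i)
  }

  ## keep windows with enough above-enter activity; snap boundaries to the
  ## first/last above-enter samples (the activity transitions themselves,
  ## not the end of the closing rest run)
  keep <- list()
  for (win in windows) {
    idx <- win[1L]:min(win[2L] - 1L, n)
    above <- idx[sm[idx] > thr$enter]
    above_time <- sum(dt[above])
    if (above_time >= config$min_activity_s) {
      keep[[length(keep) + 1L]] <- c(min(above), max(above))
    }
  }

  ## refine boundaries on a lightly smoothed trace: the 0.5-s average widens
  ## each edge by up to half its window, so re-locate the enter-threshold
  ## crossing within +/- one coarse window using a 0.1-s average
  wf <- max(1L, round(0.1 * rate))
  if (wf %% 2 == 0) wf <- wf + 1L
  smf <- smooth_total_velocity(rect$v_total, wf)
  low <- thr$baseline + thr$spread  # rest level: where activity truly ends
  keep <- lapply(keep, function(win) {
    a <- win[1L]; b <- win[2L]
    lo <- max(1L, a - w)
    hi <- min(n, b + w)
    fine_a <- lo + which(smf[lo:min(b, a + w)] > thr$enter) - 1L
    fine_b <- max(a, b - w) + which(smf[max(a, b - w):hi] > thr$enter) - 1L
    a <- if (length(fine_a)) min(fine_a) else a
    b <- if (length(fine_b)) max(fine_b) else b
    ## a shallow onset crosses the enter threshold well after leaving rest:
    ## walk outward (bounded by one coarse window) to the rest level, then
    ## pull back in by half the fine window (its own smearing)
    while (a > lo && smf[a - 1L] > low) a <- a - 1L
    while (b < hi && smf[b + 1L] > low) b <- b + 1L
    half <- wf %/% 2L
    if (b - a > 2L * half) {
      a <- a + half
      b <- b - half
    }
    c(a, b)
  })

  start_s <- vapply(keep, function(w) t[w[1L]], numeric(1))
  stop_s <- vapply(keep, function(w) {
    if (w[2L] < n) t[w[2L] + 1L] else t[n] + 1 / rate
  }, numeric(1))
  nw <- length(start_s)
  out <- data.frame(start_s = start_s, stop_s = stop_s,
                    contrast = rep(NA_real_, nw),
                    flagged = rep(FALSE, nw),
                    reason = rep(NA_character_, nw))
  structure(out, thresholds = thr, config = config, smoothed = sm,
            class = c("trial_windows", "data.frame"))
}

#' Flag ambiguous trial windows
#'
#' Mirrors the exclusion of trials whose start and stop could not be clearly
#' identified: a window is flagged when the ratio of its median smoothed
#' total angular velocity to that of its flanking rests falls below the
#' contrast floor, and every window is flagged when the detected window
#' count disagrees with the expected trial count for the session. Flagged
#' windows are excluded from measures and counted in the exclusion summary.
#'
#' @param windows A `trial_windows` data frame from [detect_trials()].
#' @param rect The rectified stream the windows were detected in.
#' @param config A [segmentation_config()].
#' @param expected_n Expected number of trials (e.g. `nrow(manifest)`), or
#'   `NULL` to skip the count check.
#' @return `windows` with `contrast`, `flagged` and `reason` filled in.
#' @export
flag_ambiguous <- function(windows, rect, config = segmentation_config(),
                           expected_n = NULL) {
  t <- rect$t
  sm <- attr(windows, "smoothed")
  if (is.null(sm)) {
    rate <- 1 / stats::median(diff(t))
    w <- round(config$smooth_s * rate); if (w %% 2 == 0) w <- w + 1L
    sm <- smooth_total_velocity(rect$v_total, w)
  }
  guard <- 0.5  # s excluded from flanks next to window boundaries
  nwin <- nrow(windows)
  for (i in seq_len(nwin)) {
    in_win <- t >= windows$start_s[i] & t < windows$stop_s[i]
    left_edge <- if (i > 1L) windows$stop_s[i - 1L] else t[1L]
    right_edge <- if (i < nwin) windows$start_s[i + 1L] else t[length(t)]
    in_flank <- (t >= left_edge + guard & t < windows$start_s[i] - guard) |
      (t >= windows$stop_s[i] + guard & t < right_edge - guard)
    rest_med <- if (any(in_flank)) stats::median(sm[in_flank]) else
      attr(windows, "thresholds")$baseline
    windows$contrast[i] <- stats::median(sm[in_win]) /
      max(rest_med, .Machine$double.eps)
    if (windows$contrast[i] < config$contrast_floor) {
      windows$flagged[i] <- TRUE
      windows$reason[i] <- "low_contrast"
    }
  }
  if (!is.null(expected_n) && nwin != expected_n) {
    windows$flagged <- rep(TRUE, nwin)
    windows$reason <- ifelse(is.na(windows$reason), "count_mismatch",
                             paste(windows$reason, "count_mismatch", sep = ";"))
  }
  windows
}

#' Assign task and condition labels to detected windows
#'
#' Labels detected windows with the session manifest entries, matched in
#' chronological order. The total detected window count must equal the
#' manifest entry count; a mismatch is a session-level error directing the
#' session to manual review (never a silent reassignment). Flagged windows
#' keep their labels but are excluded from the measure table downstream.
#'
#' @param windows A `trial_windows` data frame (windows in time order).
#' @param manifest Data frame with columns `participant`, `task`,
#'   `condition`, one row per performed trial in order.
#' @return `windows` with `participant`, `task` and `condition` columns
#'   prepended.
#' @export
assign_conditions <- function(windows, manifest) {
  stopifnot(all(c("participant", "task", "condition") %in% names(manifest)))
  if (nrow(windows) != nrow(manifest)) {
    stop(sprintf(
      paste0("session %s: detected %d window(s) but manifest lists %d ",
             "trial(s); manual review required"),
      manifest$participant[1L], nrow(windows), nrow(manifest)), call. = FALSE)
  }
  ord <- order(windows$start_s)
  out <- cbind(manifest[, c("participant", "task", "condition")],
               as.data.frame(windows)[ord, , drop = FALSE])
  rownames(out) <- NULL
  attributes_keep <- attributes(windows)[c("thresholds", "config")]
  structure(out, thresholds = attributes_keep$thresholds,
            config = attributes_keep$config,
            class = c("trial_windows", "data.frame"))
}

#' Format an exclusion summary
#'
#' Renders the cohort-level exclusion statistic in the conventional
#' "excluded/total (percent)" form, e.g. `"31/500 (6.2%)"`.
#'
#' @param n_excluded Number of excluded trials.
#' @param n_total Total number of trials analyzed.
#' @return A list with `n_excluded`, `n_total`, `percent` (rounded to one
#'   decimal) and `label`.
#' @export
exclusion_summary <- function(n_excluded, n_total) {
  pct <- round(100 * n_excluded / n_total, 1)
  list(n_excluded = n_excluded, n_total = n_total, percent = pct,
       label = sprintf("%d/%d (%.1f%%)", n_excluded, n_total, pct))
}
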