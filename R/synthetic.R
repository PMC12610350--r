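#' Cohort simulation configuration
#'
#' Parameters of the synthetic study: cohort size, the variance components
#' that control true reliability, sensor noise, the fast-pace effect, and the
#' session timing. Participant-level speed and tempo effects and
#' trial-to-trial fluctuations are log-normal multipliers (so simulated
#' measures stay positive), with standard deviations `between_subject_sd`
#' and `within_subject_sd` on the log scale. The implied true intraclass
#' correlation of any log-measure across repeated trials is
#' `between_subject_sd^2 / (between_subject_sd^2 + within_subject_sd^2)`.
#'
#' @param n_participants Number of participants (>= 2). Default 25.
#' @param between_subject_sd SD of participant log-normal effects. Default
#'   0.25.
#' @param within_subject_sd SD of trial-to-trial log-normal fluctuations.
#'   Default 0.10. The defaults imply a true ICC of about 0.86, i.e. good
#'   reliability.
#' @param gyro_noise_sd White sensor noise on each angular-velocity channel,
#'   degrees/s. Default 0.5, an upper-end figure for consumer MEMS gyroscopes
#'   at a 62 Hz bandwidth.
#' @param accel_noise_sd White sensor noise on each acceleration channel,
#'   m/s^2. Default 0.05.
#' @param pace_multiplier_fast Fast-pace factor (> 1): multiplies burst
#'   amplitudes and divides the repetition period (and gap). Default 1.4.
#' @param sample_rate Sampling rate, Hz. Default 62.
#' @param rest_duration Rest between consecutive trials, seconds. Default 30.
#' @param timestamp_jitter Add uniform jitter (+/- half a millisecond) to the
#'   sample grid. Default `FALSE`.
#' @param seed Root seed for cohort generation.
#' @return A list of class `cohort_config`. Includes `true_icc`, the implied
#'   variance-ratio ICC.
#' @export
cohort_config <- function(n_participants = 25, between_subject_sd = 0.25,
                          within_subject_sd = 0.10, gyro_noise_sd = 0.5,
                          accel_noise_sd = 0.05, pace_multiplier_fast = 1.4,
                          sample_rate = 62, rest_duration = 30,
                          timestamp_jitter = FALSE, seed = 1L) {
  if (n_participants < 2) stop("n_participants must be >= 2", call. = FALSE)
  if (between_subject_sd < 0 || within_subject_sd < 0 ||
      gyro_noise_sd < 0 || accel_noise_sd < 0) {
    stop("all standard deviations must be >= 0", call. = FALSE)
  }
  if (pace_multiplier_fast <= 1) {
    stop("pace_multiplier_fast must be > 1", call. = FALSE)
  }
  s2b <- between_subject_sd^2
  s2w <- within_subject_sd^2
  structure(list(
    n_participants = as.integer(n_participants),
    between_subject_sd = between_subject_sd,
    within_subject_sd = within_subject_sd,
    gyro_noise_sd = gyro_noise_sd, accel_noise_sd = accel_noise_sd,
    pace_multiplier_fast = pace_multiplier_fast,
    sample_rate = sample_rate, rest_duration = rest_duration,
    timestamp_jitter = isTRUE(timestamp_jitter),
    seed = as.integer(seed),
    true_icc = if (s2b + s2w > 0) s2b / (s2b + s2w) else NA_real_
  ), class = "cohort_config")
}

## effective (pace- and effect-adjusted) burst parameters for one trial
effective_params <- function(profile, pace, effects, config) {
  m <- if (pace == "fast") config$pace_multiplier_fast else 1
  period <- profile$period * effects$tempo / m
  gap <- profile$gap * effects$tempo / m
  if (period <= 0) stop("non-positive repetition period after pace scaling",
                        call. = FALSE)
  list(period = period, gap = gap,
       gyro_amp = profile$gyro_amp * effects$speed * m,
       accel_amp = profile$accel_amp * effects$speed * m)
}

#' Noise-free expected trial measures
#'
#' Closed-form expectations of the three outcome measures under the
#' half-sine burst model, used as the analytic oracle for the empirical
#' measures. With per-axis peak angular velocity `A`, peak acceleration `B`,
#' effective period `P`, gap `g` and `r` repetitions:
#' duration `= rP + (r-1)g`; the active fraction is `q = rP / duration`;
#' mean total angular velocity `= q * sum(2A/pi)` (mean of `|A sin|` over a
#' burst is `2A/pi`); and the per-axis population SD of acceleration is
#' `B * sqrt(q/2 - 4q^2/pi^2)`, summed over axes. Sensor noise is excluded.
#'
#' @param profile A [task_profile()].
#' @param reps Repetition count.
#' @param pace `"comfortable"` or `"fast"`.
#' @param effects List with log-normal multipliers `speed` and `tempo`
#'   (default both 1).
#' @param config A [cohort_config()] (supplies the fast-pace multiplier).
#' @return A one-row data frame with `duration_s`,
#'   `avg_total_ang_vel_dps`, `total_sd_accel_ms2`.
#' @export
expected_trial_measures <- function(profile, reps, pace = "comfortable",
                                    effects = list(speed = 1, tempo = 1),
                                    config = cohort_config()) {
  p <- effective_params(profile, pace, effects, config)
  duration <- reps * p$period + (reps - 1) * p$gap
  q <- reps * p$period / duration
  data.frame(
    duration_s = duration,
    avg_total_ang_vel_dps = q * sum(2 * p$gyro_amp / pi),
    total_sd_accel_ms2 = sum(p$accel_amp * sqrt(q / 2 - 4 * q^2 / pi^2))
  )
}

## render one segment of half-sine burst signal on a local ms-grid
## returns an n x 6 matrix (gyro xyz, accel xyz) without noise
render_burst_segment <- function(n, t, p, reps, gravity) {
  cycle <- p$period + p$gap
  j <- pmin(floor(t / cycle), reps - 1)
  tau <- t - j * cycle
  active <- tau < p$period
  phase <- ifelse(active, sin(pi * pmin(tau, p$period) / p$period), 0)
  sign_rep <- ifelse(j %% 2 == 0, 1, -1)   # alternate burst direction per rep
  gyro <- outer(phase * sign_rep, p$gyro_amp)
  accel <- outer(phase, p$accel_amp) + rep(gravity, each = n)
  cbind(gyro, accel)
}

#' Generate one synthetic trial
#'
#' Renders `reps` half-sine repetitions of a task at the given pace as a raw
#' 6-channel segment (local time base starting at 0), plus its ground truth.
#' Angular-velocity bursts alternate direction between consecutive
#' repetitions (the signed channels swing both ways, as a to-and-fro task
#' does); acceleration bursts push against the constant gravity offset.
#' White sensor noise is added to every channel. Uses the current RNG state.
#'
#' @inheritParams expected_trial_measures
#' @param config A [cohort_config()] (sampling rate, noise, pace factor).
#' @return A list with `stream` (a [sensor_stream()] segment) and `truth`
#'   (one-row data frame: exact duration and the noise-free expected
#'   measures).
#' @export
generate_trial <- function(profile, reps, pace = "comfortable",
                           effects = list(speed = 1, tempo = 1),
                           config = cohort_config()) {
  stopifnot(inherits(profile, "task_profile"))
  p <- effective_params(profile, pace, effects, config)
  duration <- reps * p$period + (reps - 1) * p$gap
  n <- max(2L, round(duration * config$sample_rate))
  t <- ms_grid(n, config)
  sig <- render_burst_segment(n, t, p, reps, profile$gravity)
  sig <- sig + cbind(
    matrix(stats::rnorm(3 * n, 0, config$gyro_noise_sd), n, 3),
    matrix(stats::rnorm(3 * n, 0, config$accel_noise_sd), n, 3)
  )
  truth <- expected_trial_measures(profile, reps, pace, effects, config)
  list(
    stream = sensor_stream(t, sig[, 1:3], sig[, 4:6],
                           rate = config$sample_rate,
                           provenance = sprintf("synthetic:%s/%d@%s",
                                                profile$name, reps, pace)),
    truth = truth
  )
}

## millisecond-integer time grid for n samples at config$sample_rate
ms_grid <- function(n, config) {
  ms <- round((seq_len(n) - 1) * 1000 / config$sample_rate)
  if (config$timestamp_jitter) {
    # +/- 2 ms on a ~16 ms grid: cannot reorder samples, stays integer ms
    ms <- ms + sample(-2:2, n, replace = TRUE)
  }
  ms / 1000
}

rest_segment <- function(n, gravity, config) {
  cbind(
    matrix(stats::rnorm(3 * n, 0, config$gyro_noise_sd), n, 3),
    matrix(stats::rnorm(3 * n, 0, config$accel_noise_sd), n, 3) +
      rep(gravity, each = n)
  )
}

#' Generate one synthetic session
#'
#' One continuous stream for one participant: a lead-in rest, then every
#' task under every condition in the given randomized orders, with
#' `rest_duration` seconds of noise-only signal between consecutive trials
#' and a trailing rest. Trial-to-trial log-normal fluctuations (SD
#' `within_subject_sd`) are drawn per trial and combined with the
#' participant-level effects.
#'
#' @param participant Participant identifier.
#' @param config A [cohort_config()].
#' @param profiles Named list of [task_profile()]s.
#' @param task_order Permutation of `names(profiles)`; drawn at random when
#'   `NULL`.
#' @param condition_orders Named list (one permutation of
#'   [session_conditions()] per task); drawn at random when `NULL`.
#' @param participant_effects List with `speed` and `tempo` multipliers for
#'   this participant (default both 1).
#' @return A list with `stream` (full-session [sensor_stream()]), `truth`
#'   (data frame: one row per trial with window start/stop, exact duration,
#'   noise-free expected measures and the realized multipliers) and
#'   `manifest` (participant/task/condition in performance order).
#' @export
generate_session <- function(participant, config = cohort_config(),
                             profiles = default_task_profiles(),
                             task_order = NULL, condition_orders = NULL,
                             participant_effects = list(speed = 1, tempo = 1)) {
  tasks <- names(profiles)
  if (is.null(task_order)) task_order <- sample(tasks)
  stopifnot(setequal(task_order, tasks))
  if (is.null(condition_orders)) {
    condition_orders <- stats::setNames(
      lapply(tasks, function(i) sample(session_conditions())), tasks)
  }
  rate <- config$sample_rate
  n_rest <- max(2L, round(config$rest_duration * rate))
  gravity <- profiles[[1L]]$gravity

  ## draw the trial plan (including all trial-level multipliers) up front,
  ## before any signal rendering, so the same RNG sub-stream yields the
  ## same plan whether or not streams are rendered
  plan <- session_plan(config, task_order, condition_orders,
                       participant_effects)

  segs <- list(rest_segment(n_rest, gravity, config))
  truth <- list()
  manifest <- list()
  n_before <- n_rest  # samples rendered so far

  for (row in plan) {
      task <- row$task
      cond <- row$condition
      spec <- condition_spec(cond)
      eff <- row$effects
      trial <- generate_trial(profiles[[task]], spec$reps, spec$pace, eff, config)
      n_trial <- nrow(trial$stream)
      segs[[length(segs) + 1L]] <-
        as.matrix(trial$stream[, stream_channels])
      truth[[length(truth) + 1L]] <- cbind(
        data.frame(participant = participant, task = task, condition = cond,
                   start_sample = n_before + 1L, n_samples = n_trial,
                   speed_mult = eff$speed, tempo_mult = eff$tempo),
        trial$truth
      )
      manifest[[length(manifest) + 1L]] <-
        data.frame(participant = participant, task = task, condition = cond)
      n_before <- n_before + n_trial
      segs[[length(segs) + 1L]] <- rest_segment(n_rest, gravity, config)
      n_before <- n_before + n_rest
  }

  sig <- do.call(rbind, segs)
  n <- nrow(sig)
  t <- ms_grid(n, config)
  truth <- do.call(rbind, truth)
  truth$start_s <- t[truth$start_sample]
  stop_idx <- truth$start_sample + truth$n_samples  # first sample after trial
  truth$stop_s <- t[pmin(stop_idx, n)]
  # half-open window [start, stop): recorded duration equals stop - start
  truth$duration_s <- truth$stop_s - truth$start_s
  truth <- truth[, c("participant", "task", "condition", "start_s", "stop_s",
                     "duration_s", "avg_total_ang_vel_dps",
                     "total_sd_accel_ms2", "speed_mult", "tempo_mult")]
  list(
    stream = sensor_stream(t, sig[, 1:3], sig[, 4:6], rate = rate,
                           provenance = sprintf("synthetic:session/%s",
                                                participant)),
    truth = truth,
    manifest = do.call(rbind, manifest)
  )
}

participant_seed <- function(seed, p) {
  as.integer((as.numeric(seed) * 10007 + p * 131) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Draws participant-level log-normal speed and tempo effects (one pair per
#' participant), randomizes task and condition orders per participant, and
#' generates each session from a per-participant seed derived by counter
#' from the root seed, so cohorts are reproducible regardless of generation
#' order. With `render_streams = FALSE` no raw 62-Hz signal is rendered;
#' the returned ground-truth measure table (analytic expectations times the
#' realized participant and trial multipliers) is the generative truth that
#' the raw pipeline estimates, and is what large Monte-Carlo studies of the
#' statistical layer consume.
#'
#' @param config A [cohort_config()].
#' @param profiles Named list of [task_profile()]s.
#' @param render_streams Render raw sensor streams per session? Default
#'   `TRUE`.
#' @return A list of class `synthetic_cohort`: `sessions` (named list with
#'   `stream`, `truth`, `manifest` per participant; streams `NULL` when not
#'   rendered), `effects` (participant multipliers), `truth_table` (all
#'   sessions' ground-truth rows), `manifest` (all sessions), `true_icc`,
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            profiles = default_task_profiles(),
                            render_streams = TRUE) {
  set.seed(config$seed)
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  effects <- data.frame(
    participant = ids,
    speed = exp(stats::rnorm(config$n_participants, 0,
                             config$between_subject_sd)),
    tempo = exp(stats::rnorm(config$n_participants, 0,
                             config$between_subject_sd))
  )
  tasks <- names(profiles)
  orders <- lapply(seq_along(ids), function(i) {
    list(task_order = sample(tasks),
         condition_orders = stats::setNames(
           lapply(tasks, function(x) sample(session_conditions())), tasks))
  })

  sessions <- vector("list", length(ids))
  names(sessions) <- ids
  for (i in seq_along(ids)) {
    set.seed(participant_seed(config$seed, i))
    pe <- list(speed = effects$speed[i], tempo = effects$tempo[i])
    if (render_streams) {
      sessions[[i]] <- generate_session(
        ids[i], config, profiles,
        task_order = orders[[i]]$task_order,
        condition_orders = orders[[i]]$condition_orders,
        participant_effects = pe)
    } else {
      sessions[[i]] <- truth_only_session(
        ids[i], config, profiles,
        task_order = orders[[i]]$task_order,
        condition_orders = orders[[i]]$condition_orders,
        participant_effects = pe)
    }
  }
  truth_table <- do.call(rbind, lapply(sessions, `[[`, "truth"))
  rownames(truth_table) <- NULL
  manifest <- do.call(rbind, lapply(sessions, `[[`, "manifest"))
  rownames(manifest) <- NULL
  structure(list(sessions = sessions, effects = effects,
                 truth_table = truth_table, manifest = manifest,
                 true_icc = config$true_icc, config = config),
            class = "synthetic_cohort")
}

## the per-session trial plan: performance order plus the trial-level
## log-normal multipliers, drawn in one deterministic sweep
session_plan <- function(config, task_order, condition_orders,
                         participant_effects) {
  plan <- list()
  for (task in task_order) {
    stopifnot(setequal(condition_orders[[task]], session_conditions()))
    for (cond in condition_orders[[task]]) {
      plan[[length(plan) + 1L]] <- list(
        task = task, condition = cond,
        effects = list(
          speed = participant_effects$speed *
            exp(stats::rnorm(1, 0, config$within_subject_sd)),
          tempo = participant_effects$tempo *
            exp(stats::rnorm(1, 0, config$within_subject_sd))
        )
      )
    }
  }
  plan
}

## measure-level session: identical trial plan (same RNG draws) as the
## rendered path, but no 62-Hz signal
truth_only_session <- function(participant, config, profiles, task_order,
                               condition_orders, participant_effects) {
  plan <- session_plan(config, task_order, condition_orders,
                       participant_effects)
  rows <- list()
  manifest <- list()
  for (row in plan) {
    spec <- condition_spec(row$condition)
    m <- expected_trial_measures(profiles[[row$task]], spec$reps, spec$pace,
                                 row$effects, config)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(participant = participant, task = row$task,
                 condition = row$condition,
                 start_s = NA_real_, stop_s = NA_real_),
      m[, c("duration_s", "avg_total_ang_vel_dps", "total_sd_accel_ms2")],
      data.frame(speed_mult = row$effects$speed,
                 tempo_mult = row$effects$tempo)
    )
    manifest[[length(manifest) + 1L]] <-
      data.frame(participant = participant, task = row$task,
                 condition = row$condition)
  }
  list(stream = NULL, truth = do.call(rbind, rows),
       manifest = do.call(rbind, manifest))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d participants, %d trials, true ICC %.3f, seed %d%s\n",
    nrow(x$effects), nrow(x$truth_table), x$true_icc, x$config$seed,
    if (is.null(x$sessions[[1L]]$stream)) " (measures only)" else ""))
  invisible(x)
}

#' Ground-truth measure table of a cohort
#'
#' Reshapes a cohort's ground truth into the long measure-table layout the
#' statistical layer consumes (participant, task, condition, the three
#' measures), so that reliability and validity analyses can be run directly
#' on the generative truth.
#'
#' @param cohort A `synthetic_cohort`.
#' @return A data frame with columns `participant`, `task`, `condition`,
#'   `duration_s`, `avg_total_ang_vel_dps`, `total_sd_accel_ms2`.
#' @export
truth_measure_table <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cohort$truth_table[, c("participant", "task", "condition", "duration_s",
                         "avg_total_ang_vel_dps", "total_sd_accel_ms2")]
}

#' Write a cohort's ground truth manifest as JSON
#'
#' Serializes windows, condition labels, true measures, the seed and a
#' config echo, alongside the raw CSV streams written by
#' [write_raw_csv()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(cohort, path) {
  jsonlite::write_json(list(
    seed = cohort$config$seed,
    true_icc = cohort$true_icc,
    config = unclass(cohort$config),
    effects = cohort$effects,
    truth = cohort$truth_table
  ), path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
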