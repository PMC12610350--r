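#' Define a task motion profile
#'
#' A task profile parameterizes how one functional task (e.g. lifting a cup
#' to the mouth) renders on a wrist-worn inertial sensor. Each repetition is
#' a smooth half-sine burst per axis: angular velocity reaches `gyro_amp`
#' degrees/s at mid-repetition and is zero at the endpoints, and a
#' motion-correlated half-sine acceleration burst of `accel_amp` m/s^2 rides
#' on a constant gravity offset. Repetitions are `period` seconds long and
#' separated by `gap` seconds of rest-level signal.
#'
#' @param name Task label.
#' @param gyro_amp Length-3 non-negative vector: peak angular velocity per
#'   axis, degrees/s.
#' @param period Seconds per repetition (> 0) at a comfortable pace.
#' @param gap Seconds of inactivity between consecutive repetitions (>= 0).
#'   Default 0: repetitions are performed back to back, so the expected mean
#'   total angular velocity of a trial does not depend on how many
#'   repetitions it contains.
#' @param accel_amp Length-3 non-negative vector: peak acceleration per axis
#'   above gravity, m/s^2.
#' @param gravity Length-3 vector: constant gravity offset per axis, m/s^2.
#' @return A list of class `task_profile`.
#' @export
task_profile <- function(name, gyro_amp, period, gap = 0,
                         accel_amp = c(1.7, 1.7, 1.7),
                         gravity = c(0, 0, 9.81)) {
  stopifnot(length(gyro_amp) == 3L, length(accel_amp) == 3L,
            length(gravity) == 3L)
  if (any(gyro_amp < 0) || any(accel_amp < 0)) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  if (period <= 0) stop("burst period must be > 0", call. = FALSE)
  if (gap < 0) stop("inter-repetition gap must be >= 0", call. = FALSE)
  structure(list(name = name, gyro_amp = as.numeric(gyro_amp),
                 period = period, gap = gap,
                 accel_amp = as.numeric(accel_amp),
                 gravity = as.numeric(gravity)),
            class = "task_profile")
}

#' Default task profiles
#'
#' Four profiles for the tasks of the session design: picking up a cup,
#' handwriting a name, putting a letter in a mailbox, and tying a shoe.
#' Amplitudes and periods are calibrated loosely to typical healthy-adult
#' magnitudes for these tasks (mean total angular velocity roughly 110, 148,
#' 156 and 37 degrees/s and 5-repetition cup trials near 17.6 s); they are
#' plausible renderings, not reproductions of any particular cohort.
#'
#' @return Named list of [task_profile()] objects
#'   (`cup`, `writing`, `letter`, `shoe`).
#' @export
default_task_profiles <- function() {
  list(
    cup = task_profile("cup", gyro_amp = c(95, 50, 28), period = 3.5,
                       accel_amp = c(1.7, 1.7, 1.7)),
    writing = task_profile("writing", gyro_amp = c(30, 18, 10), period = 5.3,
                           accel_amp = c(1.6, 1.6, 1.6)),
    letter = task_profile("letter", gyro_amp = c(120, 70, 42), period = 3.9,
                          accel_amp = c(1.7, 1.7, 1.7)),
    shoe = task_profile("shoe", gyro_amp = c(125, 75, 44), period = 8.8,
                        accel_amp = c(1.6, 1.6, 1.6))
  )
}

#' Session condition labels
#'
#' The five conditions every task is performed under: 5, 10 and 20
#' repetitions at a comfortable pace (`c5`, `c10`, `c20`), 10 repetitions at
#' a fast pace (`f10`), and a repeated block of 10 comfortable repetitions
#' (`c10r`) used for within-session reliability.
#'
#' @return Character vector of the five condition labels.
#' @export
session_conditions <- function() c("c5", "c10", "c20", "f10", "c10r")

condition_spec <- function(label) {
  switch(label,
    c5 = list(reps = 5L, pace = "comfortable"),
    c10 = list(reps = 10L, pace = "comfortable"),
    c20 = list(reps = 20L, pace = "comfortable"),
    f10 = list(reps = 10L, pace = "fast"),
    c10r = list(reps = 10L, pace = "comfortable"),
    stop("unknown condition label: ", label, call. = FALSE)
  )
}
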