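# Small fixtures built in code.

# A quiet config for unit tests: tiny cohort, short rests where the test
# does not exercise the rest rule itself.
quiet_config <- function(...) {
  cohort_config(n_participants = 2, ...)
}

# A stream of pure sensor noise (plus gravity) lasting `dur` seconds.
noise_stream <- function(dur = 60, config = cohort_config(n_participants = 2)) {
  n <- round(dur * config$sample_rate)
  t <- round((seq_len(n) - 1) * 1000 / config$sample_rate) / 1000
  sensor_stream(
    t,
    gyro = matrix(rnorm(3 * n, 0, config$gyro_noise_sd), n, 3),
    accel = matrix(rnorm(3 * n, 0, config$accel_noise_sd), n, 3) +
      rep(c(0, 0, 9.81), each = n),
    rate = config$sample_rate, provenance = "fixture:noise"
  )
}

# Manually assemble a session stream out of trial segments and rests so a
# test controls every trial's profile. Returns stream + true windows.
manual_session <- function(trials, rest_s = 30,
                           config = cohort_config(n_participants = 2)) {
  rate <- config$sample_rate
  n_rest <- round(rest_s * rate)
  gravity <- c(0, 0, 9.81)
  segs <- list(matrix(0, n_rest, 6))
  segs[[1]][, 4:6] <- rep(gravity, each = n_rest)
  segs[[1]] <- segs[[1]] + cbind(
    matrix(rnorm(3 * n_rest, 0, config$gyro_noise_sd), n_rest, 3),
    matrix(rnorm(3 * n_rest, 0, config$accel_noise_sd), n_rest, 3))
  starts <- numeric(0); stops <- numeric(0)
  n_before <- n_rest
  for (tr in trials) {
    seg <- generate_trial(tr$profile, tr$reps, tr$pace %||% "comfortable",
                          config = config)
    nseg <- nrow(seg$stream)
    segs[[length(segs) + 1]] <- as.matrix(
      seg$stream[, c("gyro_x", "gyro_y", "gyro_z",
                     "accel_x", "accel_y", "accel_z")])
    starts <- c(starts, n_before + 1)
    stops <- c(stops, n_before + nseg + 1)
    n_before <- n_before + nseg
    rest <- matrix(0, n_rest, 6)
    rest[, 4:6] <- rep(gravity, each = n_rest)
    rest <- rest + cbind(
      matrix(rnorm(3 * n_rest, 0, config$gyro_noise_sd), n_rest, 3),
      matrix(rnorm(3 * n_rest, 0, config$accel_noise_sd), n_rest, 3))
    segs[[length(segs) + 1]] <- rest
    n_before <- n_before + n_rest
  }
  sig <- do.call(rbind, segs)
  n <- nrow(sig)
  t <- round((seq_len(n) - 1) * 1000 / rate) / 1000
  list(
    stream = sensor_stream(t, sig[, 1:3], sig[, 4:6], rate = rate,
                           provenance = "fixture:manual_session"),
    start_s = t[starts],
    stop_s = t[pmin(stops, n)]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
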