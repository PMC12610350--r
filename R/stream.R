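#' Construct a sensor stream
#'
#' A sensor stream holds one participant-session of raw wrist inertial data:
#' timestamps in seconds from stream start plus three angular-velocity
#' channels (degrees/s, signed) and three acceleration channels (m/s^2,
#' signed).
#'
#' @param t Numeric vector of timestamps in seconds from stream start.
#' @param gyro Numeric matrix or data frame with 3 columns (x, y, z angular
#'   velocity in degrees/s), one row per sample.
#' @param accel Numeric matrix or data frame with 3 columns (x, y, z
#'   acceleration in m/s^2), one row per sample.
#' @param rate Nominal sampling rate in Hz (default 62).
#' @param provenance Character note on where the stream came from (a file
#'   path or a generator description).
#'
#' @return A data frame of class `sensor_stream` with columns `t`, `gyro_x`,
#'   `gyro_y`, `gyro_z`, `accel_x`, `accel_y`, `accel_z` and attributes
#'   `rate` and `provenance`.
#' @export
sensor_stream <- function(t, gyro, accel, rate = 62, provenance = "unspecified") {
  gyro <- as.matrix(gyro)
  accel <- as.matrix(accel)
  stopifnot(length(t) == nrow(gyro), length(t) == nrow(accel),
            ncol(gyro) == 3L, ncol(accel) == 3L)
  if (length(t) < 2L) {
    stop("a sensor stream needs at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(t))) {
    stop("timestamps must be finite", call. = FALSE)
  }
  out <- data.frame(
    t = as.numeric(t),
    gyro_x = as.numeric(gyro[, 1L]), gyro_y = as.numeric(gyro[, 2L]),
    gyro_z = as.numeric(gyro[, 3L]),
    accel_x = as.numeric(accel[, 1L]), accel_y = as.numeric(accel[, 2L]),
    accel_z = as.numeric(accel[, 3L])
  )
  structure(out, rate = rate, provenance = provenance,
            class = c("sensor_stream", "data.frame"))
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %d samples, %.1f s, nominal %g Hz (%s)\n",
              nrow(x), diff(range(x$t)), attr(x, "rate"),
              attr(x, "provenance")))
  invisible(x)
}

stream_channels <- c("gyro_x", "gyro_y", "gyro_z",
                     "accel_x", "accel_y", "accel_z")

is_sensor_stream <- function(x) {
  is.data.frame(x) && all(c("t", stream_channels) %in% names(x))
}

#' Rectify a sensor stream
#'
#' Parses the raw signed channels into six vectors of absolute values (the
#' first processing step of the pipeline) and derives the total angular
#' velocity channel `|Vx| + |Vy| + |Vz|`, the quantity used for trial
#' segmentation and the speed measure.
#'
#' Rectification is idempotent: applying it to an already rectified stream
#' returns the same values.
#'
#' @param stream A `sensor_stream` or `rectified_stream`.
#'
#' @return A data frame of class `rectified_stream` with columns `t`, the six
#'   absolute-value channels (same names as the raw stream) and `v_total`.
#' @export
rectify <- function(stream) {
  if (!is_sensor_stream(stream)) {
    stop("`stream` must be a sensor stream (see sensor_stream())", call. = FALSE)
  }
  out <- data.frame(t = stream$t)
  for (ch in stream_channels) out[[ch]] <- abs(stream[[ch]])
  out$v_total <- out$gyro_x + out$gyro_y + out$gyro_z
  structure(out,
            rate = attr(stream, "rate") %||% 62,
            provenance = attr(stream, "provenance") %||% "unspecified",
            class = c("rectified_stream", "sensor_stream", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
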