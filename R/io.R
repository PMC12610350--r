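#' @name csv_dialect
#' @title Raw export CSV dialect
#' @description
#' Raw activity-monitor exports are plain comma-separated UTF-8 files with
#' header `t_ms,gyro_x_dps,gyro_y_dps,gyro_z_dps,accel_x_ms2,accel_y_ms2,
#' accel_z_ms2`: timestamps in integer milliseconds since stream start,
#' angular velocity in degrees/s, acceleration in m/s^2, one sample per row.
NULL

raw_csv_header <- c("t_ms", "gyro_x_dps", "gyro_y_dps", "gyro_z_dps",
                    "accel_x_ms2", "accel_y_ms2", "accel_z_ms2")

#' Read a raw sensor export
#'
#' Reads a delimited raw export (see [csv_dialect]) into a [sensor_stream()].
#' The reader is strict: a missing column is a schema error naming the
#' column, and a non-numeric cell is a parse error naming the first offending
#' row. Duplicated or non-monotonic timestamps are accepted here and reported
#' by [validate_stream()]; the pipeline refuses such streams downstream.
#'
#' @param path Path to a CSV file in the documented dialect.
#' @param rate Nominal sampling rate in Hz recorded on the stream.
#' @return A `sensor_stream`.
#' @export
read_raw_csv <- function(path, rate = 62) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(raw_csv_header, names(raw))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num <- lapply(raw[raw_csv_header], function(col) {
    suppressWarnings(as.numeric(col))
  })
  for (nm in raw_csv_header) {
    bad <- which(is.na(num[[nm]]) & !is.na(raw[[nm]]))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric value in column '%s' at row %d",
                   nm, bad[1L]), call. = FALSE)
    }
  }
  sensor_stream(
    t = num$t_ms / 1000,
    gyro = cbind(num$gyro_x_dps, num$gyro_y_dps, num$gyro_z_dps),
    accel = cbind(num$accel_x_ms2, num$accel_y_ms2, num$accel_z_ms2),
    rate = rate, provenance = path
  )
}

#' Write a sensor stream as a raw CSV export
#'
#' Inverse of [read_raw_csv()]: writes the documented dialect at full float
#' precision so that write-then-read reproduces every sample exactly.
#' Timestamps are written as integer milliseconds.
#'
#' @param stream A `sensor_stream`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(stream, path) {
  if (!is_sensor_stream(stream)) stop("`stream` must be a sensor stream", call. = FALSE)
  if (nrow(stream) == 0L) stop("refusing to write an empty stream", call. = FALSE)
  out <- data.frame(
    t_ms = round(stream$t * 1000),
    gyro_x_dps = stream$gyro_x, gyro_y_dps = stream$gyro_y,
    gyro_z_dps = stream$gyro_z,
    accel_x_ms2 = stream$accel_x, accel_y_ms2 = stream$accel_y,
    accel_z_ms2 = stream$accel_z
  )
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a sensor stream
#'
#' Pure diagnostic pass over a stream: reports the median sampling interval,
#' the fraction of inter-sample gaps longer than twice the nominal interval,
#' and the number of monotonicity violations (non-increasing timestamps,
#' which includes duplicates). The input is never modified; callers decide
#' whether to refuse a stream (the pipeline refuses any stream with
#' monotonicity violations rather than silently sorting).
#'
#' @param stream A `sensor_stream` with at least 2 samples.
#' @return A list of class `stream_validation` with elements
#'   `n_samples`, `median_interval_s`, `nominal_interval_s`,
#'   `gap_fraction`, `n_gaps`, `n_monotonicity_violations`, `ok`.
#' @export
validate_stream <- function(stream) {
  if (!is_sensor_stream(stream)) stop("`stream` must be a sensor stream", call. = FALSE)
  if (nrow(stream) < 2L) stop("validation needs at least 2 samples", call. = FALSE)
  dt <- diff(stream$t)
  nominal <- 1 / (attr(stream, "rate") %||% 62)
  gaps <- dt > 2 * nominal
  viol <- sum(dt <= 0)
  structure(list(
    n_samples = nrow(stream),
    median_interval_s = stats::median(dt),
    nominal_interval_s = nominal,
    gap_fraction = mean(gaps),
    n_gaps = sum(gaps),
    n_monotonicity_violations = viol,
    ok = viol == 0L
  ), class = "stream_validation")
}

#' @export
print.stream_validation <- function(x, ...) {
  cat(sprintf(paste0(
    "<stream_validation> %d samples | median dt %.5f s (nominal %.5f) | ",
    "%d gap(s) > 2x nominal (%.2f%%) | %d monotonicity violation(s) | %s\n"),
    x$n_samples, x$median_interval_s, x$nominal_interval_s,
    x$n_gaps, 100 * x$gap_fraction, x$n_monotonicity_violations,
    if (x$ok) "OK" else "REFUSE"))
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report A `stream_validation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a session manifest
#'
#' A manifest lists, in performance order, the (participant, task, condition)
#' of every trial in a session; the analyst's record of the randomized order.
#' Stored as a JSON array of objects.
#'
#' @param manifest Data frame with columns `participant`, `task`, `condition`.
#' @param path File path.
#' @return `read_manifest`: the manifest data frame. `write_manifest`:
#'   `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("participant", "task", "condition") %in% names(manifest)))
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.data.frame(m, stringsAsFactors = FALSE)
  stopifnot(all(c("participant", "task", "condition") %in% names(m)))
  m
}
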