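#' Tri-axial accelerometer recording
#'
#' Container for one sensor channel's acceleration time series. Acceleration
#' is stored in g on a uniform time grid; axes are device axes (`ax`, `ay`,
#' `az`) until [estimate_vertical_axis()] rotates the frame.
#'
#' @param accel numeric matrix, n x 3, acceleration in g.
#' @param fs sampling rate (Hz).
#' @param location wearing location, `"chest"` or `"lumbar"`.
#' @param subject,visit,task identifiers (free-form; kept as metadata).
#' @param sensor_height pendulum length l (m), i.e. the height of the sensor
#'   above the ground; optional, `NA` if unknown.
#' @param start_s time of the first sample (s).
#'
#' @return an object of class `accel_recording` with elements `time`
#'   (seconds), `accel` (n x 3 matrix, g), `fs`, and the metadata fields.
#' @export
accel_recording <- function(accel, fs, location = c("chest", "lumbar"),
                            subject = NA, visit = NA, task = NA,
                            sensor_height = NA_real_, start_s = 0) {
  location <- match.arg(location)
  accel <- as.matrix(accel)
  if (ncol(accel) != 3) stop("`accel` must have 3 columns (ax, ay, az in g)")
  if (!is.numeric(accel) || anyNA(accel)) stop("`accel` must be numeric with no missing samples")
  stopifnot(fs > 0)
  colnames(accel) <- c("ax_g", "ay_g", "az_g")
  structure(list(
    time = start_s + seq_len(nrow(accel)) / fs - 1 / fs,
    accel = accel,
    fs = fs,
    location = location,
    subject = subject,
    visit = visit,
    task = task,
    sensor_height = sensor_height
  ), class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("accel_recording: %s, %.1f s at %g Hz (%d samples)\n",
              x$location, nrow(x$accel) / x$fs, x$fs, nrow(x$accel)))
  if (!is.na(x$subject))
    cat(sprintf("  subject %s, visit %s, task %s\n", x$subject, x$visit, x$task))
  if (!is.na(x$sensor_height))
    cat(sprintf("  sensor height %.3f m\n", x$sensor_height))
  invisible(x)
}

duration_s <- function(rec) nrow(rec$accel) / rec$fs

#' Write / read a recording as CSV
#'
#' The on-disk format is a plain CSV with header `time_s,ax_g,ay_g,az_g`,
#' monotone time at a fixed rate. Numbers are written with fixed precision so
#' repeated writes of the same recording are byte-identical.
#'
#' @param rec an [accel_recording].
#' @param path file path.
#' @return `write_recording_csv()` returns `path` invisibly;
#'   `read_recording_csv()` returns an [accel_recording].
#' @export
write_recording_csv <- function(rec, path) {
  df <- data.frame(
    time_s = sprintf("%.6f", rec$time),
    ax_g = sprintf("%.6f", rec$accel[, 1]),
    ay_g = sprintf("%.6f", rec$accel[, 2]),
    az_g = sprintf("%.6f", rec$accel[, 3])
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param location,subject,visit,task,sensor_height metadata attached to the
#'   recording read back from `path` (the CSV itself carries only the signal).
#' @export
read_recording_csv <- function(path, location = "chest", subject = NA,
                               visit = NA, task = NA,
                               sensor_height = NA_real_) {
  df <- read.csv(path)
  need <- c("time_s", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(df)))
    stop("recording CSV must have columns ", paste(need, collapse = ", "))
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  # total span is robust to per-sample timestamp rounding; snap to mHz
  fs <- round((nrow(df) - 1) / (df$time_s[nrow(df)] - df$time_s[1]), 3)
  accel_recording(as.matrix(df[, c("ax_g", "ay_g", "az_g")]), fs = fs,
                  location = location, subject = subject, visit = visit,
                  task = task, sensor_height = sensor_height,
                  start_s = df$time_s[1])
}
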