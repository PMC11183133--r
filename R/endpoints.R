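# Per-recording extraction and endpoint aggregation.

pendulum_length <- function(rec, config, default_height_m = 1.70) {
  if (!is.null(rec$sensor_height) && !is.na(rec$sensor_height))
    return(rec$sensor_height)
  frac <- config$sensor_height_fraction[[rec$location]]
  frac * default_height_m
}

#' Run the full single-sensor gait pipeline on one recording
#'
#' Aligns the recording to gravity, detects walking bouts from 3-s windows,
#' locates initial/final contacts in each bout with the wavelet detector,
#' double-integrates the vertical acceleration to per-step excursions, and
#' assembles the inverted-pendulum stride table. The pipeline is a pure
#' function of the recording and the configuration (no hidden randomness).
#'
#' @param rec an [accel_recording].
#' @param config a [pipeline_config()].
#' @return object of class `gait_extraction`: list with
#'   \describe{
#'     \item{bouts}{data.frame `bout, start_s, end_s, n_initial_contacts,
#'       n_cycles`;}
#'     \item{events}{list of [gait_events()], one per bout;}
#'     \item{strides}{a `stride_table` with the recording's subject / visit /
#'       task / location attached;}
#'     \item{log}{processing log: windows classified, gait windows, strides
#'       rejected, detector warnings.}
#'   }
#' @export
extract_gait <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "accel_recording"))
  aligned <- estimate_vertical_axis(rec)
  bouts <- detect_gait_bouts(aligned, config = config)
  l <- pendulum_length(rec, config)
  fs <- aligned$fs

  warn_log <- character(0)
  events <- list()
  stride_parts <- list()
  n_rejected <- 0L
  n_ic <- integer(nrow(bouts))
  for (b in seq_len(nrow(bouts))) {
    i0 <- round(bouts$start_s[b] * fs) + 1
    i1 <- min(nrow(aligned$accel), round(bouts$end_s[b] * fs))
    vacc <- aligned$accel[i0:i1, 1]
    ev <- withCallingHandlers(
      detect_contact_events(vacc, fs, config, offset_s = bouts$start_s[b]),
      warning = function(w) {
        warn_log <<- c(warn_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    events[[b]] <- ev
    n_ic[b] <- length(ev$initial_contacts)
    if (length(ev$initial_contacts) >= 3) {
      exc <- compute_vertical_excursion(
        vacc, fs, events = ev,
        highpass_cutoff = config$integration_highpass_hz,
        order = config$highpass_order, offset_s = bouts$start_s[b])
      st <- compute_stride_parameters(ev, exc, l, config, bout_id = b)
      n_rejected <- n_rejected + attr(st, "n_rejected")
      if (nrow(st)) stride_parts[[length(stride_parts) + 1]] <- st
    }
  }
  strides <- if (length(stride_parts)) {
    do.call(rbind, stride_parts)
  } else {
    compute_stride_parameters(gait_events(numeric(0)), numeric(0), l, config)
  }
  for (col in c("subject", "visit", "task", "location")) {
    strides[[col]] <- rep(rec[[col]] %||% NA, length.out = nrow(strides))
  }
  attr(strides, "n_rejected") <- n_rejected
  class(strides) <- c("stride_table", "data.frame")
  bouts$n_initial_contacts <- n_ic
  bouts$n_cycles <- floor(pmax(n_ic - 1, 0) / 2)

  structure(list(
    bouts = bouts,
    events = events,
    strides = strides,
    log = list(
      n_windows = length(attr(bouts, "window_flags")),
      n_gait_windows = sum(attr(bouts, "window_flags")),
      n_bouts = nrow(bouts),
      n_strides = nrow(strides),
      n_strides_rejected = n_rejected,
      pendulum_length_m = l,
      warnings = warn_log
    )
  ), class = "gait_extraction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gait_extraction <- function(x, ...) {
  cat(sprintf("gait_extraction: %d bouts, %d strides (%d rejected)\n",
              nrow(x$bouts), nrow(x$strides), x$log$n_strides_rejected))
  invisible(x)
}

#' Aggregate strides to subject-level gait endpoints
#'
#' For each subject x task x visit cell, the median of each endpoint is
#' extracted (strides are pooled across the cell's bouts); for activity
#' tasks the 95th percentile of gait speed is added (linear interpolation
#' between order statistics). Visit values are then averaged per subject and
#' task; a subject with only one visit in a cell keeps that visit's value.
#'
#' @param strides a stride table (or plain data.frame) with columns
#'   `subject`, `visit`, `task`, the endpoint columns `gait_speed_mps`,
#'   `cadence_spm`, `stride_time_s`, `stride_length_m`, and optionally
#'   `location` (kept as a grouping variable when present).
#' @param p95_tasks tasks for which the 95th-percentile gait speed endpoint
#'   is computed (long recordings with many steps).
#' @return object of class `endpoint_summary`: list of two long-format
#'   data.frames, `per_visit` (`subject, task, [location,] visit, endpoint,
#'   value`) and `cross_visit` (same minus `visit`).
#' @export
aggregate_endpoints <- function(strides,
                                p95_tasks = c("simulated_activities",
                                              "outside_activities")) {
  ep <- c(gait_speed = "gait_speed_mps", cadence = "cadence_spm",
          stride_time = "stride_time_s", stride_length = "stride_length_m")
  df <- as.data.frame(strides)
  if (!nrow(df)) {
    out <- data.frame(subject = character(0), task = character(0),
                      visit = character(0), endpoint = character(0),
                      value = numeric(0))
    return(structure(list(per_visit = out, cross_visit = out[-3]),
                     class = "endpoint_summary"))
  }
  grp_cols <- intersect(c("subject", "task", "location"), names(df))
  cells <- split(df, df[c(grp_cols, "visit")], drop = TRUE)
  per_visit <- do.call(rbind, lapply(cells, function(cell) {
    base <- cell[1, c(grp_cols, "visit"), drop = FALSE]
    vals <- vapply(ep, function(col) median(cell[[col]]), numeric(1))
    rows <- data.frame(base, endpoint = names(ep), value = unname(vals),
                       row.names = NULL)
    if (cell$task[1] %in% p95_tasks) {
      rows <- rbind(rows, data.frame(
        base, endpoint = "gait_speed_p95",
        value = unname(quantile(cell$gait_speed_mps, 0.95, type = 7)),
        row.names = NULL))
    }
    rows
  }))
  rownames(per_visit) <- NULL
  cross <- aggregate(per_visit$value,
                     by = per_visit[c(grp_cols, "endpoint")],
                     FUN = mean)
  names(cross)[ncol(cross)] <- "value"
  structure(list(per_visit = per_visit, cross_visit = cross),
            class = "endpoint_summary")
}

#' @export
print.endpoint_summary <- function(x, ...) {
  cat(sprintf("endpoint_summary: %d per-visit cells, %d cross-visit values\n",
              nrow(x$per_visit), nrow(x$cross_visit)))
  invisible(x)
}
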