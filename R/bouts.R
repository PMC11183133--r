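# Gait-bout detection from 3-s windows.
#
# Each non-overlapping window is summarised by three features of the
# vertical dynamic acceleration — intensity, locomotor-band dominance and
# short-lag periodicity — and classified by a transparent logistic rule.
# Consecutive positive windows are merged into maximal bouts on the window
# grid.

#' Per-window signal features for gait classification
#'
#' @param rec a gravity-aligned [accel_recording] (see
#'   [estimate_vertical_axis()]).
#' @param window_s window length (s); windows are non-overlapping.
#' @param band locomotor frequency band (Hz).
#' @return data.frame, one row per window: `start_s`, `end_s`, `rms_g` (RMS
#'   of vertical dynamic acceleration), `band_fraction` (share of spectral
#'   power in the locomotor band), `ac_peak` (maximum normalised
#'   autocorrelation at lags 0.25-1.5 s).
#' @export
window_features <- function(rec, window_s = 3, band = c(0.5, 3)) {
  stopifnot(isTRUE(rec$vertical_aligned))
  fs <- rec$fs
  w <- round(window_s * fs)
  n_win <- floor(nrow(rec$accel) / w)
  if (n_win < 1) stop("recording shorter than one window")
  lag_rng <- round(c(0.25, 1.5) * fs)
  out <- lapply(seq_len(n_win), function(i) {
    idx <- ((i - 1) * w + 1):(i * w)
    x <- rec$accel[idx, 1]
    xc <- x - mean(x)
    rms <- sqrt(mean(xc^2))
    dom <- dominant_frequency(x, fs, band)
    ac_peak <- 0
    if (rms > 1e-12) {
      ac <- stats::acf(xc, lag.max = min(lag_rng[2], length(xc) - 1),
                       plot = FALSE, demean = FALSE)$acf[, 1, 1]
      lags <- seq_along(ac) - 1
      sel <- lags >= lag_rng[1]
      if (any(sel)) ac_peak <- max(ac[sel])
    }
    data.frame(start_s = (i - 1) * window_s, end_s = i * window_s,
               rms_g = rms, band_fraction = dom$band_fraction,
               ac_peak = ac_peak)
  })
  do.call(rbind, out)
}

#' Frozen logistic gait-window classifier
#'
#' A transparent stand-in for a pre-trained gait classifier: a logistic rule
#' over the three [window_features()], with coefficients fit once on
#' simulator output and frozen here. A window is called gait when
#' `b0 + b1*log10(rms_g) + b2*band_fraction + b3*ac_peak > 0`. Inspectable
#' and swappable: any object with a `predict` method mapping the feature
#' frame to a logical vector can replace it in [detect_gait_bouts()].
#'
#' @param coef named numeric coefficients (intercept, log10_rms,
#'   band_fraction, ac_peak).
#' @return object of class `gait_classifier`.
#' @export
gait_window_classifier <- function(coef = c(intercept = -6.0,
                                            log10_rms = 1.2,
                                            band_fraction = 4.5,
                                            ac_peak = 4.5)) {
  structure(list(coef = coef), class = "gait_classifier")
}

#' @export
predict.gait_classifier <- function(object, newdata, ...) {
  b <- object$coef
  score <- b[["intercept"]] +
    b[["log10_rms"]] * log10(pmax(newdata$rms_g, 1e-5)) +
    b[["band_fraction"]] * newdata$band_fraction +
    b[["ac_peak"]] * newdata$ac_peak
  score > 0
}

#' Detect walking bouts from 3-s windows
#'
#' Classifies each non-overlapping window of the vertical dynamic
#' acceleration as gait / non-gait and merges consecutive positive windows
#' into maximal bouts. Bout boundaries lie on the window grid, intervals are
#' half-open `[start, end)`.
#'
#' @param rec an [accel_recording]; aligned to gravity automatically if
#'   needed.
#' @param window_s window length (s).
#' @param classifier a window classifier (default the frozen logistic rule).
#' @param config a [pipeline_config()].
#' @return object of class `gait_bouts`: data.frame `bout`, `start_s`,
#'   `end_s`, with the per-window flags in attribute `window_flags`.
#' @export
detect_gait_bouts <- function(rec, window_s = NULL,
                              classifier = NULL,
                              config = pipeline_config()) {
  if (is.null(window_s)) window_s <- config$window_s
  if (is.null(classifier)) classifier <- config$classifier
  rec <- estimate_vertical_axis(rec)
  feats <- window_features(rec, window_s, config$locomotor_band_hz)
  flags <- predict(classifier, feats)
  runs <- rle(as.logical(flags))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sel <- which(runs$values)
  df <- data.frame(
    bout = seq_along(sel),
    start_s = (starts[sel] - 1) * window_s,
    end_s = ends[sel] * window_s
  )
  structure(df, window_flags = flags, window_s = window_s,
            class = c("gait_bouts", "data.frame"))
}

#' @export
print.gait_bouts <- function(x, ...) {
  cat(sprintf("gait_bouts: %d bouts, %.1f s total walking\n",
              nrow(x), sum(x$end_s - x$start_s)))
  invisible(x)
}

#' Filter walking bouts by duration and gait-cycle count
#'
#' Retains a bout only if it lasts at least `min_duration_s` seconds AND
#' contains at least `min_cycles` complete gait cycles (a cycle = one
#' stride = two steps; with `n` initial contacts the bout holds
#' `floor((n-1)/2)` cycles).
#'
#' @param bouts data.frame of bouts with columns `start_s`, `end_s` and a
#'   list-column or parallel list of events; pass the result of
#'   [extract_gait()] (`$bouts` with `$events`) or any data.frame carrying a
#'   `n_initial_contacts` column.
#' @param events list of [gait_events()], one per bout row; not needed when
#'   `bouts` has `n_initial_contacts`.
#' @param min_duration_s,min_cycles the filter thresholds.
#' @return list: `retained` (filtered data.frame), `removed` (the rest),
#'   `report` (counts and percentage removed).
#' @export
filter_bouts <- function(bouts, events = NULL, min_duration_s = 9,
                         min_cycles = 4) {
  dur <- bouts$end_s - bouts$start_s
  if (!is.null(events)) {
    n_ic <- vapply(events, function(e) length(e$initial_contacts), integer(1))
  } else if ("n_initial_contacts" %in% names(bouts)) {
    n_ic <- bouts$n_initial_contacts
  } else {
    stop("bouts must carry events or an n_initial_contacts column")
  }
  cycles <- floor(pmax(n_ic - 1, 0) / 2)
  keep <- dur >= min_duration_s & cycles >= min_cycles
  list(
    retained = bouts[keep, , drop = FALSE],
    removed = bouts[!keep, , drop = FALSE],
    report = list(
      n_total = length(keep),
      n_removed = sum(!keep),
      pct_removed = if (length(keep)) 100 * mean(!keep) else 0
    )
  )
}

#' Walking-bout statistics for one recording
#'
#' @param bouts data.frame with `start_s`, `end_s` and `n_initial_contacts`
#'   (steps per bout = its initial-contact count), typically the `retained`
#'   element of [filter_bouts()].
#' @return one-row data.frame: `mean_bout_duration_s`, `total_walking_time_s`,
#'   `n_bouts`, `total_steps`. Empty input yields zeros.
#' @export
compute_bout_stats <- function(bouts) {
  if (!nrow(bouts)) {
    return(data.frame(mean_bout_duration_s = 0, total_walking_time_s = 0,
                      n_bouts = 0L, total_steps = 0L))
  }
  dur <- bouts$end_s - bouts$start_s
  data.frame(
    mean_bout_duration_s = mean(dur),
    total_walking_time_s = sum(dur),
    n_bouts = nrow(bouts),
    total_steps = sum(bouts$n_initial_contacts)
  )
}
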