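# Inverted-pendulum spatial gait parameters.
#
# Double integration of the vertical acceleration (with zero-phase high-pass
# drift removal after each stage) gives the vertical centre-of-mass
# displacement; its per-step peak-to-peak amplitude h enters the inverted
# pendulum formula: step length = 2 * sqrt(2*l*h - h^2), with l the pendulum
# length. A stride spans two consecutive same-foot initial contacts, so its
# length is the sum of two consecutive step lengths.

#' Vertical centre-of-mass excursion from vertical acceleration
#'
#' Double-integrates the vertical dynamic acceleration to displacement with
#' zero-phase high-pass drift removal after each integration stage, then
#' measures the peak-to-peak excursion — over the whole segment, or per step
#' when `events` are supplied.
#'
#' @param vacc vertical dynamic acceleration (gravity removed), in g.
#' @param fs sampling rate (Hz).
#' @param events optional [gait_events()]; when given, one excursion per
#'   inter-initial-contact interval (step) is returned.
#' @param highpass_cutoff drift-removal cutoff (Hz).
#' @param order Butterworth order of the drift filter.
#' @param offset_s time of the first sample of `vacc` (s), the clock on which
#'   event times are expressed.
#' @return a single excursion (m), or a numeric vector with one value per
#'   step when `events` is given. Zero acceleration yields zero excursion.
#' @export
compute_vertical_excursion <- function(vacc, fs, events = NULL,
                                       highpass_cutoff = 0.1, order = 4,
                                       offset_s = 0) {
  if (length(vacc) < 3) stop("segment must have at least 3 samples")
  if (all(abs(vacc - mean(vacc)) < 1e-15)) {
    z <- numeric(length(vacc))
  } else {
    a <- (vacc - mean(vacc)) * GRAVITY_MS2
    v <- highpass_zerophase(cumtrapz_dt(a, 1 / fs), fs, highpass_cutoff, order)
    z <- highpass_zerophase(cumtrapz_dt(v, 1 / fs), fs, highpass_cutoff, order)
  }
  if (is.null(events)) return(max(z) - min(z))
  ic <- events$initial_contacts - offset_s
  if (length(ic) < 2) return(numeric(0))
  vapply(seq_len(length(ic) - 1), function(k) {
    i0 <- max(1, round(ic[k] * fs) + 1)
    i1 <- min(length(z), round(ic[k + 1] * fs) + 1)
    if (i1 - i0 < 2) return(NA_real_)
    max(z[i0:i1]) - min(z[i0:i1])
  }, numeric(1))
}

#' Inverted-pendulum step length
#'
#' `2 * sqrt(2*l*h - h^2)`: the chord of a circular arc of radius `l` whose
#' sagitta is the vertical excursion `h`.
#'
#' @param h vertical centre-of-mass excursion (m); must satisfy `0 <= h < l`.
#' @param l pendulum length (m).
#' @return step length (m); `h = 0` gives 0.
#' @export
step_length <- function(h, l) {
  stopifnot(all(h >= 0), all(h < l))
  2 * sqrt(2 * l * h - h^2)
}

#' Per-stride spatiotemporal parameters from contact events and excursions
#'
#' Builds the stride table: stride time is the interval between consecutive
#' same-foot initial contacts (every second contact, no left/right labelling
#' from a trunk sensor); stride length is the sum of the two step lengths
#' `2*sqrt(2*l*h - h^2)` inside the stride; gait speed is stride length over
#' stride time; cadence is `120 / stride time` steps/min. Strides with
#' implausible values are dropped and counted.
#'
#' @param events a [gait_events()] with at least 2 initial contacts (fewer
#'   yields an empty table).
#' @param excursions per-step vertical excursions (m), one per
#'   inter-initial-contact interval, as returned by
#'   [compute_vertical_excursion()].
#' @param l pendulum length (m); steps with `h >= l` are invalid and the
#'   enclosing stride is dropped.
#' @param config a [pipeline_config()] supplying the plausibility bounds.
#' @param bout_id bout identifier stored with each stride.
#' @return a `stride_table`: data.frame with columns `bout`, `start_s`,
#'   `stride_time_s`, `stride_length_m`, `gait_speed_mps`, `cadence_spm`,
#'   `h_m`, `l_m`; attribute `n_rejected` counts strides dropped by the
#'   plausibility bounds or invalid geometry.
#' @export
compute_stride_parameters <- function(events, excursions, l,
                                      config = pipeline_config(),
                                      bout_id = 1L) {
  empty <- structure(
    data.frame(bout = integer(0), start_s = numeric(0),
               stride_time_s = numeric(0), stride_length_m = numeric(0),
               gait_speed_mps = numeric(0), cadence_spm = numeric(0),
               h_m = numeric(0), l_m = numeric(0)),
    n_rejected = 0L, class = c("stride_table", "data.frame"))
  ic <- events$initial_contacts
  if (length(ic) < 3) return(empty)
  stopifnot(length(excursions) == length(ic) - 1)
  step_len <- function(h) {
    if (is.na(h) || h < 0 || h >= l) return(NA_real_)
    2 * sqrt(2 * l * h - h^2)
  }
  rows <- list()
  n_rej <- 0L
  for (k in seq(1, length(ic) - 2, by = 2)) {
    st <- ic[k + 2] - ic[k]
    sl <- step_len(excursions[k]) + step_len(excursions[k + 1])
    if (is.na(sl) ||
        st < config$stride_time_bounds_s[1] ||
        st > config$stride_time_bounds_s[2] ||
        sl < config$stride_length_bounds_m[1] ||
        sl > config$stride_length_bounds_m[2]) {
      n_rej <- n_rej + 1L
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      bout = bout_id, start_s = ic[k], stride_time_s = st,
      stride_length_m = sl, gait_speed_mps = sl / st,
      cadence_spm = 120 / st,
      h_m = mean(excursions[c(k, k + 1)]), l_m = l)
  }
  if (!length(rows)) {
    attr(empty, "n_rejected") <- n_rej
    return(empty)
  }
  out <- do.call(rbind, rows)
  structure(out, n_rejected = n_rej, class = c("stride_table", "data.frame"))
}

#' @export
print.stride_table <- function(x, ...) {
  cat(sprintf("stride_table: %d strides (%d rejected by plausibility bounds)\n",
              nrow(x), attr(x, "n_rejected")))
  if (nrow(x)) {
    cat(sprintf("  gait speed %.2f m/s, stride time %.2f s (medians)\n",
                median(x$gait_speed_mps), median(x$stride_time_s)))
  }
  invisible(x)
}
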