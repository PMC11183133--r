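# Wavelet-based initial/final contact detection.
#
# The method family: de-mean the vertical acceleration, integrate once
# (velocity), smooth/differentiate with a continuous wavelet transform using
# the first derivative of a Gaussian at a scale tied to the dominant step
# frequency; minima of the transform mark initial contacts. Differentiating
# the transformed signal and re-transforming gives a signal whose maxima
# mark final contacts.

#' Gait events container
#'
#' Holds initial-contact (heel strike) and final-contact (toe off) times for
#' one bout. The constructor sorts both lists and enforces the alternation
#' invariant: each retained final contact lies strictly between two
#' successive initial contacts (at most one per inter-step interval; the
#' strongest candidate wins when `strength` is supplied).
#'
#' @param initial_contacts,final_contacts event times (s).
#' @param fc_strength optional weights used to pick one final contact per
#'   inter-initial-contact interval.
#' @return object of class `gait_events`.
#' @export
gait_events <- function(initial_contacts, final_contacts = numeric(0),
                        fc_strength = NULL) {
  ic <- sort(unique(as.numeric(initial_contacts)))
  fc_in <- as.numeric(final_contacts)
  if (is.null(fc_strength)) fc_strength <- rep(1, length(fc_in))
  keep <- numeric(0)
  if (length(ic) >= 2 && length(fc_in)) {
    for (k in seq_len(length(ic) - 1)) {
      inside <- which(fc_in > ic[k] & fc_in < ic[k + 1])
      if (length(inside))
        keep <- c(keep, fc_in[inside[which.max(fc_strength[inside])]])
    }
  }
  structure(list(initial_contacts = ic, final_contacts = sort(keep)),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("gait_events: %d initial, %d final contacts\n",
              length(x$initial_contacts), length(x$final_contacts)))
  invisible(x)
}

#' Dominant frequency of a signal in a band
#'
#' Periodogram peak restricted to `band`, with a dominance ratio (peak power
#' over the mean power of the full positive-frequency spectrum) used to
#' decide whether a locomotor rhythm is present at all.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param band numeric length-2 search band (Hz).
#' @return list `freq` (Hz), `dominance` (unitless ratio), `band_fraction`
#'   (share of total power inside the band).
#' @export
dominant_frequency <- function(x, fs, band = c(0.5, 3)) {
  x <- x - mean(x)
  n <- length(x)
  if (n < 8 || var(x) < 1e-14)
    return(list(freq = NA_real_, dominance = 0, band_fraction = 0))
  nfft <- nextn(n, 2)
  p <- Mod(fft(c(x, numeric(nfft - n))))^2
  half <- 2:(nfft %/% 2)            # drop DC and Nyquist
  f <- (half - 1) * fs / nfft
  p <- p[half]
  in_band <- f >= band[1] & f <= band[2]
  if (!any(in_band))
    return(list(freq = NA_real_, dominance = 0, band_fraction = 0))
  i <- which.max(p * in_band)
  list(freq = f[i],
       dominance = p[i] / mean(p),
       band_fraction = sum(p[in_band]) / sum(p))
}

#' Continuous wavelet transform with a first-derivative-of-Gaussian wavelet
#'
#' Correlates the signal with the scaled wavelet `psi(u) = -u * exp(-u^2/2)`
#' (a smoothed differentiator). Edges are handled by reflection padding; the
#' kernel support is truncated at five scales.
#'
#' @param x numeric signal.
#' @param scale wavelet scale in samples.
#' @return numeric vector, same length as `x`.
#' @export
cwt_gaus1 <- function(x, scale) {
  stopifnot(scale > 0)
  m <- ceiling(5 * scale)
  u <- (-m:m) / scale
  kern <- -u * exp(-u^2 / 2) / sqrt(scale)
  n <- length(x)
  pad <- min(m, n - 1)
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  out <- stats::filter(xp, rev(kern), method = "convolution", sides = 2)
  as.numeric(out[(pad + 1):(pad + n)])
}

#' Detect initial and final contacts in a vertical-acceleration segment
#'
#' @param vacc vertical dynamic acceleration (gravity removed), in g.
#' @param fs sampling rate (Hz).
#' @param config a [pipeline_config()]; supplies the locomotor band, the
#'   wavelet scale factor and the drift high-pass.
#' @param offset_s time of the first sample (s); event times are reported on
#'   this clock.
#' @return a [gait_events()] object. When no dominant locomotor frequency is
#'   found in the band (e.g. stillness or pure noise) an empty event set is
#'   returned with a warning.
#' @details The wavelet scale is set so the transform's peak response lies at
#'   `config$cwt_scale_factor` times the dominant step frequency:
#'   `scale = fs / (2 * pi * factor * f_step)` samples (the wavelet's centre
#'   frequency is `1/(2*pi)` cycles per sample at scale 1).
#' @export
detect_contact_events <- function(vacc, fs, config = pipeline_config(),
                                  offset_s = 0) {
  band <- config$locomotor_band_hz
  dom <- dominant_frequency(vacc, fs, band)
  if (is.na(dom$freq) || dom$dominance < 20 || dom$band_fraction < 0.2) {
    warning("no dominant locomotor frequency in band; returning empty events")
    return(gait_events(numeric(0)))
  }
  f_step <- dom$freq
  if (length(vacc) < 2 * fs / f_step) {
    warning("segment shorter than two step cycles; returning empty events")
    return(gait_events(numeric(0)))
  }
  a <- (vacc - mean(vacc)) * GRAVITY_MS2
  v <- cumtrapz_dt(a, 1 / fs)
  v <- highpass_zerophase(v, fs, config$integration_highpass_hz,
                          config$highpass_order)
  scale <- fs / (2 * pi * config$cwt_scale_factor * f_step)
  w1 <- cwt_gaus1(v, scale)

  min_dist <- max(1, round(0.5 * fs / f_step))
  thr1 <- 0.3 * quantile(abs(w1), 0.9)
  ic_idx <- find_extrema(-w1, min_height = thr1, min_dist = min_dist)

  d1 <- c(diff(w1), 0) * fs
  w2 <- cwt_gaus1(d1, scale)
  thr2 <- 0.3 * quantile(abs(w2), 0.9)
  fc_idx <- find_extrema(w2, min_height = thr2, min_dist = min_dist)

  gait_events(offset_s + (ic_idx - 1) / fs,
              offset_s + (fc_idx - 1) / fs,
              fc_strength = w2[fc_idx])
}

# local maxima above min_height with a minimum separation; on ties/conflicts
# the taller peak wins
find_extrema <- function(x, min_height, min_dist) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

# trapezoid cumulative integral with uniform spacing dt, first value 0
cumtrapz_dt <- function(x, dt) {
  c(0, cumsum((x[-1] + x[-length(x)]) / 2)) * dt
}

# zero-phase Butterworth high-pass (applied forward and backward)
highpass_zerophase <- function(x, fs, cutoff, order = 4) {
  wc <- cutoff / (fs / 2)
  if (wc >= 1) stop("high-pass cutoff must be below Nyquist")
  bf <- signal::butter(order, wc, type = "high")
  as.numeric(signal::filtfilt(bf, x))
}
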