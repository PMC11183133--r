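#' Simulation configuration for a synthetic gait study
#'
#' Collects every knob of the synthetic-data generator: study structure
#' (subjects, visits, tasks, sampling rate), the walking-speed and stride-time
#' distributions, device-specific noise and bias, and the visit-to-visit
#' correlation of subject-level gait parameters.
#'
#' Defaults emulate a two-visit validation study in healthy adults: 20
#' subjects, two visits about a week apart, a 128 Hz tri-axial accelerometer,
#' three self-paced walking speeds plus an in-lab simulated-activity session
#' and a longer outside-lab session. Speed and stride-time distributions
#' (normal pace 1.25 +/- 0.15 m/s, stride time 1.05 +/- 0.08 s, slow/fast
#' multipliers 0.75/1.25) are generator choices representative of healthy
#' self-paced gait.
#'
#' @param n_subjects number of subjects.
#' @param n_visits number of visits per subject.
#' @param sampling_rate_hz accelerometer sampling rate (Hz).
#' @param tasks character vector drawn from `walk_slow`, `walk_normal`,
#'   `walk_fast`, `simulated_activities`, `outside_activities`.
#' @param speed_mean_mps,speed_sd_mps between-subject distribution of
#'   normal-pace gait speed (m/s).
#' @param speed_multipliers length-2 numeric, multiplicative slow and fast
#'   factors relative to normal pace; must straddle 1.
#' @param stride_time_mean_s,stride_time_sd_s between-subject distribution of
#'   normal-pace stride time (s).
#' @param chest_bias_mps additive device effect of the chest channel on true
#'   gait speed, implemented as a rescaling of the vertical-excursion
#'   amplitude so that the chest signal encodes `speed + chest_bias_mps`
#'   while the ground truth keeps `speed` (m/s). 0 = unbiased chest device.
#' @param noise_sd_g white sensor-noise SD per axis for the lumbar channel
#'   (g); the chest channel uses `noise_sd_g * chest_noise_multiplier`.
#' @param chest_noise_multiplier chest/lumbar noise ratio (>= 1 reflects the
#'   noisier mounting of a harness-worn chest device).
#' @param visit_retest_rho correlation of subject-level speed and stride-time
#'   parameters across visits, in (0, 1].
#' @param walk_task_duration_s duration of each fixed-speed walking task (s).
#' @param lab_session_duration_s,outside_session_duration_s duration of the
#'   in-lab simulated-activity and outside-lab free-moving sessions (s).
#' @param walk_fraction fraction of an activity session spent walking.
#' @param mean_bout_duration_s mean duration of a walking bout inside an
#'   activity session (s), exponentially distributed above a 5 s floor.
#' @param subject_height_mean_m,subject_height_sd_m body-height distribution
#'   used to derive pendulum lengths.
#' @param random_orientation logical; tilt each recording by a random device
#'   orientation (up to `max_tilt_deg`) so that vertical-axis estimation is
#'   exercised.
#' @param max_tilt_deg maximum random tilt angle (degrees).
#' @param age_range_yr integer range subjects' ages are drawn from.
#' @param seed integer seed; every per-subject substream is derived from it,
#'   so adding subjects does not perturb existing ones.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_study()], [simulate_walk_segment()],
#'   [simulate_activity_session()]
#' @export
sim_config <- function(n_subjects = 20,
                       n_visits = 2,
                       sampling_rate_hz = 128,
                       tasks = c("walk_slow", "walk_normal", "walk_fast",
                                 "simulated_activities", "outside_activities"),
                       speed_mean_mps = 1.25,
                       speed_sd_mps = 0.15,
                       speed_multipliers = c(0.75, 1.25),
                       stride_time_mean_s = 1.05,
                       stride_time_sd_s = 0.08,
                       chest_bias_mps = 0,
                       noise_sd_g = 0.02,
                       chest_noise_multiplier = 1.25,
                       visit_retest_rho = 0.9,
                       walk_task_duration_s = 30,
                       lab_session_duration_s = 420,
                       outside_session_duration_s = 1200,
                       walk_fraction = 0.5,
                       mean_bout_duration_s = 30,
                       subject_height_mean_m = 1.70,
                       subject_height_sd_m = 0.09,
                       random_orientation = TRUE,
                       max_tilt_deg = 15,
                       age_range_yr = c(25, 61),
                       seed = 20240617) {
  known <- c("walk_slow", "walk_normal", "walk_fast",
             "simulated_activities", "outside_activities")
  tasks <- match.arg(tasks, known, several.ok = TRUE)
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_visits = as.integer(n_visits),
    sampling_rate_hz = sampling_rate_hz,
    tasks = tasks,
    speed_mean_mps = speed_mean_mps,
    speed_sd_mps = speed_sd_mps,
    speed_multipliers = speed_multipliers,
    stride_time_mean_s = stride_time_mean_s,
    stride_time_sd_s = stride_time_sd_s,
    chest_bias_mps = chest_bias_mps,
    noise_sd_g = noise_sd_g,
    chest_noise_multiplier = chest_noise_multiplier,
    visit_retest_rho = visit_retest_rho,
    walk_task_duration_s = walk_task_duration_s,
    lab_session_duration_s = lab_session_duration_s,
    outside_session_duration_s = outside_session_duration_s,
    walk_fraction = walk_fraction,
    mean_bout_duration_s = mean_bout_duration_s,
    subject_height_mean_m = subject_height_mean_m,
    subject_height_sd_m = subject_height_sd_m,
    random_orientation = isTRUE(random_orientation),
    max_tilt_deg = max_tilt_deg,
    age_range_yr = age_range_yr,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_subjects >= 1, cfg$n_visits >= 1,
    cfg$sampling_rate_hz > 0,
    cfg$visit_retest_rho > 0, cfg$visit_retest_rho <= 1,
    length(cfg$speed_multipliers) == 2,
    cfg$speed_multipliers[1] < 1, cfg$speed_multipliers[2] > 1,
    cfg$speed_sd_mps >= 0, cfg$stride_time_sd_s >= 0, cfg$noise_sd_g >= 0,
    cfg$chest_noise_multiplier >= 1,
    cfg$walk_fraction > 0, cfg$walk_fraction < 1
  )
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic gait study configuration\n")
  cat(sprintf("  %d subjects x %d visits, fs = %g Hz, seed = %d\n",
              x$n_subjects, x$n_visits, x$sampling_rate_hz, x$seed))
  cat("  tasks:", paste(x$tasks, collapse = ", "), "\n")
  cat(sprintf("  normal speed %g +/- %g m/s, multipliers (%g, %g)\n",
              x$speed_mean_mps, x$speed_sd_mps,
              x$speed_multipliers[1], x$speed_multipliers[2]))
  cat(sprintf("  stride time %g +/- %g s; retest rho %g\n",
              x$stride_time_mean_s, x$stride_time_sd_s, x$visit_retest_rho))
  cat(sprintf("  noise %g g (chest x%g), chest speed bias %g m/s\n",
              x$noise_sd_g, x$chest_noise_multiplier, x$chest_bias_mps))
  invisible(x)
}

#' Extraction-pipeline configuration
#'
#' Parameters of the single-sensor gait pipeline. Every numeric choice of the
#' pipeline lives here so a processing run is self-describing.
#'
#' @param window_s bout-classifier window length (s).
#' @param locomotor_band_hz frequency band (Hz) searched for the dominant
#'   step frequency.
#' @param cwt_scale_factor the wavelet scale is chosen so the transform's
#'   peak response sits at `cwt_scale_factor` times the dominant step
#'   frequency.
#' @param integration_highpass_hz zero-phase high-pass cutoff (Hz) applied
#'   after each integration stage to remove drift.
#' @param highpass_order Butterworth order of that filter (applied forward
#'   and backward).
#' @param min_bout_duration_s,min_bout_cycles walking-bout filter: retain a
#'   bout only if it lasts at least `min_bout_duration_s` seconds and
#'   contains at least `min_bout_cycles` complete gait cycles.
#' @param stride_time_bounds_s,stride_length_bounds_m plausibility bounds;
#'   strides outside either range are dropped and counted.
#' @param sensor_height_fraction named pair: pendulum length as a fraction of
#'   body height per wearing location (anthropometric convention: lumbar
#'   sensors sit at ~53% of body height, sternal sensors at ~72%).
#' @param classifier window classifier used by [detect_gait_bouts()];
#'   defaults to the frozen logistic rule [gait_window_classifier()].
#'
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_s = 3,
                            locomotor_band_hz = c(0.5, 3),
                            cwt_scale_factor = 1.25,
                            integration_highpass_hz = 0.1,
                            highpass_order = 4,
                            min_bout_duration_s = 9,
                            min_bout_cycles = 4,
                            stride_time_bounds_s = c(0.4, 2.25),
                            stride_length_bounds_m = c(0.3, 3),
                            sensor_height_fraction = c(lumbar = 0.53, chest = 0.72),
                            classifier = gait_window_classifier()) {
  stopifnot(window_s > 0, length(locomotor_band_hz) == 2,
            locomotor_band_hz[1] > 0,
            locomotor_band_hz[2] > locomotor_band_hz[1],
            integration_highpass_hz > 0, cwt_scale_factor > 0,
            min_bout_duration_s >= 0, min_bout_cycles >= 0,
            all(c("lumbar", "chest") %in% names(sensor_height_fraction)))
  structure(list(
    window_s = window_s,
    locomotor_band_hz = locomotor_band_hz,
    cwt_scale_factor = cwt_scale_factor,
    integration_highpass_hz = integration_highpass_hz,
    highpass_order = highpass_order,
    min_bout_duration_s = min_bout_duration_s,
    min_bout_cycles = min_bout_cycles,
    stride_time_bounds_s = stride_time_bounds_s,
    stride_length_bounds_m = stride_length_bounds_m,
    sensor_height_fraction = sensor_height_fraction,
    classifier = classifier
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Gait extraction configuration\n")
  cat(sprintf("  %g s windows; locomotor band %g-%g Hz; CWT scale factor %g\n",
              x$window_s, x$locomotor_band_hz[1], x$locomotor_band_hz[2],
              x$cwt_scale_factor))
  cat(sprintf("  integration high-pass %g Hz (order %d, zero phase)\n",
              x$integration_highpass_hz, x$highpass_order))
  cat(sprintf("  bout filter: >= %g s and >= %g cycles\n",
              x$min_bout_duration_s, x$min_bout_cycles))
  cat(sprintf("  stride bounds: time %g-%g s, length %g-%g m\n",
              x$stride_time_bounds_s[1], x$stride_time_bounds_s[2],
              x$stride_length_bounds_m[1], x$stride_length_bounds_m[2]))
  invisible(x)
}
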