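# Synthetic accelerometer-walking generator.
#
# The forward model inverts the inverted-pendulum estimator used by the
# extraction pipeline: given gait speed v and stride time T, the step length
# is sl = v * T / 2 and the vertical centre-of-mass excursion is
#   h = l - sqrt(l^2 - (sl/2)^2),   with pendulum length l,
# the exact inverse of the estimator's sl = 2 * sqrt(2*l*h - h^2). Vertical
# displacement is a cosine arc at step frequency with peak-to-peak h;
# vertical acceleration is its exact second derivative plus gravity.

#' Vertical centre-of-mass excursion implied by a walking condition
#'
#' Inverts the inverted-pendulum step-length formula: given gait speed and
#' stride time (hence step length `sl = speed * stride_time / 2`) and
#' pendulum length `l`, returns the vertical excursion `h` such that
#' `sl = 2 * sqrt(2 * l * h - h^2)`.
#'
#' @param speed gait speed (m/s).
#' @param stride_time stride duration (s).
#' @param l pendulum length (m).
#' @return vertical excursion h (m).
#' @export
pendulum_excursion <- function(speed, stride_time, l) {
  sl <- speed * stride_time / 2
  if (sl >= 2 * l)
    stop(sprintf("infeasible geometry: step length %.3f m >= 2 * pendulum length %.3f m",
                 sl, l))
  l - sqrt(l^2 - (sl / 2)^2)
}

# deterministic per-substream seeds so adding subjects/locations never
# perturbs existing draws; kept below 2^31 - 1
substream_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in seq_along(idx)) {
    s <- (s * 69069 + 1000003 * (as.double(idx[k]) + k)) %% 2147483629
  }
  as.integer(s)
}

# Rodrigues rotation about a unit axis
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# random device tilt: rotation of up to max_tilt_deg about a random
# horizontal axis, composed with a random yaw about vertical
random_orientation <- function(max_tilt_deg) {
  yaw <- runif(1, 0, 2 * pi)
  phi <- runif(1, 0, 2 * pi)
  tilt <- runif(1, 0, max_tilt_deg) * pi / 180
  rotation_matrix(c(cos(phi), sin(phi), 0), tilt) %*%
    rotation_matrix(c(0, 0, 1), yaw)
}

empty_truth <- function(duration) {
  list(
    initial_contacts = numeric(0),
    final_contacts = numeric(0),
    bouts = data.frame(start_s = numeric(0), end_s = numeric(0)),
    step_count = 0L,
    strides = data.frame(bout = integer(0), start_s = numeric(0),
                         stride_time_s = numeric(0), stride_length_m = numeric(0),
                         gait_speed_mps = numeric(0), cadence_spm = numeric(0))
  )
}

walk_truth <- function(speed, stride_time, duration, offset = 0, bout_id = 1L) {
  t_step <- stride_time / 2
  ic <- seq(t_step / 2, duration - 1e-9, by = t_step)
  fc <- if (length(ic) >= 2) head(ic, -1) + t_step / 2 else numeric(0)
  k <- seq(1, length.out = max(0, floor((length(ic) - 1) / 2)), by = 2)
  strides <- data.frame(
    bout = rep(bout_id, length(k)),
    start_s = offset + ic[k],
    stride_time_s = rep(stride_time, length(k)),
    stride_length_m = rep(speed * stride_time, length(k)),
    gait_speed_mps = rep(speed, length(k)),
    cadence_spm = rep(120 / stride_time, length(k))
  )
  list(
    initial_contacts = offset + ic,
    final_contacts = offset + fc,
    bouts = data.frame(start_s = offset, end_s = offset + duration),
    step_count = length(ic),
    strides = strides
  )
}

# raw tri-axial walking signal (n x 3, in g, device frame = AP, ML, V)
walk_signal <- function(n, fs, speed, stride_time, h) {
  t <- seq_len(n) / fs - 1 / fs
  if (speed <= 0 || h <= 0) {
    return(cbind(numeric(n), numeric(n), rep(1, n)))
  }
  omega <- 2 * pi * 2 / stride_time              # step angular frequency
  # vertical displacement z = (h/2) cos(omega t): minima (initial contacts)
  # at t = T_step/2 + k T_step, peak-to-peak excursion exactly h
  az_dyn <- -(h / 2) * omega^2 * cos(omega * t) / GRAVITY_MS2
  amp_v <- (h / 2) * omega^2 / GRAVITY_MS2
  ap <- 0.40 * amp_v * sin(omega * t + pi / 3)
  ml <- 0.25 * amp_v * sin(omega * t / 2 + pi / 5)
  cbind(ap, ml, 1 + az_dyn)
}

merge_truth <- function(parts) {
  if (!length(parts)) return(empty_truth(0))
  list(
    initial_contacts = unlist(lapply(parts, `[[`, "initial_contacts")),
    final_contacts = unlist(lapply(parts, `[[`, "final_contacts")),
    bouts = do.call(rbind, lapply(parts, `[[`, "bouts")),
    step_count = sum(vapply(parts, `[[`, integer(1), "step_count")),
    strides = do.call(rbind, lapply(parts, `[[`, "strides"))
  )
}

#' Simulate one continuous walking (or standing) segment
#'
#' Generates a tri-axial acceleration segment from the inverted-pendulum
#' forward model together with its complete ground truth: initial/final
#' contact instants, bout interval, per-stride parameters and step count.
#' `speed = 0` produces quiet standing (vertical channel at 1 g plus noise,
#' no events).
#'
#' @param speed true gait speed (m/s); 0 for standing.
#' @param stride_time stride duration (s).
#' @param duration segment duration (s); must cover at least one stride when
#'   walking. Rounded to a whole number of samples.
#' @param sensor_height pendulum length l (m).
#' @param sampling_rate sampling rate (Hz).
#' @param noise_sd white sensor-noise SD per axis (g).
#' @param seed integer seed for the noise draw.
#' @param signal_speed speed actually encoded in the signal amplitude; lets a
#'   device bias be injected while the ground truth keeps `speed`. Defaults
#'   to `speed`.
#' @param orientation optional 3 x 3 rotation applied to the (AP, ML, V)
#'   device frame, simulating an arbitrary mounting orientation.
#' @param location,subject,visit,task metadata for the recording.
#'
#' @return list with elements `recording` (an [accel_recording]) and `truth`
#'   (ground-truth list: `initial_contacts`, `final_contacts`, `bouts`,
#'   `step_count`, `strides`).
#' @examples
#' seg <- simulate_walk_segment(1.2, 1.0, duration = 10, sensor_height = 1,
#'                              sampling_rate = 128, noise_sd = 0, seed = 1)
#' seg$truth$step_count  # 20 steps in 10 s at stride time 1 s
#' @export
simulate_walk_segment <- function(speed, stride_time, duration,
                                  sensor_height, sampling_rate = 128,
                                  noise_sd = 0, seed = 1,
                                  signal_speed = speed,
                                  orientation = NULL,
                                  location = "chest", subject = NA,
                                  visit = NA, task = NA) {
  stopifnot(speed >= 0, stride_time > 0, duration > 0, sensor_height > 0)
  if (speed > 0 && duration < stride_time)
    stop("duration must cover at least one stride")
  n <- round(duration * sampling_rate)
  duration <- n / sampling_rate
  h <- if (signal_speed > 0) {
    pendulum_excursion(signal_speed, stride_time, sensor_height)
  } else 0
  sig <- walk_signal(n, sampling_rate, signal_speed, stride_time, h)
  if (!is.null(orientation)) sig <- sig %*% t(orientation)
  if (noise_sd > 0) {
    set.seed(seed)
    sig <- sig + matrix(rnorm(3 * n, sd = noise_sd), n, 3)
  }
  truth <- if (speed > 0) walk_truth(speed, stride_time, duration)
           else empty_truth(duration)
  list(
    recording = accel_recording(sig, fs = sampling_rate, location = location,
                                subject = subject, visit = visit, task = task,
                                sensor_height = sensor_height),
    truth = truth
  )
}

# non-gait filler: stillness, optionally with a broadband "object moving"
# burst; contains no periodic locomotor-band component by construction
nongait_signal <- function(n, fs, noise_sd, burst = FALSE) {
  sig <- cbind(numeric(n), numeric(n), rep(1, n))
  if (noise_sd > 0) sig <- sig + matrix(rnorm(3 * n, sd = noise_sd), n, 3)
  if (burst && n > fs) {
    len <- min(n, round(runif(1, 2, 5) * fs))
    at <- sample.int(n - len + 1, 1)
    idx <- at:(at + len - 1)
    sig[idx, ] <- sig[idx, ] + matrix(rnorm(3 * len, sd = 0.08), len, 3)
  }
  sig
}

#' Simulate a free-moving activity session
#'
#' Alternates walking bouts with non-gait segments (quiet sitting/standing,
#' broadband object-handling bursts) to emulate a simulated-activity or
#' free-living session. Bout durations are exponential above a 5 s floor;
#' the mean non-gait gap is chosen so the expected walking fraction equals
#' `walk_fraction`. Ground-truth bout intervals exactly delimit the generated
#' walking; per-bout speed and stride time jitter around the subject values
#' by ~3%.
#'
#' @param duration_s session length (s).
#' @param walk_fraction target fraction of time spent walking, in (0, 1).
#'   Values above 0.99 produce a single continuous bout.
#' @param mean_bout_duration_s mean walking-bout duration (s).
#' @param speed,stride_time subject-level gait parameters (m/s, s).
#' @param sensor_height pendulum length l (m).
#' @param sampling_rate sampling rate (Hz).
#' @param noise_sd sensor-noise SD (g).
#' @param seed integer seed for the session structure (bout layout, per-bout
#'   jitter, object-handling bursts) — the physical scene, shared by
#'   co-located devices.
#' @param noise_seed integer seed for the device-specific sensor noise;
#'   defaults to `seed + 1`.
#' @inheritParams simulate_walk_segment
#' @return list with `recording` and `truth` as in [simulate_walk_segment()];
#'   `truth$bouts` has one row per walking bout.
#' @export
simulate_activity_session <- function(duration_s, walk_fraction = 0.5,
                                      mean_bout_duration_s = 30,
                                      speed = 1.25, stride_time = 1.05,
                                      sensor_height = 0.9,
                                      sampling_rate = 128, noise_sd = 0.02,
                                      seed = 1, noise_seed = seed + 1,
                                      signal_speed = speed,
                                      orientation = NULL,
                                      location = "chest", subject = NA,
                                      visit = NA, task = NA) {
  stopifnot(walk_fraction > 0, walk_fraction < 1, duration_s > 0)
  fs <- sampling_rate
  set.seed(seed)
  n_total <- round(duration_s * fs)

  if (walk_fraction > 0.99) {
    return(simulate_walk_segment(speed, stride_time, duration_s,
                                 sensor_height, fs, noise_sd,
                                 seed = noise_seed,
                                 signal_speed = signal_speed,
                                 orientation = orientation,
                                 location = location, subject = subject,
                                 visit = visit, task = task))
  }

  gap_mean <- mean_bout_duration_s * (1 - walk_fraction) / walk_fraction
  segs <- list()      # each: list(kind, n_samples, speed, stride_time, burst)
  n_used <- 0
  walking <- FALSE    # sessions open with a non-gait segment
  while (n_used < n_total) {
    if (walking) {
      dur <- 5 + stats::rexp(1, rate = 1 / max(mean_bout_duration_s - 5, 1))
      sp <- speed * (1 + rnorm(1, sd = 0.03))
      st <- stride_time * (1 + rnorm(1, sd = 0.03))
      ns <- min(round(dur * fs), n_total - n_used)
      # drop a terminal fragment too short for a stride
      if (ns / fs >= max(2 * st, 5)) {
        segs[[length(segs) + 1]] <- list(kind = "walk", n = ns, speed = sp,
                                         stride_time = st)
      } else {
        segs[[length(segs) + 1]] <- list(kind = "still", n = ns,
                                         burst = FALSE)
      }
    } else {
      dur <- max(2, stats::rexp(1, rate = 1 / max(gap_mean, 2)))
      ns <- min(round(dur * fs), n_total - n_used)
      segs[[length(segs) + 1]] <- list(kind = "still", n = ns,
                                       burst = runif(1) < 0.5)
    }
    n_used <- n_used + segs[[length(segs)]]$n
    walking <- !walking
  }

  sig <- matrix(0, n_total, 3)
  parts <- list()
  at <- 0L
  bout_id <- 0L
  for (sg in segs) {
    if (sg$n < 1) next
    idx <- (at + 1):(at + sg$n)
    if (sg$kind == "walk") {
      bout_id <- bout_id + 1L
      sp_sig <- sg$speed + (signal_speed - speed)  # carry injected bias
      h <- pendulum_excursion(sp_sig, sg$stride_time, sensor_height)
      sig[idx, ] <- walk_signal(sg$n, fs, sp_sig, sg$stride_time, h)
      tr <- walk_truth(sg$speed, sg$stride_time, sg$n / fs,
                       offset = at / fs, bout_id = bout_id)
      parts[[length(parts) + 1]] <- tr
    } else {
      sig[idx, ] <- nongait_signal(sg$n, fs, 0, burst = sg$burst)
    }
    at <- at + sg$n
  }
  if (!is.null(orientation)) sig <- sig %*% t(orientation)
  if (noise_sd > 0) {
    set.seed(noise_seed)
    sig <- sig + matrix(rnorm(3 * n_total, sd = noise_sd), n_total, 3)
  }
  truth <- merge_truth(parts)
  list(
    recording = accel_recording(sig, fs = fs, location = location,
                                subject = subject, visit = visit, task = task,
                                sensor_height = sensor_height),
    truth = truth
  )
}

task_speed <- function(cfg, task, speed_normal) {
  switch(task,
         walk_slow = speed_normal * cfg$speed_multipliers[1],
         walk_fast = speed_normal * cfg$speed_multipliers[2],
         speed_normal)
}

task_duration <- function(cfg, task) {
  switch(task,
         simulated_activities = cfg$lab_session_duration_s,
         outside_activities = cfg$outside_session_duration_s,
         cfg$walk_task_duration_s)
}

is_activity_task <- function(task) {
  task %in% c("simulated_activities", "outside_activities")
}

#' Simulate a complete two-location gait validation study
#'
#' Draws subject-level gait parameters (normal-pace speed, stride time, body
#' height, age), correlates them across visits at `visit_retest_rho`, and
#' generates every recording of the study design: each subject x visit x
#' task, for a chest and a lumbar channel. The two channels share identical
#' ground-truth kinematics and the subject's effective pendulum length (both
#' sensors ride the same trunk, so they see the same centre-of-mass
#' excursion); they differ only by device noise (chest noise =
#' `noise_sd_g * chest_noise_multiplier`), the optional chest speed bias, and
#' their mounting orientation.
#'
#' @param config a [sim_config()].
#' @return an object of class `gait_study`: list with
#'   \describe{
#'     \item{recordings}{named list of [accel_recording] objects, keyed
#'       `subject/visit/task/location`;}
#'     \item{truth}{ground-truth list with the same keys minus location
#'       (truth is shared between channels);}
#'     \item{metadata}{data.frame `subject, visit, task, location, age,
#'       height_m, key`;}
#'     \item{subjects}{per subject x visit drawn parameters;}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  recs <- list()
  truths <- list()
  meta <- list()
  subj_rows <- list()
  leg_fraction <- 0.53   # effective pendulum length / body height

  for (s in seq_len(cfg$n_subjects)) {
    set.seed(substream_seed(cfg$seed, s, 0))
    height <- rnorm(1, cfg$subject_height_mean_m, cfg$subject_height_sd_m)
    height <- min(max(height, 1.45), 2.05)
    age <- sample(seq(cfg$age_range_yr[1], cfg$age_range_yr[2]), 1)
    l <- leg_fraction * height
    z_speed <- rnorm(cfg$n_visits)
    z_stride <- rnorm(cfg$n_visits)
    rho <- cfg$visit_retest_rho
    for (v in seq_len(cfg$n_visits)) {
      # visit > 1 parameters correlate with visit 1 at visit_retest_rho
      zs <- if (v == 1) z_speed[1] else
        rho * z_speed[1] + sqrt(1 - rho^2) * z_speed[v]
      zt <- if (v == 1) z_stride[1] else
        rho * z_stride[1] + sqrt(1 - rho^2) * z_stride[v]
      speed_normal <- max(cfg$speed_mean_mps + cfg$speed_sd_mps * zs, 0.4)
      stride_time <- max(cfg$stride_time_mean_s + cfg$stride_time_sd_s * zt, 0.6)
      subj_rows[[length(subj_rows) + 1]] <- data.frame(
        subject = s, visit = v, age = age, height_m = height,
        pendulum_length_m = l, speed_normal_mps = speed_normal,
        stride_time_s = stride_time
      )
      for (task in cfg$tasks) {
        sp <- task_speed(cfg, task, speed_normal)
        dur <- task_duration(cfg, task)
        tkey <- paste(s, v, task, sep = "/")
        for (loc in c("chest", "lumbar")) {
          noise <- cfg$noise_sd_g *
            if (loc == "chest") cfg$chest_noise_multiplier else 1
          bias <- if (loc == "chest") cfg$chest_bias_mps else 0
          loc_i <- if (loc == "chest") 1L else 2L
          orient <- NULL
          if (cfg$random_orientation) {
            set.seed(substream_seed(cfg$seed, s, v, match(task, cfg$tasks),
                                    loc_i, 1))
            orient <- random_orientation(cfg$max_tilt_deg)
          }
          # session structure is part of the shared physical scene: its seed
          # must not depend on location, only the sensor-noise seed does
          scene_seed <- substream_seed(cfg$seed, s, v, match(task, cfg$tasks))
          noise_seed <- substream_seed(cfg$seed, s, v, match(task, cfg$tasks),
                                       loc_i, 2)
          out <- if (is_activity_task(task)) {
            simulate_activity_session(
              dur, walk_fraction = cfg$walk_fraction,
              mean_bout_duration_s = cfg$mean_bout_duration_s,
              speed = sp, stride_time = stride_time, sensor_height = l,
              sampling_rate = cfg$sampling_rate_hz, noise_sd = noise,
              seed = scene_seed, noise_seed = noise_seed,
              signal_speed = sp + bias,
              orientation = orient, location = loc, subject = s,
              visit = v, task = task)
          } else {
            simulate_walk_segment(
              sp, stride_time, dur, sensor_height = l,
              sampling_rate = cfg$sampling_rate_hz, noise_sd = noise,
              seed = noise_seed, signal_speed = sp + bias,
              orientation = orient, location = loc, subject = s,
              visit = v, task = task)
          }
          key <- paste(tkey, loc, sep = "/")
          recs[[key]] <- out$recording
          if (loc == "lumbar") truths[[tkey]] <- out$truth
          meta[[length(meta) + 1]] <- data.frame(
            subject = s, visit = v, task = task, location = loc,
            age = age, height_m = height, key = key
          )
        }
      }
    }
  }
  structure(list(
    recordings = recs,
    truth = truths,
    metadata = do.call(rbind, meta),
    subjects = do.call(rbind, subj_rows),
    config = cfg
  ), class = "gait_study")
}

#' @export
print.gait_study <- function(x, ...) {
  cat(sprintf("gait_study: %d recordings (%d subjects x %d visits x %d tasks x 2 locations)\n",
              length(x$recordings), x$config$n_subjects, x$config$n_visits,
              length(x$config$tasks)))
  invisible(x)
}

#' Fragment ground-truth bouts to emulate device-dependent bout splitting
#'
#' Takes a table of per-subject walking bouts and, with probability
#' `split_prob`, splits each bout in two at a uniform point, discarding a
#' short `gap_s` of walking at the split. Splitting increases the bout count
#' and shortens the mean bout, while total walking time and step count change
#' only by the small discarded gaps — the signature of a device that chops
#' long bouts into consecutive shorter ones.
#'
#' @param bouts data.frame with columns `subject`, `duration_s`, `steps`.
#' @param split_prob probability that a bout is split.
#' @param gap_s walking time lost at each split (s).
#' @param seed integer seed.
#' @return data.frame with the same columns, after fragmentation.
#' @seealso [compare_bout_stats()]
#' @export
fragment_bouts <- function(bouts, split_prob = 0.3, gap_s = 1, seed = 1) {
  stopifnot(all(c("subject", "duration_s", "steps") %in% names(bouts)))
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(bouts))) {
    b <- bouts[i, ]
    if (runif(1) < split_prob && b$duration_s > 2 * gap_s + 6) {
      cut <- runif(1, 3, b$duration_s - gap_s - 3)
      d1 <- cut
      d2 <- b$duration_s - cut - gap_s
      rate <- b$steps / b$duration_s
      out[[length(out) + 1]] <- data.frame(
        subject = rep(b$subject, 2),
        duration_s = c(d1, d2),
        steps = round(rate * c(d1, d2))
      )
    } else {
      out[[length(out) + 1]] <- b[, c("subject", "duration_s", "steps")]
    }
  }
  do.call(rbind, out)
}
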