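# shared fixture builders; everything is generated in code at test time

# fraction of reference events matched by a detected event within tol
match_rate <- function(detected, reference, tol_s = 0.05) {
  if (!length(reference)) return(NA_real_)
  if (!length(detected)) return(0)
  mean(vapply(reference, function(t) min(abs(detected - t)) <= tol_s,
              logical(1)))
}

# per-matched-event absolute timing error (s)
match_errors <- function(detected, reference) {
  vapply(reference, function(t) min(abs(detected - t)), numeric(1))
}

# small walking recording with aligned vertical channel and truth
quick_walk <- function(speed = 1.2, stride_time = 1.0, duration = 20,
                       l = 0.9, fs = 128, noise_sd = 0, seed = 1,
                       orientation = NULL) {
  seg <- simulate_walk_segment(speed, stride_time, duration,
                               sensor_height = l, sampling_rate = fs,
                               noise_sd = noise_sd, seed = seed,
                               orientation = orientation)
  seg$aligned <- estimate_vertical_axis(seg$recording)
  seg
}

# a tiny two-visit study configuration for orchestration tests
tiny_config <- function(seed = 5, ...) {
  sim_config(n_subjects = 5, walk_task_duration_s = 15,
             lab_session_duration_s = 60, outside_session_duration_s = 120,
             seed = seed, ...)
}

# endpoint-level study table with known effects, for model tests
model_table <- function(n_subjects = 20, devices = c("chest", "lumbar"),
                        tasks = c("walk_slow", "walk_fast"),
                        device_effects = setNames(rep(0, length(devices)),
                                                  devices),
                        task_effects = setNames(seq(0, 0.3,
                                                    length.out = length(tasks)),
                                                tasks),
                        subject_sd = 0.1, sigma = 0.05, seed = 1) {
  set.seed(seed)
  tab <- expand.grid(subject = seq_len(n_subjects), device = devices,
                     task = tasks, stringsAsFactors = FALSE)
  subj <- rnorm(n_subjects, 0, subject_sd)
  age <- sample(25:61, n_subjects, replace = TRUE)
  tab$age <- age[tab$subject]
  tab$value <- 1.2 + subj[tab$subject] +
    unname(task_effects[tab$task]) + unname(device_effects[tab$device]) +
    rnorm(nrow(tab), 0, sigma)
  tab
}
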