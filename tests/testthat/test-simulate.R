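test_that("standing produces a constant 1 g vertical channel and no events", {
  seg <- simulate_walk_segment(0, 1.0, 10, sensor_height = 1,
                               sampling_rate = 128, noise_sd = 0, seed = 1)
  expect_equal(unname(seg$recording$accel[, 3]),
               rep(1, nrow(seg$recording$accel)))
  expect_length(seg$truth$initial_contacts, 0)
  expect_equal(seg$truth$step_count, 0L)
})

test_that("step count follows 2 * duration / stride_time", {
  seg <- simulate_walk_segment(1.2, 1.0, 10, sensor_height = 1,
                               sampling_rate = 128, noise_sd = 0, seed = 1)
  expect_equal(seg$truth$step_count, 20L)
  expect_equal(nrow(seg$truth$strides), 9L)  # same-foot strides among 20 steps
})

test_that("excursion inversion matches the closed form", {
  h <- pendulum_excursion(1.2, 1.0, 1.0)
  expect_equal(h, 1 - sqrt(1 - 0.09), tolerance = 1e-12)
  # substituting h back recovers the step length
  expect_equal(2 * sqrt(2 * 1 * h - h^2), 0.6, tolerance = 1e-12)
  expect_error(pendulum_excursion(10, 2, 0.5), "infeasible")
})

test_that("a walking duration below one stride is rejected", {
  expect_error(simulate_walk_segment(1.2, 1.0, 0.5, sensor_height = 1),
               "one stride")
})

test_that("ground-truth closure: stride length = speed x stride time", {
  seg <- simulate_walk_segment(1.31, 0.97, 25, sensor_height = 0.9,
                               sampling_rate = 128, noise_sd = 0.02, seed = 3)
  st <- seg$truth$strides
  expect_equal(st$stride_length_m, st$gait_speed_mps * st$stride_time_s)
  expect_equal(st$cadence_spm, 120 / st$stride_time_s)
})

test_that("double-integrating the vertical channel recovers the excursion", {
  seg <- quick_walk(1.3, 1.0, duration = 30, l = 0.9, noise_sd = 0)
  h_true <- pendulum_excursion(1.3, 1.0, 0.9)
  ev <- gait_events(seg$truth$initial_contacts)
  exc <- compute_vertical_excursion(seg$aligned$accel[, 1], 128, events = ev)
  expect_lt(abs(median(exc, na.rm = TRUE) - h_true) / h_true, 0.02)
})

test_that("every ground-truth event lies inside a ground-truth bout", {
  ses <- simulate_activity_session(240, walk_fraction = 0.5,
                                   mean_bout_duration_s = 25, speed = 1.2,
                                   stride_time = 1.0, sensor_height = 0.9,
                                   sampling_rate = 128, noise_sd = 0.02,
                                   seed = 9)
  tb <- ses$truth$bouts
  for (t in c(ses$truth$initial_contacts, ses$truth$final_contacts)) {
    expect_true(any(t > tb$start_s & t < tb$end_s))
  }
  # bouts disjoint and sorted, contacts increasing
  expect_true(all(diff(tb$start_s) > 0))
  expect_true(all(tb$start_s[-1] >= tb$end_s[-nrow(tb)]))
  expect_true(all(diff(ses$truth$initial_contacts) > 0))
})

test_that("activity sessions hit the target walking fraction on average", {
  # Monte-Carlo over seeds: realized total walking time within 5% of target
  fracs <- vapply(1:40, function(s) {
    ses <- simulate_activity_session(600, walk_fraction = 0.5,
                                     mean_bout_duration_s = 30, speed = 1.25,
                                     stride_time = 1.05, sensor_height = 0.9,
                                     sampling_rate = 32, noise_sd = 0,
                                     seed = s)
    sum(ses$truth$bouts$end_s - ses$truth$bouts$start_s) / 600
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.05)
})

test_that("walk_fraction near 1 yields a single continuous bout", {
  ses <- simulate_activity_session(60, walk_fraction = 0.995,
                                   mean_bout_duration_s = 30, speed = 1.2,
                                   stride_time = 1.0, sensor_height = 0.9,
                                   sampling_rate = 64, noise_sd = 0, seed = 2)
  expect_equal(nrow(ses$truth$bouts), 1L)
  expect_equal(ses$truth$bouts$start_s, 0)
  expect_equal(ses$truth$bouts$end_s, 60)
})

test_that("the study bundle has the full design and is seed-deterministic", {
  cfg <- sim_config(n_subjects = 2, n_visits = 2,
                    tasks = c("walk_slow", "walk_normal"),
                    walk_task_duration_s = 10, seed = 7)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_length(st1$recordings, 2 * 2 * 2 * 2)
  expect_identical(st1$recordings, st2$recordings)
  expect_identical(st1$truth, st2$truth)
})

test_that("adding subjects does not perturb existing subjects' recordings", {
  cfg2 <- sim_config(n_subjects = 2, n_visits = 1, tasks = "walk_normal",
                     walk_task_duration_s = 10, seed = 7)
  cfg3 <- sim_config(n_subjects = 3, n_visits = 1, tasks = "walk_normal",
                     walk_task_duration_s = 10, seed = 7)
  s2 <- simulate_study(cfg2)
  s3 <- simulate_study(cfg3)
  for (key in names(s2$recordings)) {
    expect_identical(s2$recordings[[key]], s3$recordings[[key]])
  }
})

test_that("chest and lumbar are bit-identical without noise, bias or tilt", {
  cfg <- sim_config(n_subjects = 2, n_visits = 1,
                    tasks = c("walk_normal", "simulated_activities"),
                    walk_task_duration_s = 10, lab_session_duration_s = 45,
                    noise_sd_g = 0, chest_bias_mps = 0,
                    random_orientation = FALSE, seed = 13)
  st <- simulate_study(cfg)
  for (key in names(st$truth)) {
    ch <- st$recordings[[paste0(key, "/chest")]]
    lu <- st$recordings[[paste0(key, "/lumbar")]]
    expect_identical(ch$accel, lu$accel)
  }
})

test_that("visit-2 parameters correlate with visit 1 at the configured rho", {
  cfg <- sim_config(n_subjects = 150, n_visits = 2, tasks = "walk_normal",
                    walk_task_duration_s = 10, visit_retest_rho = 0.8,
                    seed = 21)
  # draw parameters only: use the subjects table of a study built on a
  # cheap sampling rate
  cfg$sampling_rate_hz <- 4
  st <- simulate_study(cfg)
  wide <- reshape(st$subjects[c("subject", "visit", "speed_normal_mps")],
                  direction = "wide", idvar = "subject", timevar = "visit")
  r <- cor(wide[, 2], wide[, 3])
  expect_lt(abs(r - 0.8), 0.12)
})

test_that("fragmenting bouts preserves walking time up to the split gaps", {
  bouts <- data.frame(subject = rep(1:5, each = 4),
                      duration_s = rep(40, 20), steps = rep(70, 20))
  frag <- fragment_bouts(bouts, split_prob = 1, gap_s = 1, seed = 3)
  expect_equal(nrow(frag), 40)
  tot0 <- sum(bouts$duration_s)
  expect_equal(sum(frag$duration_s), tot0 - 20)  # one 1 s gap per split
  expect_true(all(frag$duration_s < 40))
})
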