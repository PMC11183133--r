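test_that("recording CSV round-trips through the on-disk format", {
  seg <- simulate_walk_segment(1.2, 1.0, 5, sensor_height = 0.9,
                               sampling_rate = 128, noise_sd = 0.02, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(seg$recording, f)
  back <- read_recording_csv(f, location = "chest")
  expect_equal(back$fs, 128, tolerance = 1e-6)
  expect_equal(unname(back$accel), unname(seg$recording$accel),
               tolerance = 1e-5)
})

test_that("ground truth serialises to JSON and config from YAML", {
  seg <- simulate_walk_segment(1.2, 1.0, 5, sensor_height = 0.9,
                               sampling_rate = 128, noise_sd = 0, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth_json(seg$truth, f)
  gt <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(gt$step_count, 10)
  expect_equal(gt$initial_contacts, seg$truth$initial_contacts)

  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 3", "n_visits: 1", "seed: 42",
               "tasks: [walk_normal]"), y)
  cfg <- read_sim_config(y)
  expect_equal(cfg$n_subjects, 3L)
  expect_equal(cfg$seed, 42L)
  writeLines(c("n_subjects: 3", "not_a_key: 1"), y)
  expect_error(read_sim_config(y), "unknown config keys")
})

test_that("input validation flags gaps, units and missing metadata", {
  seg <- simulate_walk_segment(1.2, 1.0, 10, sensor_height = 0.9,
                               sampling_rate = 128, noise_sd = 0.01, seed = 2,
                               subject = 1, visit = 1, task = "walk_normal")
  expect_equal(nrow(validate_inputs(seg$recording)), 0L)

  gap <- seg$recording
  gap$time[641:length(gap$time)] <- gap$time[641:length(gap$time)] + 2
  iss <- validate_inputs(gap)
  expect_true("sampling_gap" %in% iss$issue)
  expect_match(iss$detail[iss$issue == "sampling_gap"], "gap of 2")

  ms2 <- seg$recording
  ms2$accel <- ms2$accel * 9.80665  # m/s^2 mislabelled as g
  iss2 <- validate_inputs(ms2)
  expect_true("unit_suspect" %in% iss2$issue)

  anon <- simulate_walk_segment(1.2, 1.0, 10, sensor_height = 0.9,
                                sampling_rate = 128, noise_sd = 0.01,
                                seed = 2)$recording
  expect_true("metadata_missing" %in% validate_inputs(anon)$issue)
})

test_that("the demo study runs end to end and is byte-deterministic", {
  cfg <- tiny_config(seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  rep1 <- run_study(cfg, pipeline_config(), out_dir = d1)
  rep2 <- run_study(cfg, pipeline_config(), out_dir = d2)

  # all four endpoint agreement panels present
  expect_true(all(c("gait_speed", "cadence", "stride_time", "stride_length")
                  %in% rep1$agreement$endpoint))
  expect_true(file.exists(file.path(d1, "report", "report.md")))
  expect_true(file.exists(file.path(d1, "report", "provenance.json")))

  files <- list.files(d1, recursive = TRUE, pattern = "\\.csv$")
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})
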