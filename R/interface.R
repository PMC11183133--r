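# Orchestration: simulate -> extract -> agree -> model in one reproducible
# run directory, plus input validation and config/ground-truth serialization.

#' Read a simulation configuration from YAML
#'
#' The YAML keys mirror the arguments of [sim_config()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}

#' Write ground truth for one recording as JSON
#'
#' @param truth a ground-truth list (see [simulate_walk_segment()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(initial_contacts = truth$initial_contacts,
         final_contacts = truth$final_contacts,
         bouts = truth$bouts,
         step_count = truth$step_count,
         strides = truth$strides),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Validate raw recordings before processing
#'
#' Report-only checks: uniform sampling (gaps flagged with their timestamp),
#' unit plausibility (a mean vector magnitude near 9.8 suggests m/s^2
#' mislabelled as g), and metadata completeness. Inputs are never mutated.
#'
#' @param recordings a list of [accel_recording] objects, or a single one.
#' @return data.frame of issues (`recording`, `issue`, `detail`); zero rows
#'   when everything is well-formed.
#' @export
validate_inputs <- function(recordings) {
  if (inherits(recordings, "accel_recording"))
    recordings <- list(recordings)
  issues <- list()
  add <- function(rec_id, issue, detail) {
    issues[[length(issues) + 1]] <<- data.frame(
      recording = rec_id, issue = issue, detail = detail)
  }
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    rec_id <- names(recordings)[i] %||% as.character(i)
    dt <- diff(rec$time)
    step <- 1 / rec$fs
    gaps <- which(dt > step * 1.5 + 1e-9)
    for (g in gaps) {
      add(rec_id, "sampling_gap",
          sprintf("gap of %.3f s at t = %.3f s", dt[g], rec$time[g]))
    }
    if (any(abs(dt - step) > 1e-6 & dt <= step * 1.5)) {
      add(rec_id, "non_uniform_sampling", "sample spacing varies > 1e-6 s")
    }
    mag <- sqrt(sum(colMeans(rec$accel)^2))
    if (mag > 5) {
      add(rec_id, "unit_suspect",
          sprintf("mean |a| = %.2f; looks like m/s^2 mislabelled as g", mag))
    } else if (abs(mag - 1) > 0.2) {
      add(rec_id, "gravity_magnitude",
          sprintf("mean |a| = %.2f g; expect ~1 g over still periods", mag))
    }
    for (field in c("subject", "visit", "task")) {
      if (is.na(rec[[field]] %||% NA))
        add(rec_id, "metadata_missing", field)
    }
  }
  if (!length(issues)) {
    return(data.frame(recording = character(0), issue = character(0),
                      detail = character(0)))
  }
  do.call(rbind, issues)
}

write_csv_fixed <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full study: simulate, extract, agree, model
#'
#' Generates a synthetic study, runs the extraction pipeline on every
#' recording, aggregates endpoints per location, compares chest against
#' lumbar (agreement tables, mixed models, bout statistics for the
#' outside-lab task), and persists every intermediate as CSV in a run
#' directory: `raw/`, `strides/`, `endpoints/`, `agreement/`, `models/`,
#' `report/`. Deterministic given the configuration seed: re-running with
#' the same config yields byte-identical CSVs.
#'
#' @param config a [sim_config()].
#' @param pipeline a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @param write_raw also persist every raw recording CSV and ground-truth
#'   JSON under `raw/` (large; default writes metadata only).
#' @return object of class `study_report`: list with `agreement`,
#'   `models` (ANOVA + contrast tables per endpoint), `bout_comparison`,
#'   `endpoints` (per location), `provenance`; all also on disk.
#' @export
run_study <- function(config = sim_config(), pipeline = pipeline_config(),
                      out_dir, write_raw = FALSE) {
  stopifnot(inherits(config, "sim_config"),
            inherits(pipeline, "pipeline_config"))
  dirs <- file.path(out_dir, c("raw", "strides", "endpoints", "agreement",
                               "models", "report"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)

  study <- simulate_study(config)
  write_csv_fixed(study$metadata, file.path(out_dir, "raw", "metadata.csv"))
  if (write_raw) {
    for (key in names(study$recordings)) {
      f <- file.path(out_dir, "raw", paste0(gsub("/", "_", key), ".csv"))
      write_recording_csv(study$recordings[[key]], f)
    }
    for (key in names(study$truth)) {
      f <- file.path(out_dir, "raw",
                     paste0("truth_", gsub("/", "_", key), ".json"))
      write_ground_truth_json(study$truth[[key]], f)
    }
  }

  # --- extraction ---------------------------------------------------------
  extractions <- lapply(study$recordings, extract_gait, config = pipeline)
  strides <- do.call(rbind, lapply(extractions, function(e) e$strides))
  rownames(strides) <- NULL
  write_csv_fixed(
    strides[c("subject", "visit", "task", "location", "bout",
              "start_s", "stride_time_s", "stride_length_m",
              "gait_speed_mps", "cadence_spm")],
    file.path(out_dir, "strides", "strides.csv"))

  bout_rows <- do.call(rbind, lapply(names(extractions), function(key) {
    e <- extractions[[key]]
    if (!nrow(e$bouts)) return(NULL)
    cbind(key = key, e$bouts)
  }))
  if (!is.null(bout_rows))
    write_csv_fixed(bout_rows, file.path(out_dir, "strides", "bouts.csv"))

  # --- endpoints ----------------------------------------------------------
  eps <- aggregate_endpoints(strides)
  write_csv_fixed(eps$per_visit,
                  file.path(out_dir, "endpoints", "per_visit.csv"))
  write_csv_fixed(eps$cross_visit,
                  file.path(out_dir, "endpoints", "cross_visit.csv"))

  # --- agreement: chest (test) vs lumbar (reference) ----------------------
  cx <- eps$cross_visit
  chest <- cx[cx$location == "chest", c("subject", "task", "endpoint", "value")]
  lumbar <- cx[cx$location == "lumbar", c("subject", "task", "endpoint", "value")]
  agreement <- agreement_summary(chest, lumbar)
  write_csv_fixed(agreement, file.path(out_dir, "agreement", "chest_vs_lumbar.csv"))

  # --- mixed models per endpoint (walking tasks) --------------------------
  walk_tasks <- intersect(c("walk_slow", "walk_normal", "walk_fast"),
                          unique(cx$task))
  ages <- unique(study$metadata[c("subject", "age")])
  long <- merge(cx, ages, by = "subject")
  names(long)[names(long) == "location"] <- "device"
  models <- list()
  if (length(walk_tasks) >= 2) {
    for (ep in c("gait_speed", "cadence", "stride_time", "stride_length")) {
      tab <- long[long$task %in% walk_tasks & long$endpoint == ep, ]
      fit <- tryCatch(
        suppressWarnings(fit_device_task_model(tab, covariate = "age")),
        error = function(e) NULL)
      if (is.null(fit)) next
      models[[ep]] <- fit
      write_csv_fixed(cbind(term = rownames(fit$anova), fit$anova),
                      file.path(out_dir, "models", paste0(ep, "_anova.csv")))
      write_csv_fixed(fit$contrasts,
                      file.path(out_dir, "models", paste0(ep, "_contrasts.csv")))
    }
  }

  # --- bout statistics (outside-lab), chest vs lumbar ---------------------
  bout_comparison <- NULL
  if ("outside_activities" %in% config$tasks) {
    bs <- bout_stats_by_subject(extractions, study$metadata, pipeline,
                                task = "outside_activities")
    if (!is.null(bs) && length(unique(bs$location)) == 2) {
      write_csv_fixed(bs, file.path(out_dir, "strides", "bout_stats.csv"))
      bout_comparison <- compare_bout_stats(
        bs[bs$location == "chest", ], bs[bs$location == "lumbar", ])
      write_csv_fixed(bout_comparison,
                      file.path(out_dir, "models", "bout_comparison.csv"))
    }
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("chestgait")),
    seed = config$seed,
    n_subjects = config$n_subjects,
    n_visits = config$n_visits,
    tasks = config$tasks,
    pipeline = list(
      window_s = pipeline$window_s,
      integration_highpass_hz = pipeline$integration_highpass_hz,
      cwt_scale_factor = pipeline$cwt_scale_factor,
      min_bout_duration_s = pipeline$min_bout_duration_s,
      min_bout_cycles = pipeline$min_bout_cycles
    )
  )
  jsonlite::write_json(provenance, file.path(out_dir, "report", "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report_md(agreement, models, bout_comparison,
                  file.path(out_dir, "report", "report.md"))

  structure(list(
    agreement = agreement,
    models = models,
    bout_comparison = bout_comparison,
    endpoints = eps,
    strides = strides,
    extractions = extractions,
    study = study,
    provenance = provenance
  ), class = "study_report")
}

# per-subject (visit-averaged) bout statistics for one task, after the
# duration/cycle filter
bout_stats_by_subject <- function(extractions, metadata, pipeline, task) {
  meta <- metadata[metadata$task == task, ]
  if (!nrow(meta)) return(NULL)
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    e <- extractions[[meta$key[i]]]
    if (is.null(e)) return(NULL)
    fb <- filter_bouts(e$bouts,
                       min_duration_s = pipeline$min_bout_duration_s,
                       min_cycles = pipeline$min_bout_cycles)
    cbind(subject = meta$subject[i], visit = meta$visit[i],
          location = meta$location[i], compute_bout_stats(fb$retained))
  })
  per_visit <- do.call(rbind, rows)
  if (is.null(per_visit)) return(NULL)
  out <- aggregate(per_visit[c("mean_bout_duration_s", "total_walking_time_s",
                               "n_bouts", "total_steps")],
                   by = per_visit[c("subject", "location")], FUN = mean)
  out
}

write_report_md <- function(agreement, models, bout_comparison, path) {
  lines <- c("# Study report", "",
             "## Chest vs lumbar agreement", "")
  if (nrow(agreement)) {
    lines <- c(lines, utils::capture.output(
      print.data.frame(agreement, digits = 3, row.names = FALSE)))
  }
  if (length(models)) {
    lines <- c(lines, "", "## Mixed-model device effects", "")
    for (ep in names(models)) {
      dev_row <- grep("^device$", rownames(models[[ep]]$anova))
      p <- if (length(dev_row)) models[[ep]]$anova[dev_row, "Pr(>F)"] else NA
      lines <- c(lines, sprintf("- %s: device effect p = %.3g%s", ep, p,
                                if (models[[ep]]$singular) " (singular fit)" else ""))
    }
  }
  if (!is.null(bout_comparison)) {
    lines <- c(lines, "", "## Bout statistics, chest vs lumbar (paired t)", "")
    lines <- c(lines, utils::capture.output(
      print.data.frame(bout_comparison, digits = 3, row.names = FALSE)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  cat(sprintf("  %d recordings, %d strides\n",
              length(x$extractions), nrow(x$strides)))
  cat(sprintf("  agreement rows: %d; models: %s\n", nrow(x$agreement),
              paste(names(x$models), collapse = ", ")))
  invisible(x)
}
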