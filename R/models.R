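# Mixed-effects device-comparison models: endpoint ~ device * task + age
# with a subject random intercept, REML, type-III F tests (Satterthwaite
# denominator df) and least-squares-mean device contrasts per task level.

#' Fit the device-by-task mixed model for one endpoint
#'
#' Fits `value ~ device * task + age + (1 | subject)` by REML with
#' sum-to-zero factor coding, reports the type-III ANOVA F table
#' (Satterthwaite denominator df) and the least-squares-mean pairwise device
#' contrasts at each task level. Errors between devices are read off the
#' device contrasts; the model is fit on the endpoint values themselves.
#'
#' @param table long-format data.frame with columns `subject`, `device`,
#'   `value`, the crossing factor (default `task`) and optionally the
#'   covariate column (default `age`; dropped from the formula when absent).
#'   If an `endpoint` column is present, `endpoint` selects the rows to fit.
#' @param endpoint endpoint name to filter on, when `table` stacks several.
#' @param factor_name name of the crossing fixed factor (`"task"` or
#'   `"environment"`).
#' @param covariate covariate column name, or `NULL` for none.
#' @param adjust multiplicity adjustment for the post-hoc contrasts
#'   (`"none"` by default; `"holm"` or `"tukey"` available).
#' @return object of class `device_model`: list with `model` (the fitted
#'   `lmerModLmerTest`), `anova` (type-III F table), `contrasts` (data.frame
#'   `contrast, <factor>, estimate, se, df, lower, upper, t, p`), `varcomp`
#'   (variance components), `singular` (logical), `formula`.
#' @export
fit_device_task_model <- function(table, endpoint = NULL,
                                  factor_name = "task", covariate = "age",
                                  adjust = "none") {
  df <- as.data.frame(table)
  if (!is.null(endpoint) && "endpoint" %in% names(df))
    df <- df[df$endpoint == endpoint, ]
  need <- c("subject", "device", "value", factor_name)
  stopifnot(all(need %in% names(df)))
  if (!is.null(covariate) && !covariate %in% names(df)) covariate <- NULL
  keep <- c(need, covariate)
  df <- df[complete.cases(df[keep]), keep]
  df$subject <- factor(df$subject)
  df$device <- factor(df$device)
  df[[factor_name]] <- factor(df[[factor_name]])
  if (nlevels(df$device) < 2) stop("need at least 2 devices")
  if (nlevels(df[[factor_name]]) < 2)
    stop(sprintf("need at least 2 levels of '%s'", factor_name))
  if (nlevels(df$subject) < 5) stop("need at least 5 subjects")

  rhs <- paste0("device * ", factor_name,
                if (!is.null(covariate)) paste0(" + ", covariate) else "",
                " + (1 | subject)")
  form <- as.formula(paste("value ~", rhs))
  contr <- list(device = "contr.sum")
  contr[[factor_name]] <- "contr.sum"
  mod <- lmerTest::lmer(form, data = df, REML = TRUE, contrasts = contr)
  singular <- lme4::isSingular(mod)
  if (singular)
    warning("singular random-effects fit (subject variance ~ 0); ",
            "fixed effects remain valid, flagged in the result")
  aov3 <- anova(mod, type = 3, ddf = "Satterthwaite")
  emm <- emmeans::emmeans(mod, specs = as.formula(paste("~ device |",
                                                        factor_name)),
                          lmer.df = "satterthwaite")
  ctr <- summary(emmeans::contrast(emm, method = "pairwise", adjust = adjust),
                 infer = c(TRUE, TRUE))
  ctr <- as.data.frame(ctr)
  names(ctr)[names(ctr) == "lower.CL"] <- "lower"
  names(ctr)[names(ctr) == "upper.CL"] <- "upper"
  names(ctr)[names(ctr) == "p.value"] <- "p"
  names(ctr)[names(ctr) == "t.ratio"] <- "t"
  names(ctr)[names(ctr) == "SE"] <- "se"
  vc <- as.data.frame(lme4::VarCorr(mod))[, c("grp", "vcov", "sdcor")]

  structure(list(
    model = mod,
    anova = as.data.frame(aov3),
    contrasts = ctr,
    varcomp = vc,
    singular = singular,
    formula = form,
    factor_name = factor_name
  ), class = "device_model")
}

#' @export
print.device_model <- function(x, digits = 3, ...) {
  cat("Mixed-effects device comparison:",
      deparse(x$formula), "\n")
  if (x$singular) cat("  (singular random-effects fit)\n")
  cat("\nType-III ANOVA (Satterthwaite df):\n")
  print(round(x$anova, digits))
  cat("\nLeast-squares-mean device contrasts:\n")
  print.data.frame(x$contrasts, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Post-hoc pairwise device contrasts from a fitted device model
#'
#' Least-squares-mean differences for each device pair at each level of the
#' crossing factor, with t-based CIs on Satterthwaite df. No multiplicity
#' correction by default; `"holm"` or `"tukey"` are available.
#'
#' @param fit a `device_model` from [fit_device_task_model()].
#' @param adjust multiplicity adjustment passed to emmeans.
#' @param conf confidence level.
#' @return data.frame of contrasts (one row per device pair x factor level).
#' @export
posthoc_contrasts <- function(fit, adjust = "none", conf = 0.95) {
  stopifnot(inherits(fit, "device_model"))
  emm <- emmeans::emmeans(fit$model,
                          specs = as.formula(paste("~ device |",
                                                   fit$factor_name)),
                          lmer.df = "satterthwaite")
  ctr <- summary(emmeans::contrast(emm, method = "pairwise", adjust = adjust),
                 infer = c(TRUE, TRUE), level = conf)
  as.data.frame(ctr)
}

#' Fit the device-by-environment mixed model
#'
#' As [fit_device_task_model()] with the crossing factor `environment`
#' (in-lab vs outside-lab) instead of `task`.
#'
#' @inheritParams fit_device_task_model
#' @return a `device_model`.
#' @export
fit_environment_model <- function(table, endpoint = NULL, covariate = "age",
                                  adjust = "none") {
  fit_device_task_model(table, endpoint = endpoint,
                        factor_name = "environment", covariate = covariate,
                        adjust = adjust)
}

#' Paired comparison of walking-bout statistics between devices
#'
#' Two-sided paired t-tests on the per-subject bout statistics (mean bout
#' duration, total walking time, number of bouts, total steps) of two
#' devices. When every within-subject difference is exactly zero the test
#' degenerates and `p = 1` with a zero mean difference is reported.
#'
#' @param test,ref data.frames with a `subject` column and the metric
#'   columns `mean_bout_duration_s`, `total_walking_time_s`, `n_bouts`,
#'   `total_steps` (one row per subject, visit-averaged).
#' @param metrics metric columns to compare.
#' @return data.frame, one row per metric: `metric, n, mean_diff, ci_lower,
#'   ci_upper, t, df, p`.
#' @export
compare_bout_stats <- function(test, ref,
                               metrics = c("mean_bout_duration_s",
                                           "total_walking_time_s",
                                           "n_bouts", "total_steps")) {
  stopifnot("subject" %in% names(test), "subject" %in% names(ref))
  m <- merge(test, ref, by = "subject", suffixes = c("_test", "_ref"))
  if (nrow(m) < 3) stop("paired comparison requires at least 3 subjects")
  rows <- lapply(metrics, function(met) {
    d <- m[[paste0(met, "_test")]] - m[[paste0(met, "_ref")]]
    d <- d[!is.na(d)]
    n <- length(d)
    if (all(d == 0)) {
      return(data.frame(metric = met, n = n, mean_diff = 0,
                        ci_lower = 0, ci_upper = 0,
                        t = 0, df = n - 1, p = 1))
    }
    if (sd(d) == 0) {
      # deterministic nonzero shift: zero within-pair variance
      return(data.frame(metric = met, n = n, mean_diff = mean(d),
                        ci_lower = mean(d), ci_upper = mean(d),
                        t = sign(mean(d)) * Inf, df = n - 1, p = 0))
    }
    tt <- t.test(d)
    data.frame(metric = met, n = n, mean_diff = unname(tt$estimate),
               ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, rows)
}
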