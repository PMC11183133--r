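test_that("an injected device offset is recovered by the contrasts", {
  tab <- model_table(device_effects = c(chest = -0.10, lumbar = 0), seed = 2)
  fit <- fit_device_task_model(tab)
  ctr <- fit$contrasts
  expect_equal(nrow(ctr), 2L)  # one pair x two tasks
  for (i in seq_len(nrow(ctr))) {
    expect_lt(abs(ctr$estimate[i] - (-0.10)), 0.03)
    expect_true(ctr$lower[i] <= -0.10 && -0.10 <= ctr$upper[i])
  }
  dev_p <- fit$anova["device", "Pr(>F)"]
  expect_lt(dev_p, 1e-6)
})

test_that("equal device means give near-zero contrasts and large p", {
  tab <- model_table(seed = 3)
  # make devices exactly equal within subject x task
  half <- tab[tab$device == "chest", ]
  tab$value[tab$device == "lumbar"] <- half$value
  fit <- suppressWarnings(fit_device_task_model(tab))
  expect_lt(max(abs(fit$contrasts$estimate)), 1e-10)
  expect_gt(min(fit$contrasts$p), 0.99)
})

test_that("three devices and two tasks give six contrast rows", {
  tab <- model_table(devices = c("chest", "lumbar", "mat"),
                     device_effects = c(chest = 0, lumbar = 0, mat = 0.05),
                     seed = 4)
  fit <- fit_device_task_model(tab)
  expect_equal(nrow(fit$contrasts), 6L)
})

test_that("degenerate designs are rejected", {
  tab <- model_table(n_subjects = 2, seed = 5)
  expect_error(fit_device_task_model(tab), "at least 5 subjects")
  one_dev <- model_table(seed = 6)
  one_dev <- one_dev[one_dev$device == "chest", ]
  expect_error(fit_device_task_model(one_dev), "2 devices")
})

test_that("zero subject variance reduces REML fixed effects to OLS", {
  tab <- model_table(subject_sd = 0, sigma = 0.05, seed = 7)
  fit <- suppressWarnings(fit_device_task_model(tab, covariate = NULL))
  expect_true(fit$singular)
  ols <- lm(value ~ device * task, data = transform(
    tab, device = C(factor(device), "contr.sum"),
    task = C(factor(task), "contr.sum")))
  expect_equal(unname(lme4::fixef(fit$model)), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("ANOVA p-values are invariant to factor level relabelling", {
  tab <- model_table(device_effects = c(chest = -0.05, lumbar = 0), seed = 8)
  fit1 <- fit_device_task_model(tab)
  tab2 <- tab
  tab2$device <- factor(tab2$device, levels = c("lumbar", "chest"))
  tab2$task <- factor(tab2$task, levels = c("walk_fast", "walk_slow"))
  fit2 <- fit_device_task_model(tab2)
  expect_equal(fit1$anova[, "Pr(>F)"], fit2$anova[, "Pr(>F)"],
               tolerance = 1e-8)
})

test_that("the environment model mirrors the task model", {
  tab <- model_table(tasks = c("in_lab", "outside"),
                     task_effects = c(in_lab = 0, outside = 0.05), seed = 9)
  names(tab)[names(tab) == "task"] <- "environment"
  fit <- fit_environment_model(tab)
  expect_s3_class(fit, "device_model")
  env_p <- fit$anova["environment", "Pr(>F)"]
  expect_lt(env_p, 0.05)
  # model matrix has full rank: 2 devices x 2 environments + age
  expect_equal(length(lme4::fixef(fit$model)), 5L)
})

test_that("identical bout statistics give p = 1; exact shifts give p ~ 0", {
  bs <- data.frame(subject = 1:20, mean_bout_duration_s = runif(20, 20, 40),
                   total_walking_time_s = runif(20, 300, 600),
                   n_bouts = rpois(20, 12), total_steps = rpois(20, 900))
  same <- compare_bout_stats(bs, bs)
  expect_true(all(same$p == 1))
  expect_true(all(same$mean_diff == 0))
  shifted <- bs
  shifted$mean_bout_duration_s <- bs$mean_bout_duration_s - 5
  cmp <- compare_bout_stats(shifted, bs)
  row <- cmp[cmp$metric == "mean_bout_duration_s", ]
  expect_equal(row$mean_diff, -5)
  expect_lt(row$p, 1e-10)
})

test_that("fragmentation shows more, shorter bouts but similar totals", {
  set.seed(10)
  n <- 20
  bouts <- do.call(rbind, lapply(1:n, function(s) {
    k <- 6 + rpois(1, 4)
    dur <- 10 + stats::rexp(k, 1 / 25)
    data.frame(subject = s, duration_s = dur,
               steps = round(dur * 110 / 60))
  }))
  # each device measures bout durations/steps with ~4% per-bout noise
  jitter <- function(b) {
    b$duration_s <- b$duration_s * (1 + rnorm(nrow(b), 0, 0.04))
    b$steps <- round(b$steps * (1 + rnorm(nrow(b), 0, 0.04)))
    b
  }
  chest <- jitter(fragment_bouts(bouts, split_prob = 0.3, gap_s = 0.5,
                                 seed = 11))
  lumbar <- jitter(bouts)
  agg <- function(b) do.call(rbind, lapply(split(b, b$subject), function(d) {
    data.frame(subject = d$subject[1], mean_bout_duration_s = mean(d$duration_s),
               total_walking_time_s = sum(d$duration_s),
               n_bouts = nrow(d), total_steps = sum(d$steps))
  }))
  cmp <- compare_bout_stats(agg(chest), agg(lumbar))
  get <- function(met) cmp[cmp$metric == met, ]
  expect_lt(get("mean_bout_duration_s")$p, 0.05)
  expect_lt(get("mean_bout_duration_s")$mean_diff, 0)
  expect_lt(get("n_bouts")$p, 0.05)
  expect_gt(get("n_bouts")$mean_diff, 0)
  # totals are preserved: relative difference below 1%
  tot <- get("total_walking_time_s")
  stp <- get("total_steps")
  expect_lt(abs(tot$mean_diff) / mean(agg(lumbar)$total_walking_time_s), 0.01)
  expect_lt(abs(stp$mean_diff) / mean(agg(lumbar)$total_steps), 0.01)
})
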