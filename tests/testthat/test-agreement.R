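test_that("Bland-Altman matches the direct formulas", {
  # differences {-0.1, 0, 0.1}: bias 0, LoA = +/- 1.96 * 0.1
  ref <- c(1, 1, 1)
  test <- ref + c(-0.1, 0, 0.1)
  ba <- bland_altman(test, ref)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_lower, -0.196)
  expect_equal(ba$loa_upper, 0.196)

  # identical series collapse to zero-width limits
  ba0 <- bland_altman(ref, ref)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))

  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman and Pearson match brute-force oracles", {
  set.seed(11)
  for (i in 1:25) {
    ref <- rnorm(20, 1.2, 0.2)
    test <- ref + rnorm(20, 0, 0.1)
    ba <- bland_altman(test, ref)
    d <- test - ref
    m <- sum(d) / 20
    s <- sqrt(sum((d - m)^2) / 19)
    expect_equal(ba$bias, m, tolerance = 1e-12)
    expect_equal(ba$loa_lower, m - 1.96 * s, tolerance = 1e-12)
    expect_equal(ba$loa_upper, m + 1.96 * s, tolerance = 1e-12)
    pr <- pearson_cor(test, ref)
    num <- sum((test - mean(test)) * (ref - mean(ref)))
    den <- sqrt(sum((test - mean(test))^2) * sum((ref - mean(ref))^2))
    expect_equal(pr$r, num / den, tolerance = 1e-12)
    tval <- pr$r * sqrt(18 / (1 - pr$r^2))
    expect_equal(pr$p, 2 * pt(-abs(tval), 18), tolerance = 1e-12)
  }
})

test_that("error metrics follow their definitions", {
  em <- error_metrics(c(1.1, 0.9), c(1.0, 1.0))
  expect_equal(em$bias, 0)
  expect_equal(em$mad, 0.1)
  expect_equal(em$mpe, 0)
  expect_equal(error_metrics(1.2, 1.0)$mpe, 20)
  expect_equal(unlist(error_metrics(c(1, 2), c(1, 2))[c("bias", "mad", "mpe")]),
               c(bias = 0, mad = 0, mpe = 0))
  expect_warning(em0 <- error_metrics(c(1, 1), c(1, 0)), "zero reference")
  expect_equal(em0$n_mpe, 1)
})

test_that("ICC(2,1) matches an ANOVA mean-squares oracle", {
  set.seed(21)
  for (i in 1:25) {
    m <- matrix(rnorm(40), 20, 2) + rnorm(20)
    r <- icc_2way_random_absolute(m)
    df <- data.frame(y = c(m), s = factor(rep(1:20, 2)),
                     rt = factor(rep(1:2, each = 20)))
    a <- anova(aov(y ~ s + rt, df))
    msr <- a["s", "Mean Sq"]; msc <- a["rt", "Mean Sq"]
    mse <- a["Residuals", "Mean Sq"]
    icc_o <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 20)
    expect_equal(r$icc, icc_o, tolerance = 1e-10)
    expect_true(r$lb <= r$icc && r$icc <= r$ub)
  }
})

test_that("ICC edge and asymptotic behaviour", {
  x <- rnorm(10, sd = 2)
  expect_equal(icc_2way_random_absolute(cbind(x, x))$icc, 1)
  # anti-correlated columns: negative ICC, no error
  expect_lt(icc_2way_random_absolute(cbind(x, -x))$icc, 0)
  # variance ratio 9:1 -> ICC -> 0.9 at large n
  set.seed(5)
  n <- 10000
  subj <- rnorm(n, sd = 3)
  m <- cbind(subj + rnorm(n), subj + rnorm(n))
  expect_equal(icc_2way_random_absolute(m)$icc, 0.9, tolerance = 0.02)
  expect_error(icc_2way_random_absolute(matrix(c(1, 2, NA, 4), 2, 2)),
               "complete")
})

test_that("agreement benchmarks use the printed boundaries", {
  expect_equal(classify_agreement(c(0.882, 0.430, 0.75, 0.4, 0.6, -0.2, 0.74)),
               c("excellent", "moderate", "excellent", "poor", "good",
                 "poor", "good"))
})

test_that("Pearson degenerate cases error; perfect lines give +/- 1", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(2 * x + 1, x)$r, 1)
  expect_equal(pearson_cor(-x, x)$r, -1)
  expect_error(pearson_cor(rep(1, 4), x), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("shift and scale invariances hold", {
  set.seed(31)
  ref <- rnorm(20, 1.2, 0.2)
  test <- ref + rnorm(20, 0, 0.1)
  b0 <- bland_altman(test, ref)
  bs <- bland_altman(3 * test, 3 * ref)
  expect_equal(bs$bias, 3 * b0$bias, tolerance = 1e-12)
  expect_equal(bs$loa_upper - bs$loa_lower,
               3 * (b0$loa_upper - b0$loa_lower), tolerance = 1e-12)
  bt <- bland_altman(test + 5, ref + 5)
  expect_equal(bt$bias, b0$bias, tolerance = 1e-12)
  expect_equal(pearson_cor(3 * test, 3 * ref)$r, pearson_cor(test, ref)$r,
               tolerance = 1e-12)
  em <- error_metrics(3 * test, 3 * ref)
  expect_equal(em$mad, 3 * error_metrics(test, ref)$mad, tolerance = 1e-12)
})

test_that("test-retest reliability tracks the generative correlation", {
  v <- rnorm(10, 1.2, 0.2)
  tr <- test_retest(v, v)
  expect_equal(tr$icc$icc, 1)
  expect_equal(tr$pearson$r, 1)
  set.seed(41)
  n <- 1000
  z1 <- rnorm(n); z2 <- rnorm(n)
  rho <- 0.8
  tr2 <- test_retest(z1, rho * z1 + sqrt(1 - rho^2) * z2)
  expect_lt(abs(tr2$icc$icc - 0.8), 0.05)
  # independent visits: ICC near zero
  tr3 <- test_retest(rnorm(n), rnorm(n))
  expect_lt(abs(tr3$icc$icc), 0.1)
})

test_that("the agreement table assembles all panels per task x endpoint", {
  set.seed(51)
  subj <- 1:12
  mk <- function(dev_bias) {
    do.call(rbind, lapply(c("walk_slow", "walk_fast"), function(tk) {
      data.frame(subject = subj, task = tk, endpoint = "gait_speed",
                 value = rnorm(12, 1.2, 0.15) + dev_bias)
    }))
  }
  ref <- mk(0)
  test <- ref
  test$value <- test$value + rnorm(nrow(test), -0.05, 0.02)
  at <- agreement_summary(test, ref)
  expect_equal(nrow(at), 2L)
  expect_true(all(c("bias", "loa_lower", "mad", "mpe", "icc", "pearson_r")
                  %in% names(at)))
  expect_true(all(at$loa_lower <= at$bias & at$bias <= at$loa_upper))
  expect_equal(at$bias, rep(-0.05, 2), tolerance = 0.03)
})
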