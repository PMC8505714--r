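ev_fixture <- function() {
  # two grasp trials and one no-movement trial, fs = 1000
  event_table(
    sample = c(0L, 3000L, 3000L, 5000L, 5300L,
               10000L, 13000L, 13000L, 15000L, 15600L,
               20000L, 23000L, 23000L, 25000L),
    kind = c("trial_start", "condition_marker", "cue", "go", "button_release",
             "trial_start", "condition_marker", "cue", "go", "button_release",
             "trial_start", "condition_marker", "cue", "go"),
    code = c(NA, 1L, NA, NA, NA, NA, 3L, NA, NA, NA, NA, 6L, NA, NA))
}

test_that("reaction time is the Go-to-release interval", {
  rt <- compute_rt(ev_fixture(), 1000)
  expect_equal(rt$rt_s, c(0.3, 0.6, NA))
  expect_equal(rt$flagged, c(FALSE, FALSE, FALSE))
  expect_equal(rt$code, c(1L, 3L, 6L))
})

test_that("a release preceding Go (or missing) flags the grasp trial", {
  ev <- event_table(sample = c(0L, 3000L, 5000L, 4000L),
                    kind = c("trial_start", "condition_marker", "go",
                             "button_release"),
                    code = c(NA, 2L, NA, NA))
  rt <- compute_rt(ev, 1000)
  expect_true(rt$flagged[1])
  ev2 <- event_table(sample = c(0L, 3000L, 5000L),
                     kind = c("trial_start", "condition_marker", "go"),
                     code = c(NA, 2L, NA))
  expect_true(compute_rt(ev2, 1000)$flagged[1])
})

test_that("virtual onsets add one pooled mean RT to every Go cue", {
  rt <- compute_rt(ev_fixture(), 1000)
  vo <- compute_virtual_onsets(rt, 1000)
  expect_equal(vo$mean_rt_s, 0.45)          # mean of 0.3 and 0.6
  expect_equal(vo$onsets, c(5450L, 15450L, 25450L))  # incl. no-movement
  # single retained RT
  rt1 <- rt; rt1$rt_s[2] <- NA
  expect_equal(compute_virtual_onsets(rt1, 1000)$onsets[1], 5300L)
  # no retained RTs errors
  rt0 <- rt; rt0$rt_s <- NA_real_
  expect_error(compute_virtual_onsets(rt0, 1000), "no retained")
})

test_that("RT screening precedes the mean: slow trials shift no onset", {
  rt <- compute_rt(ev_fixture(), 1000)
  vo <- compute_virtual_onsets(rt, 1000)
  rt_slow <- rt
  rt_slow$rt_s[3] <- 5.0                     # inject an RT > 2 s trial
  vo2 <- compute_virtual_onsets(rt_slow, 1000)
  expect_equal(vo2$onsets, vo$onsets)
})

test_that("computed reaction times recover the generator ground truth", {
  fx <- desk_subject()
  gt <- fx$sim$ground_truth
  rt <- compute_rt(fx$sim$events, fx$cfg$sampling_rate_hz)
  grasp <- gt$condition_code != 6L
  expect_lt(abs(mean(rt$rt_s[grasp]) - mean(gt$rt_s[grasp])), 0.001)
  # virtual onsets deviate from true onsets with ~zero mean
  vo <- compute_virtual_onsets(rt, fx$cfg$sampling_rate_hz)
  kept <- grasp & gt$rt_s <= 2
  dev <- (vo$onsets[kept] - gt$true_onset_sample[kept]) /
    fx$cfg$sampling_rate_hz
  se <- sd(dev) / sqrt(length(dev))
  expect_lt(abs(mean(dev)), 3 * se + 1e-3)
})

test_that("grasp intervals come from threshold crossings of the force", {
  fs <- 1000
  f <- numeric(5000)
  f[1001:3000] <- 1                              # rises 1.0 s, falls 3.0 s
  g <- detect_grasp_interval(f, fs)
  expect_false(g$flagged)
  expect_lt(abs(g$duration_s - 2.0), 2 / fs)     # exact up to one sample
  expect_lt(abs(g$grasp_start_s - 1.0), 2 / fs)
  expect_true(detect_grasp_interval(numeric(100), fs)$flagged)
  expect_error(detect_grasp_interval(c(-1, 1), fs), "non-negative")
})

test_that("behavioral summary recovers grasp starts in the study window", {
  fx <- desk_subject()
  bs <- behavioral_summary(fx$sim, conditions = fx$cfg$condition_codes)
  grasp <- !is.na(bs$trials$grasp_start_s)
  m <- mean(bs$trials$grasp_start_s[grasp])
  expect_gte(m, 0.9)
  expect_lte(m, 1.25)
  expect_true(all(bs$trials$release_s[grasp] >
                    bs$trials$grasp_start_s[grasp]))
  expect_equal(bs$trials$duration_s[grasp],
               bs$trials$release_s[grasp] - bs$trials$grasp_start_s[grasp])
})

test_that("repeated-measures ANOVA matches the explicit sums-of-squares oracle", {
  set.seed(5)
  Y <- matrix(rnorm(18), 6, 3)
  res <- duration_anova(Y)
  n <- 6; k <- 3; gm <- mean(Y)
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (mean(Y[, j]) - gm)^2
  sse <- 0
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (Y[i, j] - mean(Y[i, ]) - mean(Y[, j]) + gm)^2
  F_oracle <- (ssc / (k - 1)) / (sse / ((k - 1) * (n - 1)))
  expect_equal(res$F, F_oracle)
  expect_equal(res$p, pf(F_oracle, k - 1, (k - 1) * (n - 1),
                         lower.tail = FALSE))
  # Mauchly's W against the stats oracle on the same table
  mt <- stats::mauchly.test(lm(Y ~ 1), X = ~1)
  expect_equal(res$mauchly_w, unname(mt$statistic), tolerance = 1e-10)
  expect_equal(res$mauchly_p, unname(mt$p.value), tolerance = 1e-10)
})

test_that("ANOVA degrees of freedom and degenerate inputs behave", {
  Y <- matrix(rnorm(45), 9, 5)
  res <- duration_anova(Y)
  expect_equal(res$df, c(4L, 32L))            # n = 9 subjects, k = 5
  expect_equal(duration_anova(matrix(2.5, 5, 4))$F, 0)  # all cells equal
  expect_error(duration_anova(matrix(c(1, NA, 2, 3, 4, 5), 3, 2)), "missing")
  expect_error(duration_anova(matrix(1:4, 2, 2)), "at least 3 subjects")
})

test_that("duration ANOVA holds its type-I level under the null generator", {
  # condition-identical duration model: p > 0.05 in >= 90% of runs
  set.seed(77)
  ps <- replicate(50, {
    Y <- matrix(rnorm(9 * 5, mean = 1.5, sd = 0.3), 9, 5)
    duration_anova(Y)$p
  })
  # nominal rate 0.95 with a 3-SD binomial margin: 2.5 + 3 * 1.54 ~ 7
  # rejections allowed out of 50
  expect_gte(mean(ps > 0.05), 0.86)
})
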