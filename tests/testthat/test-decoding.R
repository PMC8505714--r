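test_that("the default scheme yields 70 end-labeled windows", {
  sch <- window_scheme()
  ends <- sch$window_ends_s
  expect_equal(length(ends), 70L)
  expect_equal(ends[1], -0.95)
  expect_equal(ends[70], 2.50)
  # halving the step doubles the model count
  expect_equal(length(window_scheme(step_s = 0.025)$window_ends_s), 140L)
})

test_that("feature dimension is channels x amplitudes in montage order", {
  labels33 <- setdiff(default_montage(), default_excluded_channels())
  ep <- make_epochs(4, NULL, sigma = 1, n_channels = 33, seed = 1,
                    channel_labels = labels33)
  X <- extract_window_features(ep, 0.5)
  expect_equal(ncol(X), 330L)
  ep1 <- make_epochs(4, NULL, sigma = 1, n_channels = 1, seed = 1)
  expect_equal(ncol(extract_window_features(ep1, 0.5)), 10L)
  # channel subsets scale the dimension linearly
  ep7 <- make_epochs(4, NULL, sigma = 1, n_channels = 7, seed = 1)
  expect_equal(ncol(extract_window_features(ep7, 0.5)), 70L)
  # every window of the default scheme fits the [-1.5, 2.5) epoch
  sch <- window_scheme()
  for (e in sch$window_ends_s[c(1, 35, 70)])
    expect_silent(extract_window_features(ep1, e, sch))
  expect_error(extract_window_features(ep1, 2.55), "outside the epoch")
})

test_that("features are the identity on channel-constant epochs", {
  ep <- make_epochs(3, NULL, sigma = 0, n_channels = 5, seed = 1)
  for (c in 1:5) ep$data[, c, ] <- c
  X <- extract_window_features(ep, 1.0)
  expect_equal(dim(X), c(3L, 50L))
  for (c in 1:5)
    expect_true(all(X[, (c - 1) * 10 + 1:10] == c))
})

test_that("perfectly separable epochs give a flat curve at 1.0", {
  labels <- rep(c("a", "b"), each = 10)
  ep <- make_epochs(20, NULL, sigma = 0.01, n_channels = 2, seed = 2,
                    labels = labels)
  ep$data[labels == "b", , ] <- ep$data[labels == "b", , ] + 5
  cv <- cross_validated_curve(ep, repetitions = 2, seed = 1)
  expect_equal(nrow(cv), 70L)
  expect_true(all(cv$accuracy == 1))
})

test_that("peaks resolve ties to the earliest window", {
  cu <- data.frame(window_time_s = c(0.5, 1.0, 1.5),
                   accuracy = c(0.4, 0.8, 0.8))
  pk <- peak_performance(cu)
  expect_equal(pk$time_s, 1.0)
  expect_equal(pk$accuracy, 0.8)
  mono <- data.frame(window_time_s = 1:5 / 10, accuracy = 1:5 / 10)
  expect_equal(peak_performance(mono)$time_s, 0.5)   # last window
  expect_error(peak_performance(mono[0, ]), "empty")
})

test_that("grand-average curves never out-peak the mean subject peak", {
  set.seed(3)
  curves <- lapply(1:5, function(i) {
    structure(data.frame(window_time_s = window_scheme()$window_ends_s,
                         accuracy = runif(70, 0.2, 0.9), sd = 0.05),
              class = c("accuracy_curve", "data.frame"), n_trials = 100L)
  })
  g <- grand_average_curve(curves)
  expect_lte(peak_performance(g)$accuracy,
             mean(sapply(curves, function(cu) peak_performance(cu)$accuracy)))
})

test_that("curves are reproducible bit-exactly under a fixed seed", {
  fx <- desk_subject()
  a <- cross_validated_curve(fx$pp$epochs, c("palmar", "no_movement"),
                             repetitions = 2, seed = 9)
  b <- cross_validated_curve(fx$pp$epochs, c("palmar", "no_movement"),
                             repetitions = 2, seed = 9)
  expect_identical(a$accuracy, b$accuracy)
  c2 <- cross_validated_curve(fx$pp$epochs, c("palmar", "no_movement"),
                              repetitions = 2, seed = 10)
  expect_false(identical(a$accuracy, c2$accuracy))
})

test_that("class counts below the fold count are refused", {
  ep <- make_epochs(8, NULL, sigma = 1, n_channels = 1, seed = 4,
                    labels = c(rep("a", 4), rep("b", 4)))
  expect_error(cross_validated_curve(ep, folds = 5), "fewer trials")
})

test_that("the adjusted-Wald bound matches its oracles", {
  # exact binomial oracle at n = 100, k = 2
  b <- chance_upper_bound(100, 2)$bound
  expect_lt(abs(b - qbinom(0.95, 100, 0.5) / 100), 0.02)
  # consistency: the bound approaches 1/k for huge n
  expect_lt(abs(chance_upper_bound(1e8, 2)$bound - 0.5), 1e-3)
  # strictly decreasing in n
  bs <- sapply(c(20, 50, 100, 500), function(n) chance_upper_bound(n, 2)$bound)
  expect_true(all(diff(bs) < 0))
  expect_error(chance_upper_bound(100, 2, alpha = 0.6), "alpha")
  expect_error(chance_upper_bound(0, 2), "n >= 1")
})

test_that("confusion matrices are row-stochastic with sensible TPRs", {
  labels <- rep(c("a", "b", "c"), each = 10)
  ep <- make_epochs(30, NULL, sigma = 0.01, n_channels = 2, seed = 5,
                    labels = labels)
  ep$data[labels == "b", , ] <- ep$data[labels == "b", , ] + 5
  ep$data[labels == "c", , ] <- ep$data[labels == "c", , ] - 5
  cm <- confusion_at(ep, 1.0, repetitions = 2, seed = 1)
  expect_true(all(abs(rowSums(cm$normalized) - 1) < 1e-12))
  expect_equal(unname(cm$tpr), c(1, 1, 1))     # perfectly separable
  expect_equal(sum(cm$counts), 30 * 2)         # trials x repetitions
})

test_that("shuffled labels stay inside the chance band at a single window", {
  fx <- desk_subject()
  ep <- kept_epochs(fx$pp$epochs, fx$cfg$condition_codes[1:5])
  set.seed(8)
  ep$labels <- sample(ep$labels)
  cm <- confusion_at(ep, 1.0, repetitions = 2, seed = 1)
  n_per <- min(table(ep$labels))
  band <- chance_upper_bound(n_per, 5)$bound
  expect_true(all(cm$tpr <= band + 0.1))
})

test_that("distinct template pairs decode above chance, identical ones do not", {
  fx <- deep_subject()
  ep <- fx$pp$epochs
  # push and plug are generated with identical post-onset morphology
  cv_same <- cross_validated_curve(ep, c("push", "plug"),
                                   repetitions = 2, seed = 11)
  b_same <- chance_upper_bound(attr(cv_same, "n_trials"), 2)$bound
  expect_lte(peak_performance(cv_same)$accuracy, b_same + 0.02)
  # pairs with distinct post-onset shapes separate
  for (pr in list(c("palmar", "plug"), c("pinch", "push"),
                  c("twist", "plug"))) {
    cv <- cross_validated_curve(ep, pr, repetitions = 2, seed = 11)
    b <- chance_upper_bound(attr(cv, "n_trials"), 2)$bound
    expect_gt(peak_performance(cv)$accuracy, b)
  }
})
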