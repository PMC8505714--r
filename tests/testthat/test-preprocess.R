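test_that("default channel selection keeps 33 of 40 channels in order", {
  fx <- desk_subject()
  rec <- fx$sim$recording
  out <- select_channels(rec)
  expect_equal(n_channels(out), 33L)
  expect_equal(out$channel_labels,
               setdiff(rec$channel_labels, default_excluded_channels()))
  # empty exclusion is the identity
  same <- select_channels(rec, character(0))
  expect_equal(same$data, rec$data)
  # removing everything is an error
  expect_error(select_channels(rec, rec$channel_labels), "every channel")
  # unknown labels error under strict mode only
  expect_error(select_channels(rec, "XX9"), "not in recording")
  expect_silent(select_channels(rec, c("F5", "XX9"), strict = FALSE))
  # AF7 is accepted as an alias of AF5
  al <- select_channels(rec, c("FP1", "AF7"))
  expect_false("AF5" %in% al$channel_labels)
})

test_that("DC is rejected by the analysis band-pass away from the edges", {
  fs <- 100
  rec <- make_recording(matrix(100, 1, 120 * fs), fs = fs)
  out <- apply_filter(rec, filter_spec("bandpass", 4, c(0.3, 3)))
  mid <- out$data[1, (40 * fs):(80 * fs)]
  expect_lt(max(abs(mid)), 1e-6 * 100)
})

test_that("zero-phase filtering leaves a symmetric impulse response", {
  fs <- 100
  x <- numeric(12000); x[6000] <- 1
  rec <- make_recording(matrix(x, 1), fs = fs)
  y <- apply_filter(rec, filter_spec("lowpass", 4, 40))$data[1, ]
  k <- 500
  expect_lt(max(abs(y[6000 + 1:k] - y[6000 - 1:k])), 1e-8)
  # the near-unit-circle 0.3-Hz pole raises the recursion's noise floor
  yb <- apply_filter(rec, filter_spec("bandpass", 4, c(0.3, 3)))$data[1, ]
  expect_lt(max(abs(yb[6000 + 1:k] - yb[6000 - 1:k])), 1e-6)
})

test_that("in-band sinusoids pass the band-pass at unit gain", {
  fs <- 100
  t <- seq(0, 120, by = 1 / fs)[-1]
  rec <- make_recording(matrix(sin(2 * pi * 1.5 * t), 1), fs = fs)
  y <- apply_filter(rec, filter_spec("bandpass", 4, c(0.3, 3)))$data[1, ]
  mid <- seq(40 * fs, 80 * fs)
  gain <- max(abs(y[mid]))
  # oracle: |H(1.5 Hz)|^2 for the forward-backward order-4 Butterworth
  bf <- signal::butter(4, c(0.3, 3) / (fs / 2), "pass")
  z <- exp(1i * 2 * pi * 1.5 / fs)
  H2 <- Mod(sum(bf$b * z^-(seq_along(bf$b) - 1)) /
            sum(bf$a * z^-(seq_along(bf$a) - 1)))^2
  expect_lt(abs(gain - H2), 0.01)
  expect_gt(gain, 0.95)                 # within 5% of the input amplitude
})

test_that("corner frequencies at or above Nyquist are rejected", {
  rec <- make_recording(matrix(0, 1, 1000), fs = 100)
  expect_error(apply_filter(rec, filter_spec("lowpass", 4, 50)), "Nyquist")
  expect_error(filter_spec("bandpass", 4, c(3, 0.3)), "increasing")
})

test_that("common average reference zeroes the cross-channel mean", {
  # identical constant on all channels vanishes
  rec <- make_recording(matrix(5, 4, 100))
  expect_true(all(common_average_reference(rec)$data == 0))
  # (+a, -a) pair is already zero-mean and passes unchanged
  a <- sin(seq_len(200))
  rec2 <- make_recording(rbind(a, -a))
  expect_equal(common_average_reference(rec2)$data, rec2$data,
               ignore_attr = TRUE)
  # random 33 x 1000 matrix: all column means below 1e-10
  set.seed(1)
  rec3 <- make_recording(matrix(rnorm(33 * 1000), 33))
  expect_lt(max(abs(colMeans(common_average_reference(rec3)$data))), 1e-10)
  expect_error(common_average_reference(make_recording(matrix(1, 1, 10))),
               "at least two")
})

test_that("downsampling decimates samples and rescales events", {
  rec <- make_recording(matrix(seq_len(10000), 1, 10000), fs = 1000)
  out <- downsample(rec, 100)
  expect_equal(ncol(out$data), 1000L)
  expect_equal(out$sampling_rate_hz, 100)
  # constants are preserved exactly
  cst <- downsample(make_recording(matrix(3.3, 2, 500), fs = 1000), 100)
  expect_true(all(cst$data == 3.3))
  # a 2-Hz sinusoid survives decimation within 2% of the analytic samples
  fs <- 1000
  t <- (seq_len(10 * fs) - 1) / fs
  rec2 <- make_recording(matrix(sin(2 * pi * 2 * t), 1), fs = fs)
  dec <- downsample(rec2, 100)$data[1, ]
  t2 <- (seq_len(1000) - 1) / 100
  expect_lt(max(abs(dec - sin(2 * pi * 2 * t2))), 0.02)
  # events rescale by integer division
  ev <- event_table(c(999L, 1000L), c("go", "go"))
  both <- downsample(rec, 100, events = ev)
  expect_equal(both$events$sample, c(99L, 100L))
  expect_error(downsample(rec, 300), "integer multiple")
})

test_that("filtering and re-referencing are linear operators", {
  set.seed(2)
  x <- matrix(rnorm(2 * 4000), 2)
  rec1 <- make_recording(x)
  rec3 <- make_recording(3 * x)
  spec <- filter_spec("bandpass", 4, c(0.3, 3))
  # recursive filtering amplifies rounding differences; linearity holds to
  # a small relative tolerance
  d <- apply_filter(rec3, spec)$data - 3 * apply_filter(rec1, spec)$data
  expect_lt(max(abs(d)), 1e-4 * max(abs(x)))
  expect_equal(common_average_reference(rec3)$data,
               3 * common_average_reference(rec1)$data)
})

test_that("processing steps are logged in order", {
  fx <- desk_subject()
  expect_equal(fx$pp$stages,
               c("rt_screening", "channel_selection", "lowpass_40hz",
                 "amplitude_rejection", "statistical_rejection", "car",
                 "bandpass_0.3_3hz", "downsample", "epoch"))
  expect_equal(fx$pp$epochs$sampling_rate_hz, 100)
})
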