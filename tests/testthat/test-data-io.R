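test_that("BrainVision round trip preserves data to float32 and events exactly", {
  cfg <- desk_config(n_sessions = 1, tpc = 1, fs = 200)
  sim <- simulate_subject(cfg, mrcp_templates(cfg), seed = 3)
  base <- file.path(withr::local_tempdir(), "subj")
  write_brainvision(sim$recording, sim$events, base)
  back <- read_brainvision(paste0(base, ".vhdr"))
  expect_equal(back$recording$channel_labels, sim$recording$channel_labels)
  expect_equal(back$recording$sampling_rate_hz, 200)
  expect_lt(max(abs(back$recording$data - sim$recording$data)),
            max(abs(sim$recording$data)) * 2^-22)
  expect_equal(back$events$sample, sim$events$sample)
  expect_equal(back$events$kind, sim$events$kind)
  expect_equal(back$events$code, sim$events$code)
})

test_that("int16 BrainVision data is scaled by the channel resolution", {
  dir <- withr::local_tempdir()
  writeLines(c("Brain Vision Data Exchange Header File Version 1.0",
               "[Common Infos]", "DataFile=x.eeg", "DataFormat=BINARY",
               "DataOrientation=MULTIPLEXED", "NumberOfChannels=2",
               "SamplingInterval=1000",
               "[Binary Infos]", "BinaryFormat=INT_16",
               "[Channel Infos]", "Ch1=A,,0.1,µV", "Ch2=B,,0.5,µV"),
             file.path(dir, "x.vhdr"))
  con <- file(file.path(dir, "x.eeg"), "wb")
  writeBin(c(50L, 50L, -20L, 10L), con, size = 2L, endian = "little")
  close(con)
  rec <- read_brainvision(file.path(dir, "x.vhdr"))$recording
  expect_equal(rec$data[1, ], c(5.0, -2.0))   # 50 * 0.1, -20 * 0.1
  expect_equal(rec$data[2, ], c(25.0, 5.0))   # 50 * 0.5, 10 * 0.5
})

test_that("structural and dialect errors are explicit", {
  dir <- withr::local_tempdir()
  hdr <- file.path(dir, "bad.vhdr")
  writeLines(c("Brain Vision Data Exchange Header File Version 1.0",
               "[Common Infos]", "DataFile=bad.eeg", "DataFormat=BINARY",
               "DataOrientation=MULTIPLEXED", "NumberOfChannels=40",
               "SamplingInterval=1000",
               "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
               "[Channel Infos]",
               sprintf("Ch%d=ch%d,,1,µV", 1:40, 1:40)), hdr)
  # 39 x 101 float32 values cannot be split into 40 channels
  con <- file(file.path(dir, "bad.eeg"), "wb")
  writeBin(numeric(39 * 101), con, size = 4L, endian = "little")
  close(con)
  expect_error(read_brainvision(hdr), "40 declared channels")
  expect_error(read_brainvision(file.path(dir, "absent.vhdr")), "not found")
  # unsupported binary format
  writeLines(c("Brain Vision Data Exchange Header File Version 1.0",
               "[Common Infos]", "DataFile=bad.eeg", "DataFormat=BINARY",
               "DataOrientation=MULTIPLEXED", "NumberOfChannels=39",
               "SamplingInterval=1000",
               "[Binary Infos]", "BinaryFormat=INT_32",
               "[Channel Infos]",
               sprintf("Ch%d=ch%d,,1,µV", 1:39, 1:39)),
             file.path(dir, "fmt.vhdr"))
  file.copy(file.path(dir, "bad.eeg"), file.path(dir, "fmt.eeg"))
  expect_error(read_brainvision(file.path(dir, "fmt.vhdr")),
               "unsupported BrainVision dialect")
})

test_that("marker descriptions tolerate arbitrary internal whitespace", {
  dir <- withr::local_tempdir()
  rec <- make_recording(matrix(0, 1, 100))
  base <- file.path(dir, "m")
  write_brainvision(rec, NULL, base)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,0",
               "Mk2=Stimulus,S3,11,1,0",
               "Mk3=Stimulus,S    4,21,1,0",
               "Mk4=Stimulus,S 99,31,1,0",
               "Mk5=Comment,blob,41,1,0"), paste0(base, ".vmrk"))
  ev <- read_brainvision(paste0(base, ".vhdr"))$events
  expect_equal(ev$kind, c("condition_marker", "condition_marker",
                          "other", "other"))
  expect_equal(ev$code[1:2], c(3L, 4L))
  expect_equal(ev$sample, c(10L, 20L, 30L, 40L))   # converted to 0-based
})

test_that("internal container round trip is bit-exact", {
  fx <- desk_subject()
  path <- withr::local_tempfile(fileext = ".rds")
  save_recording(fx$sim$recording, path)
  expect_identical(load_recording(path), fx$sim$recording)
})

test_that("event tables round-trip through CSV and stay ordered", {
  ev <- event_table(c(30L, 10L, 20L), c("go", "trial_start", "cue"))
  expect_equal(ev$sample, c(10L, 20L, 30L))      # sorted on construction
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  expect_equal(read_events(path), ev)
  expect_error(event_table(1, "condition_marker", 9), "1..6")
  expect_error(event_table(1, "nonsense"), "unknown event kind")
})

test_that("epoch extraction follows the half-open sample convention", {
  fs <- 100
  rec <- make_recording(matrix(7, 2, 30 * fs), fs = fs)
  ep <- epoch_recording(rec, onsets = c(500L, 1000L), window = c(-1.5, 2.5))
  expect_equal(dim(ep$data), c(2, 2, 400))        # 4 s x 100 Hz, half-open
  expect_true(all(ep$data == 7))                  # pure slicing
  expect_equal(ep$time_axis[1], -1.5)
  expect_equal(ep$time_axis[400], 2.49)
  expect_true(0 %in% ep$time_axis)                # t = 0 sample included
  # zero recording slices to zero
  ep0 <- epoch_recording(make_recording(matrix(0, 1, 3000)), 1500L)
  expect_equal(sum(ep0$data), 0)
})

test_that("onsets too close to the recording edge are flagged, not dropped", {
  rec <- make_recording(matrix(1, 1, 300), fs = 100)
  ep <- epoch_recording(rec, onsets = c(100L, 160L), window = c(-1.5, 2.5))
  expect_equal(ep$kept, c(FALSE, FALSE))
  expect_equal(ep$reject_reason, c("edge", "edge"))
  expect_equal(dim(ep$data)[1], 2)                # still two trials
})
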