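# Epoching, windowing, subject exclusion, standardization.

test_that("the six mis-annotated subjects are excluded, order preserved", {
  kept <- exclude_subjects(1:109)
  expect_length(kept, 103)
  expect_false(any(c(38, 88, 89, 82, 100, 104) %in% kept))
  expect_identical(kept, sort(kept))
  expect_identical(exclude_subjects(c(1, 2, 3)), c(1, 2, 3))
  expect_length(exclude_subjects(c(38, 88)), 0)
})

test_that("epoch extraction reproduces the two dataset geometries", {
  rec <- simulate_recording(synth_config(n_trials = 10, seed = 4))
  ep <- extract_epochs(rec, c("T1", "T2"), 4)           # 160 Hz, 4 s
  expect_equal(dim(ep$epochs)[3], 640)
  expect_equal(dim(ep$epochs)[1], 10)

  # 250 Hz, 4.5 s epoch offset 1.5 s into a 6 s trial -> 1125 samples
  cfg <- synth_config(sampling_rate_hz = 250, trial_duration_s = 6,
                      n_trials = 4, erd_band_hz = c(8, 12), seed = 4)
  rec2 <- simulate_recording(cfg)
  ep2 <- extract_epochs(rec2, cfg$class_labels, 4.5, offset_s = 1.5)
  expect_equal(dim(ep2$epochs)[3], 1125)
})

test_that("epochs running past the record end are dropped with a message", {
  sig <- matrix(rnorm(2 * 1000), 2)
  ev <- data.frame(onset_sample = c(0L, 600L), duration_samples = 320L,
                   label = "T1")
  rec <- annotated_recording(sig, 160, ev)
  expect_message(ep <- extract_epochs(rec, "T1", 4), "dropping 1")
  expect_equal(dim(ep$epochs)[1], 1)
  expect_error(extract_epochs(rec, "T9", 2), "no events")
  expect_error(extract_epochs(rec, "T1", 0), "positive")
})

test_that("windowing partitions epochs exactly and labels are inherited", {
  rec <- simulate_recording(synth_config(n_trials = 45, seed = 1))
  ep <- extract_epochs(rec, c("T1", "T2"), 4)
  ws <- window_epochs(ep, 80)
  expect_equal(dim(ws$windows)[1], 360)                 # 45 x 8
  expect_true(all(table(ws$provenance$epoch) == 8))
  # provenance is a bijection onto (epoch, window) pairs
  expect_false(any(duplicated(ws$provenance)))
  expect_setequal(ws$provenance$window, 1:8)
  # each window's label equals its source epoch's
  expect_identical(ws$labels, ep$labels[ws$provenance$epoch])
  # concatenating a given epoch's windows reconstructs that epoch
  i <- 17
  rows <- which(ws$provenance$epoch == i)
  rebuilt <- do.call(cbind, lapply(rows, function(r) ws$windows[r, , ]))
  expect_equal(rebuilt, ep$epochs[i, , ])
})

test_that("windowing edge cases behave", {
  rec <- simulate_recording(synth_config(n_trials = 3, seed = 2))
  ep <- extract_epochs(rec, c("T1", "T2"), 4)
  w1 <- window_epochs(ep, 640)                          # identity case
  expect_equal(dim(w1$windows)[1], 3)
  expect_equal(w1$windows[2, , ], ep$epochs[2, , ])
  expect_message(wr <- window_epochs(ep, 300), "dropping 40")
  expect_equal(dim(wr$windows)[1], 3 * 2)
  expect_error(window_epochs(ep, 641), "exceeds")
})

test_that("standardization uses training statistics only", {
  ws <- tiny_windowed(n = 40, C = 3, W = 16)
  tr <- ws; tr$windows <- ws$windows[1:30, , , drop = FALSE]
  tr$labels <- ws$labels[1:30]; tr$provenance <- ws$provenance[1:30, ]
  te <- ws; te$windows <- ws$windows[31:40, , , drop = FALSE]
  te$labels <- ws$labels[31:40]; te$provenance <- ws$provenance[31:40, ]
  st <- standardize(tr, te)
  for (ch in 1:3) {
    expect_equal(mean(st$train$windows[, ch, ]), 0, tolerance = 1e-6)
    expect_equal(sd(as.vector(st$train$windows[, ch, ])), 1, tolerance = 1e-6)
  }
  # held-out set transformed with the *training* stats, not its own
  ch1 <- (te$windows[, 1, ] - st$stats$mean[1]) / st$stats$sd[1]
  expect_equal(st$others[[1]]$windows[, 1, ], ch1)
  # re-applying the returned stats is not the identity
  twice <- (st$train$windows[, 1, ] - st$stats$mean[1]) / st$stats$sd[1]
  expect_false(isTRUE(all.equal(twice, st$train$windows[, 1, ])))

  bad <- tr; bad$windows[, 2, ] <- 5
  expect_error(standardize(bad), "channel 2")
})

test_that("the full eegmmidb recipe and dataset IO round trip", {
  cfg <- synth_config(n_trials = 5, n_channels = 4, seed = 6)
  ws <- preprocess_recording(simulate_recording(cfg), "eegmmidb",
                             keep_labels = cfg$class_labels)
  expect_s3_class(ws, "windowed_dataset")
  expect_equal(dim(ws$windows), c(40, 4, 80))
  dir <- withr::local_tempdir()
  write_windows(ws, dir)
  back <- read_windows(dir)
  expect_equal(back$windows, ws$windows, tolerance = 1e-5)
  expect_identical(back$labels, ws$labels)
  expect_identical(back$class_names, ws$class_names)
})

test_that("annotation sidecar files round trip", {
  rec <- simulate_recording(synth_config(n_trials = 4, seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(rec, path)
  back <- read_annotations(path)
  expect_identical(back, rec$events)
  # a sidecar-equipped plain matrix builds the same recording
  rec2 <- annotated_recording(rec$signal, 160, events = back)
  expect_identical(rec2$events, rec$events)
  bad <- withr::local_tempfile()
  writeLines("a\tb\n1\t2", bad)
  expect_error(read_annotations(bad), "onset_sample")
})
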