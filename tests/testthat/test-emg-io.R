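test_that("recording construction validates shape, finiteness, annotations", {
  x <- matrix(rnorm(12 * 3000), 12, 3000)
  rec <- emg_recording(x, rate_hz = 1500, label = "WALK",
                       annotations = list(preparation = c(1, 3001)))
  expect_s3_class(rec, "emg_recording")
  expect_equal(dim(rec$samples), c(12, 3000))
  expect_equal(rec$label, "WALK")

  xb <- x; xb[3, 7] <- NaN
  expect_error(emg_recording(xb), "channel 3, sample 7")
  expect_error(emg_recording(x, rate_hz = 0), "positive")
  expect_error(emg_recording(x, annotations = list(preparation = c(5, 5))),
               "non-empty")
  expect_error(emg_recording(x, annotations = list(preparation = c(1, 4000))),
               "outside")
  expect_error(emg_recording(x[1, , drop = FALSE]), "at least 2 channels")
})

test_that("CSV round trip preserves doubles exactly and dimensions pass through", {
  dir <- withr::local_tempdir()
  x <- matrix(rnorm(12 * 3000), 12, 3000)
  rec <- emg_recording(x, rate_hz = 1500, subject_id = "S7", trial_id = "t1",
                       label = "UPSTAIRS",
                       annotations = list(preparation = c(1, 3001)))
  p <- file.path(dir, "rec.csv")
  write_recording(rec, p)
  back <- read_recording(p)
  expect_identical(back$samples, rec$samples)   # bit-exact
  expect_equal(ncol(back$samples), 3000)
  expect_equal(nrow(back$samples), 12)
  expect_equal(back$rate_hz, 1500)
  expect_equal(back$label, "UPSTAIRS")
  expect_equal(back$annotations$preparation, c(1L, 3001L))

  # corrupt one cell -> parse error naming the location
  lines <- readLines(p)
  parts <- strsplit(lines[3], ",")[[1]]
  parts[5] <- "oops"
  lines[3] <- paste(parts, collapse = ",")
  writeLines(lines, p)
  expect_error(suppressWarnings(read_recording(p)), "row 2, column 5")
})

test_that("missing sampling rate is a configuration error", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "naked.csv")
  writeLines(c("a,b", "1,2", "3,4"), p)
  expect_error(read_recording(p), "sampling rate")
  rec <- read_recording(p, meta = list(rate_hz = 1000))
  expect_equal(rec$rate_hz, 1000)
})

test_that("manifest loading groups by subject, sorts, and validates", {
  dir <- withr::local_tempdir()
  entries <- data.frame()
  for (sid in c("S2", "S1")) {
    for (tr in c("t2", "t1", "t3")) {
      rec <- emg_recording(matrix(rnorm(2 * 400), 2, 400), rate_hz = 1500,
                           subject_id = sid, trial_id = tr, label = "SIT")
      fn <- sprintf("%s_%s.csv", sid, tr)
      write_recording(rec, file.path(dir, fn))
      entries <- rbind(entries, data.frame(subject_id = sid, path = fn,
                                           trial_id = tr, label = "SIT"))
    }
  }
  mpath <- file.path(dir, "manifest.json")
  write_manifest(entries, mpath)
  ds <- load_dataset(mpath)
  expect_named(ds, c("S1", "S2"))
  expect_length(ds$S1, 3)
  expect_equal(vapply(ds$S2, `[[`, "", "trial_id"), c("t1", "t2", "t3"))

  # permuting the manifest rows leaves the grouping unchanged
  write_manifest(entries[sample(nrow(entries)), ], mpath)
  ds2 <- load_dataset(mpath)
  expect_equal(lapply(ds2, function(g) vapply(g, `[[`, "", "trial_id")),
               lapply(ds, function(g) vapply(g, `[[`, "", "trial_id")))

  # duplicate trial within subject
  bad <- rbind(entries, entries[1, ])
  write_manifest(bad, mpath)
  expect_error(load_dataset(mpath), "duplicate trial_id")

  # missing file listed by path
  bad2 <- entries
  bad2$path[2] <- "nowhere.csv"
  write_manifest(bad2, mpath)
  expect_error(load_dataset(mpath), "nowhere.csv")

  # empty manifest warns and returns empty
  write_manifest(entries[0, ], mpath)
  expect_warning(ds3 <- load_dataset(mpath), "empty manifest")
  expect_length(ds3, 0)
})

test_that("window set validates ordering and binds consistently", {
  w1 <- window_set(array(1, c(3, 2, 10)), labels = c(0, 0, 0),
                   subject_ids = rep("S1", 3), trial_ids = rep("a", 3),
                   window_order = 1:3)
  w2 <- window_set(array(2, c(2, 2, 10)), labels = c(1, 1),
                   subject_ids = rep("S1", 2), trial_ids = rep("b", 2),
                   window_order = 1:2)
  expect_error(window_set(array(1, c(2, 2, 10)), c(0, 0), rep("S1", 2),
                          rep("a", 2), c(2, 1)), "not increasing")
  b <- bind_windows(list(w1, w2))
  expect_equal(dim(b$windows), c(5, 2, 10))
  expect_equal(b$labels, c(0L, 0L, 0L, 1L, 1L))
  sub <- subset_windows(b, c(4, 1))
  expect_equal(sub$labels, c(1L, 0L))
  expect_error(bind_windows(list(w1, window_set(array(0, c(1, 3, 10)), 0,
                                                "S1", "c", 1))),
               "inconsistent")
})
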