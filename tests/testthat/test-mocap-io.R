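test_that("csv and trc files round-trip coordinates to 1e-9", {
  ms <- synthetic_markerset(5)
  tr <- random_trial(n = 12, markerset = ms, fps = 250, seed = 2)
  for (fmt in c("csv", "trc")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_trial(tr, path)
    back <- read_trial(path, ms, frame_rate = 250, signer_id = "s1")
    expect_equal(back$coords, tr$coords, tolerance = 1e-12)
    expect_lt(max(abs(back$coords - tr$coords)), 1e-9)
    expect_equal(back$frame_rate, 250)
  }
})

test_that("trc frame rate comes from the header, csv requires it", {
  ms <- synthetic_markerset(4)
  tr <- random_trial(n = 8, markerset = ms, fps = 120, seed = 3)
  trc <- withr::local_tempfile(fileext = ".trc")
  write_trial(tr, trc)
  expect_equal(read_trial(trc, ms)$frame_rate, 120)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, csv)
  expect_error(read_trial(csv, ms), "frame.rate|frame_rate")
})

test_that("a marker absent from the file is reported by name", {
  ms <- synthetic_markerset(4)
  tr <- random_trial(n = 5, markerset = ms, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, path)
  bigger <- marker_set(c(ms$names, "L elbow"), origin = "pelvis")
  expect_error(read_trial(path, bigger, frame_rate = 100), "L elbow")
})

test_that("missing coordinates are a hard error listing frame indices", {
  ms <- synthetic_markerset(3)
  coords <- array(1, dim = c(6, 3, 3))
  coords[3, 2, 1] <- NA
  coords[5, 1, 3] <- NA
  expect_error(mocap_trial(coords, ms, 100), "3, 5")
})

test_that("c3d input is rejected with conversion advice", {
  expect_error(read_trial("x.c3d", synthetic_markerset(3)), "TRC or CSV")
})

test_that("pelvis referencing zeroes the origin and is idempotent", {
  ms <- synthetic_markerset(4)
  # all markers riding on the pelvis trajectory -> all zeros
  set.seed(5)
  pel <- matrix(rnorm(30), 10, 3)
  coords <- array(0, dim = c(10, 4, 3))
  for (m in 1:4) coords[, m, ] <- pel
  tr <- reference_to_origin(mocap_trial(coords, ms, 100))
  expect_equal(max(abs(tr$coords)), 0)

  # static offset example: pelvis (1,2,3), marker at (1,2,4) -> (0,0,1)
  coords2 <- array(0, dim = c(4, 4, 3))
  coords2[, 1, ] <- matrix(c(1, 2, 3), 4, 3, byrow = TRUE)
  coords2[, 2, ] <- matrix(c(1, 2, 4), 4, 3, byrow = TRUE)
  tr2 <- reference_to_origin(mocap_trial(coords2, ms, 100))
  expect_equal(unname(tr2$coords[1, 2, ]), c(0, 0, 1))

  # idempotence and per-frame inter-marker distance preservation
  raw <- random_trial(n = 20, markerset = ms, seed = 6)
  once <- reference_to_origin(raw)
  twice <- reference_to_origin(once)
  expect_identical(once$coords, twice$coords)
  d_raw <- dist(raw$coords[7, , ])
  d_ref <- dist(once$coords[7, , ])
  expect_lt(max(abs(d_raw - d_ref)), 1e-12)
})

test_that("segment extraction takes round(duration * fps) frames", {
  ms <- synthetic_markerset(3)
  tr <- random_trial(n = 1500, markerset = ms, fps = 250, seed = 7)
  seg <- extract_segment(tr, 0, 5)
  expect_equal(dim(seg$coords)[1], 1250)
  expect_equal(seg$coords, tr$coords[1:1250, , , drop = FALSE])
  # full-trial window is the identity
  all_of_it <- extract_segment(tr, 0, 1500 / 250)
  expect_identical(all_of_it$coords, tr$coords)
  # offset window
  seg2 <- extract_segment(tr, 1, 2)
  expect_equal(seg2$coords, tr$coords[251:750, , , drop = FALSE])
  expect_error(extract_segment(tr, 2, 5), "6 s available")
})

test_that("posture matrix assembly: shapes, segments, and slicing", {
  ms <- synthetic_markerset(8)   # 7 moving markers -> 21 columns
  trials <- lapply(1:4, function(k) {
    reference_to_origin(random_trial(n = 25, markerset = ms, seed = k,
                                     signer_id = "s1",
                                     trial_id = paste0("t", k)))
  })
  pm <- build_posture_matrix(trials)
  expect_equal(dim(pm), c(100, 21))
  segs <- attr(pm, "segments")
  # segments partition the rows exactly: contiguous, no gap, no overlap
  expect_equal(segs$start, c(1, 26, 51, 76))
  expect_equal(segs$end, c(25, 50, 75, 100))
  # per-segment slicing recovers each trial's frames exactly
  for (k in 1:4) {
    rows <- segment_rows(pm, "s1", paste0("t", k))
    flat <- matrix(aperm(trials[[k]]$coords[, -1, , drop = FALSE],
                         c(1, 3, 2)), nrow = 25)
    expect_equal(unname(pm[rows, ]), unname(flat))
  }
  # single 1-frame trial
  one <- reference_to_origin(random_trial(n = 1, markerset = ms, seed = 9))
  pm1 <- build_posture_matrix(list(one))
  expect_equal(dim(pm1), c(1, 21))
  # keeping the origin adds its three zero columns
  pm_full <- build_posture_matrix(trials, drop_origin = FALSE)
  expect_equal(ncol(pm_full), 24)
  expect_equal(max(abs(pm_full[, 1:3])), 0)
})

test_that("assembly rejects mixed frame rates and unreferenced trials", {
  ms <- synthetic_markerset(3)
  a <- reference_to_origin(random_trial(n = 5, markerset = ms, fps = 100))
  b <- reference_to_origin(random_trial(n = 5, markerset = ms, fps = 120,
                                        seed = 2, trial_id = "t2"))
  expect_error(build_posture_matrix(list(a, b)), "mixed frame rates")
  raw <- random_trial(n = 5, markerset = ms, seed = 3)
  expect_error(build_posture_matrix(list(raw)), "not pelvis-referenced")
})
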