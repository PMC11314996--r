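test_that("spike correction replaces only in-interval samples", {
  # constant trace: all modes give back the constant trace
  rec <- const_recording(100)
  dirty <- rec; dirty$x[50] <- dirty$x[50] + 200
  iv <- artifact_row("transient_spike", 49, 50)
  for (mode in c("post", "pre", "bridge")) {
    fixed <- correct_spike(dirty, iv, mode)
    expect_equal(fixed$x, rec$x, info = mode)
    expect_equal(fixed$y, rec$y, info = mode)
  }

  # mode=post takes the first trusted post-interval value everywhere inside
  ramp <- gaze_recording(0:99, 0:99, rep(0, 100))
  dirty2 <- ramp
  dirty2$x[40:42] <- 900; dirty2$y[40:42] <- 520
  iv2 <- artifact_row("transient_spike", 39, 42)
  fixed2 <- correct_spike(dirty2, iv2, "post")
  expect_true(all(fixed2$x[40:42] == ramp$x[43]))
  # everything outside the interval is untouched
  expect_identical(fixed2$x[-(40:42)], dirty2$x[-(40:42)])

  # full-record interval is uncorrectable
  allbad <- const_recording(5)
  expect_error(correct_spike(allbad, artifact_row("transient_spike", -1, 10)),
               "uncorrectable")
})

test_that("injected spikes on a constant trace are recovered exactly", {
  clean <- const_recording(5000)
  it <- inject_artifacts(clean, list(n_spikes = 5), seed = 2)
  res <- clean_recording(it$dirty)
  expect_equal(rmse_recordings(res$recording, clean), 0)
})

test_that("displacement correction reintegrates the within-interval motion", {
  # constant offset on a linear ramp: ground truth recovered exactly
  ramp <- gaze_recording(0:199, 2 * (0:199), 0.5 * (0:199))
  dirty <- ramp
  dirty$x[100:149] <- dirty$x[100:149] + 100
  iv <- artifact_row("spatial_displacement", 99, 149)
  fixed <- correct_displacement(dirty, iv)
  expect_equal(fixed$x, ramp$x, tolerance = 1e-12)
  expect_equal(fixed$y, ramp$y, tolerance = 1e-12)

  # zero offset: identity
  expect_equal(correct_displacement(ramp, iv)$x, ramp$x)

  # known within-interval motion d(t): gaze wanders and returns to its
  # correct position; the recorded interval is offset by +150 px.
  # corrected(t) = p0 + cumulative sum of the within-interval derivative
  d <- c(0, 5 * sin(seq(0, 2 * pi, length.out = 49)))  # closes back to p0
  truth <- const_recording(200)
  truth$x[100:149] <- truth$x[99] + cumsum(d)
  dirty2 <- truth
  dirty2$x[100:149] <- dirty2$x[100:149] + 150
  iv2 <- artifact_row("spatial_displacement", 99, 149)
  fixed2 <- correct_displacement(dirty2, iv2)
  p0 <- truth$x[99]
  interior <- diff(dirty2$x[100:149])
  expect_equal(fixed2$x[101:149], p0 + cumsum(interior), tolerance = 1e-9)
  expect_equal(fixed2$x, truth$x, tolerance = 1e-9)

  # unterminated intervals are refused
  ivu <- artifact_row("spatial_displacement", 99, 149, note = "unterminated")
  expect_error(correct_displacement(dirty, ivu), "unterminated")
})

test_that("blink correction interpolates the padded window", {
  # flat anchors: refill equals the constant
  rec <- const_recording(2000)
  rec$x[800:900] <- NA; rec$y[800:900] <- NA; rec$valid[800:900] <- FALSE
  iv <- detect_blink_intervals(rec)
  fixed <- correct_blink(rec, iv[1, ], pad_ms = 200)
  expect_true(all(fixed$valid))
  expect_true(all(fixed$x == 840))

  # anchors on a constant-slope line: refilled samples lie exactly on it
  m <- 0.25
  lin <- gaze_recording(0:1999, m * (0:1999), rep(5, 2000))
  lin$valid[800:900] <- FALSE
  fx <- correct_blink(lin, detect_blink_intervals(lin)[1, ], pad_ms = 200)
  expect_equal(fx$x, m * (0:1999), tolerance = 1e-9)

  # boundary gap: nearest-valid hold, no extrapolation
  edge <- const_recording(500)
  edge$valid[1:50] <- FALSE
  fe <- correct_blink(edge, detect_blink_intervals(edge)[1, ], pad_ms = 100)
  expect_true(all(fe$valid))
  expect_true(all(fe$x[1:50] == 840))

  none <- gaze_recording(0:4, rep(NA, 5), rep(NA, 5), rep(FALSE, 5))
  expect_error(correct_blink(none, artifact_row("blink", 1, 2)),
               "uncorrectable")
})

test_that("clean_recording is the identity on artifact-free input", {
  spiral <- generate_spiral_trace()
  res <- clean_recording(spiral)
  expect_identical(res$recording$x, spiral$x)
  expect_identical(res$recording$y, spiral$y)
  rep <- as.data.frame(res$report)
  expect_true(all(rep == 0))
})

test_that("clean_recording counts injected artifacts and removes them", {
  fx <- generate_fixation_trace(60000, noise_sd = 0, seed = 5)
  it <- inject_artifacts(fx, list(n_spikes = 2, n_displacements = 1,
                                  n_blinks = 3), seed = 5)
  res <- clean_recording(it$dirty)
  expect_equal(res$report$n_blinks, 3)
  expect_equal(res$report$n_spikes, 2)
  expect_equal(res$report$n_displacements, 1)
  expect_equal(sum(!res$recording$valid), 0)
  v <- compute_velocity(res$recording)
  expect_true(all(v$speed[v$defined] <= 40))
  # noise-free constant base: exact recovery
  expect_equal(rmse_recordings(res$recording, it$clean), 0)
})

test_that("cleaning is idempotent and conserves the time base", {
  set.seed(31)
  for (s in c(3, 17, 29)) {
    it <- inject_artifacts(generate_fixation_trace(30000, seed = s),
                           list(n_spikes = 2, n_displacements = 2,
                                n_blinks = 2), seed = s)
    r1 <- clean_recording(it$dirty)
    expect_identical(r1$recording$t, it$dirty$t)
    expect_length(r1$recording, length(it$dirty))
    r2 <- clean_recording(r1$recording)
    expect_true(all(as.data.frame(r2$report) == 0))
    expect_identical(r2$recording$x, r1$recording$x)
    expect_identical(r2$recording$y, r1$recording$y)
  }
})

test_that("blink-protocol traces clean to zero invalid and sub-threshold speed", {
  bt <- generate_blink_protocol(seed = 9)
  res <- clean_recording(bt$dirty)
  expect_equal(sum(!res$recording$valid), 0)
  v <- compute_velocity(res$recording)
  expect_true(all(v$speed[v$defined] <= 40))
  expect_equal(res$report$n_blinks, nrow(bt$artifacts))
})
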