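test_that("fixation generator is seeded, calibrated and noise-free at sd 0", {
  flat <- generate_fixation_trace(1000, noise_sd = 0, seed = 1)
  expect_true(all(flat$x == 840) && all(flat$y == 525))

  a <- generate_fixation_trace(5000, seed = 42)
  b <- generate_fixation_trace(5000, seed = 42)
  expect_identical(a$x, b$x)

  long <- generate_fixation_trace(60000, noise_sd = 2, seed = 7)
  expect_equal(sd(long$x), 2, tolerance = 0.05)
  expect_equal(sd(long$y), 2, tolerance = 0.05)
})

test_that("spiral starts at center, grows monotonically and stays clean", {
  geom <- screen_geometry()
  sp <- generate_spiral_trace(geom = geom)
  expect_equal(c(sp$x[1], sp$y[1]), c(840, 525))
  r <- sqrt((sp$x - 840)^2 + (sp$y - 525)^2)
  expect_true(all(diff(r) >= -1e-9))
  expect_true(all(sp$x >= 0 & sp$x < 1680 & sp$y >= 0 & sp$y < 1050))
  v <- compute_velocity(sp)
  # constant path speed up to the arc-length inversion's numerical accuracy
  expect_lte(max(v$speed, na.rm = TRUE), 0.5 * (1 + 1e-5))
  # cleaning a pure spiral changes nothing
  res <- clean_recording(sp)
  expect_identical(res$recording$x, sp$x)
  # an over-tight pitch is refused
  expect_error(generate_spiral_trace(duration_ms = 60000, max_speed = 5,
                                     pitch_px = 50, geom = geom),
               "config error")
})

test_that("blink protocol produces ~1 blink/s with exact truth recovery", {
  bt <- generate_blink_protocol(duration_ms = 20000, seed = 2)
  expect_gte(nrow(bt$artifacts), 18)
  expect_lte(nrow(bt$artifacts), 22)
  det <- detect_blink_intervals(bt$dirty)
  expect_equal(det$start_ms, bt$artifacts$start_ms)
  expect_equal(det$end_ms, bt$artifacts$end_ms)
  cleaned <- clean_recording(bt$dirty)$recording
  expect_equal(sum(!cleaned$valid), 0)
})

test_that("artifact injection differs from clean exactly on truth intervals", {
  clean <- generate_fixation_trace(30000, noise_sd = 0, seed = 3)
  none <- inject_artifacts(clean, list(), seed = 3)
  expect_identical(none$dirty$x, clean$x)
  expect_equal(nrow(none$artifacts), 0L)

  it <- inject_artifacts(clean, list(n_spikes = 2, n_displacements = 2,
                                     n_blinks = 2), seed = 3)
  differs <- (it$dirty$x != clean$x | it$dirty$y != clean$y |
                !it$dirty$valid)
  differs[is.na(differs)] <- TRUE
  # padded truth intervals: blink flanking excursions extend 100 ms each side
  inside <- rep(FALSE, length(clean))
  for (k in seq_len(nrow(it$artifacts))) {
    pad <- if (it$artifacts$kind[k] == "blink") 100 else 0
    inside <- inside | (clean$t >= it$artifacts$start_ms[k] - pad &
                          clean$t <= it$artifacts$end_ms[k] + pad)
  }
  expect_true(all(inside[differs]))

  # displacements are a constant offset of the requested magnitude
  disp <- it$artifacts[it$artifacts$kind == "spatial_displacement", ]
  for (k in seq_len(nrow(disp))) {
    idx <- clean$t >= disp$start_ms[k] & clean$t < disp$end_ms[k]
    dx <- unique(round(it$dirty$x[idx] - clean$x[idx], 9))
    dy <- unique(round(it$dirty$y[idx] - clean$y[idx], 9))
    expect_length(dx, 1L)
    expect_equal(sqrt(dx^2 + dy^2), 150, tolerance = 1e-9)
  }
})

test_that("injection is deterministic and refuses impossible placements", {
  clean <- generate_fixation_trace(10000, seed = 4)
  a <- inject_artifacts(clean, list(n_spikes = 3), seed = 9)
  b <- inject_artifacts(clean, list(n_spikes = 3), seed = 9)
  expect_identical(a$dirty$x, b$dirty$x)
  expect_identical(a$artifacts, b$artifacts)

  short <- generate_fixation_trace(3000, seed = 4)
  expect_error(inject_artifacts(short, list(n_blinks = 8), seed = 1),
               "config error")
})

test_that("scoring matches detections to truth one-to-one", {
  truth <- artifact_row(c("blink", "transient_spike"), c(100, 500),
                        c(200, 503))
  perfect <- score_against_truth(truth, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  none <- score_against_truth(empty_artifacts(), truth)
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 1)  # by convention, flagged
  expect_true(none$degenerate)

  # kind mismatch does not match even with aligned midpoints
  wrong <- artifact_row("transient_spike", 100, 200)
  sc <- score_against_truth(wrong, artifact_row("blink", 100, 200))
  expect_equal(sc$recall, 0)
})

test_that("group sessions track adherence, decay and determinism", {
  sched <- build_default_schedule()
  geom <- screen_geometry()
  aois <- default_aois(geom)

  # full adherence, no noise: rates at 1 up to the saccade-transition share
  g1 <- generate_group_session(n_subjects = 1, rate_hz = 100, noise_sd = 0,
                               adherence = c(Center = 1, AJ = 1, NOAJ = 1),
                               seed = 2)[[1]]
  tr <- trial_rates(g1$clean, sched, aois)
  expect_true(all(tr$rate >= 0.99))

  # linear decay yields monotone decreasing Center trial rates
  g2 <- generate_group_session(n_subjects = 4, rate_hz = 100,
                               adherence = c(Center = 0.9, AJ = 0.5,
                                             NOAJ = 0.5),
                               decay = c(Center = 0.2), seed = 6)
  rates <- sapply(g2, function(s) {
    tr <- trial_rates(s$clean, sched, aois)
    tr$rate[tr$condition == "Center"]
  })
  expect_true(all(diff(rowMeans(rates)) < 0))

  # same seed reproduces the cohort bit for bit
  h1 <- generate_group_session(n_subjects = 2, rate_hz = 50, seed = 10)
  h2 <- generate_group_session(n_subjects = 2, rate_hz = 50, seed = 10)
  expect_identical(h1[[1]]$clean$x, h2[[1]]$clean$x)
  expect_identical(h1[[2]]$clean$x, h2[[2]]$clean$x)

  # generated traces never self-trigger the detector
  v <- compute_velocity(h1[[1]]$clean)
  expect_lt(max(v$speed, na.rm = TRUE), 40)
})
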