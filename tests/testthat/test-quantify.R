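make_session_rec <- function(x, y, valid = NULL, by_ms = 10) {
  t <- seq(0, 279999, by = by_ms)
  n <- length(t)
  gaze_recording(t, rep_len(x, n), rep_len(y, n),
                 if (is.null(valid)) NULL else rep_len(valid, n))
}

test_that("onscreen rate counts valid in-bound samples against all samples", {
  geom <- screen_geometry()
  sched <- build_default_schedule()
  rec <- make_session_rec(840, 525)
  lab <- assign_condition(rec, sched)
  expect_equal(onscreen_rate(rec, geom, lab, "Center"), 1.0)

  # 9 of 10 on-screen, one at x = 1700
  rec2 <- gaze_recording(0:9, c(rep(840, 9), 1700), rep(525, 10))
  lab2 <- assign_condition(rec2, sched)
  expect_equal(onscreen_rate(rec2, geom, lab2, "AJ"), 0.9)

  # invalid samples count against the rate
  rec3 <- gaze_recording(0:9, rep(840, 10), rep(525, 10),
                         c(rep(TRUE, 8), FALSE, FALSE))
  lab3 <- assign_condition(rec3, sched)
  expect_equal(onscreen_rate(rec3, geom, lab3, "AJ"), 0.8)

  expect_error(onscreen_rate(rec3, geom, lab3, "Center"), "undefined rate")
})

test_that("screen bounds are half-open", {
  geom <- screen_geometry()
  sched <- build_default_schedule()
  rec <- gaze_recording(0:3, c(0, 1679.99, 1680, -0.01), c(0, 1049.99, 10, 10))
  lab <- assign_condition(rec, sched)
  expect_equal(onscreen_rate(rec, geom, lab, "AJ"), 0.5)
})

test_that("AOI rate equals onscreen rate for a full-screen AOI", {
  geom <- screen_geometry()
  sched <- build_default_schedule()
  full <- aoi_set("screen", 0, 1680, 0, 1050, "Center")
  set.seed(3)
  rec <- make_session_rec(runif(28000, 0, 1680), runif(28000, 0, 1050))
  lab <- assign_condition(rec, sched)
  expect_equal(aoi_rate(rec, full, lab, "Center"),
               onscreen_rate(rec, geom, lab, "Center"))
})

test_that("AOI rate matches area fraction for uniform gaze (Monte Carlo)", {
  sched <- build_default_schedule()
  # AOI covering exactly 25% of the screen
  quarter <- aoi_set("q", 0, 840, 0, 525, "Center")
  set.seed(12)
  rec <- make_session_rec(runif(28000, 0, 1680), runif(28000, 0, 1050))
  lab <- assign_condition(rec, sched, t0_ms = 0)
  sel <- sum(lab$condition == "Center")  # 8000 uniform draws score the AOI
  got <- aoi_rate(rec, quarter, lab, "Center")
  expect_equal(got, 0.25, tolerance = 3 * sqrt(0.25 * 0.75 / sel) / 0.25)
})

test_that("AOI membership is half-open on box corners", {
  sched <- build_default_schedule()
  box <- aoi_set("b", 100, 200, 100, 200, "AJ")
  rec <- gaze_recording(0:1, c(100, 200), c(100, 200))
  lab <- assign_condition(rec, sched)
  expect_equal(aoi_rate(rec, box, lab, "AJ"), 0.5)
  expect_error(aoi_rate(rec, box, lab, "NOAJ"), "config error")
})

test_that("trial rates aggregate occurrences by trial position", {
  geom <- screen_geometry()
  sched <- build_default_schedule()
  aois <- default_aois(geom)
  # homogeneous adherence: gaze glued to the cross center; Center rates all 1
  rec <- make_session_rec(840, 525)
  tr <- trial_rates(rec, sched, aois)
  expect_equal(tr$rate[tr$condition == "Center"], rep(1, 4))
  expect_equal(tr$trial[tr$condition == "AJ"], 1:5)
  expect_equal(tr$trial[tr$condition == "Center"], 1:4)

  # adherence only in Center occurrence 1
  t <- seq(0, 279999, by = 10)
  on_cross <- t >= 50000 & t < 70000  # first Center block
  rec2 <- gaze_recording(t, ifelse(on_cross, 840, 10),
                         ifelse(on_cross, 525, 10))
  tr2 <- trial_rates(rec2, sched, aois)
  expect_equal(tr2$rate[tr2$condition == "Center"], c(1, 0, 0, 0))
})

test_that("rates are invariant to uniform temporal subsampling", {
  geom <- screen_geometry()
  sched <- build_default_schedule()
  aois <- default_aois(geom)
  g <- generate_group_session(n_subjects = 1, rate_hz = 100, seed = 8)[[1]]
  lab <- assign_condition(g$clean, sched)
  full <- aoi_rate(g$clean, aois, lab, "Center")
  sub <- gaze_recording(g$clean$t[c(TRUE, FALSE)], g$clean$x[c(TRUE, FALSE)],
                        g$clean$y[c(TRUE, FALSE)], sampling_rate_hz = 50)
  lab_s <- assign_condition(sub, sched)
  expect_equal(aoi_rate(sub, aois, lab_s, "Center"), full, tolerance = 0.05)
})

test_that("adherence table has the expected shape and direction", {
  geom <- screen_geometry()
  sched <- build_default_schedule()
  aois <- default_aois(geom)
  g <- generate_group_session(n_subjects = 1, rate_hz = 100,
                              artifact_spec = list(n_blinks = 6,
                                                   n_displacements = 2,
                                                   disp_offset_px = 2200),
                              seed = 13)[[1]]
  cleaned <- clean_recording(g$dirty)$recording
  tab <- adherence_table(g$dirty, cleaned, geom, sched, aois)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$onscreen_rate >= 0 & tab$onscreen_rate <= 1))
  expect_true(all(tab$task_rate <= tab$onscreen_rate))
  ori <- tab[tab$variant == "original", ]
  fil <- tab[tab$variant == "filtered", ]
  expect_true(all(fil$onscreen_rate >= ori$onscreen_rate))
})

test_that("AOI configs load and validate", {
  cfg <- list(aois = list(list(label = "cross", x_min = 740, x_max = 940,
                               y_min = 425, y_max = 625,
                               condition = "Center")))
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  a <- read_aoi_config(yml)
  expect_s3_class(a, "aoi_set")
  expect_error(aoi_set("bad", 10, 5, 0, 1, "X"), "invalid AOI")
})
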