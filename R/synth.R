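# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

new_injection_truth <- function(clean, dirty, artifacts, seed) {
  structure(list(clean = clean, dirty = dirty, artifacts = artifacts,
                 seed = seed),
            class = "injection_truth")
}

#' @export
print.injection_truth <- function(x, ...) {
  cat(sprintf("Injection truth (seed %d): %d samples, %d artifact(s) [%s]\n",
              x$seed, length(x$clean), nrow(x$artifacts),
              paste(names(table(x$artifacts$kind)),
                    table(x$artifacts$kind), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Synthetic fixation trace
#'
#' Steady fixation: Gaussian jitter around a target point at the given
#' sampling rate. Seeded and reproducible.
#'
#' @param duration_ms trace duration.
#' @param target fixation point `c(x, y)` in pixels.
#' @param noise_sd jitter standard deviation in pixels (default 1, far below
#'   what the 40 px/ms detection threshold could mistake for an artifact).
#' @param rate_hz sampling rate.
#' @param seed RNG seed.
#' @param subject_id identifier for the recording.
#' @return A [gaze_recording()].
#' @export
generate_fixation_trace <- function(duration_ms, target = c(840, 525),
                                    noise_sd = 1, rate_hz = 1000, seed = 1,
                                    subject_id = "synthetic") {
  stopifnot(duration_ms > 0, noise_sd >= 0)
  n <- floor(duration_ms * rate_hz / 1000)
  t <- (seq_len(n) - 1) * 1000 / rate_hz
  with_seed(seed, {
    x <- target[1] + stats::rnorm(n, sd = noise_sd)
    y <- target[2] + stats::rnorm(n, sd = noise_sd)
    gaze_recording(t, x, y, subject_id = subject_id,
                   sampling_rate_hz = rate_hz)
  })
}

# arc length of an Archimedean spiral r = b*theta from 0 to theta
spiral_arc <- function(theta, b) (b / 2) * (theta * sqrt(1 + theta^2) +
                                              asinh(theta))

#' Synthetic spiral-scanning trace
#'
#' The smooth-scanning validation protocol: an Archimedean spiral traced from
#' the screen center outward at constant path speed, fully on-screen, with
#' monotonically non-decreasing radius. The default pitch is derived so the
#' spiral's final radius fills `margin_frac` of the smaller half-extent of
#' the screen over the requested duration; passing `pitch_px` fixes the pitch
#' instead, and a spiral that would leave the screen is refused.
#'
#' @param duration_ms trace duration (default 20 s).
#' @param geom a [screen_geometry()].
#' @param max_speed path speed in px/ms; must stay below the detection
#'   threshold (default 0.5).
#' @param rate_hz sampling rate.
#' @param pitch_px optional spiral pitch (px per radian).
#' @param margin_frac fraction of the limiting half-extent used when the
#'   pitch is derived.
#' @param subject_id identifier.
#' @return A [gaze_recording()].
#' @export
generate_spiral_trace <- function(duration_ms = 20000,
                                  geom = screen_geometry(),
                                  max_speed = 0.5, rate_hz = 1000,
                                  pitch_px = NULL, margin_frac = 0.9,
                                  subject_id = "spiral") {
  stopifnot(duration_ms > 0, max_speed > 0)
  r_limit <- margin_frac * min(geom$width_px, geom$height_px) / 2
  total_arc <- max_speed * duration_ms
  if (is.null(pitch_px)) {
    # choose pitch so r(theta_f) = r_limit given the total arc length
    f <- function(th) spiral_arc(th, r_limit / th) - total_arc
    theta_f <- stats::uniroot(f, c(1e-3, 1e6))$root
    pitch_px <- r_limit / theta_f
  } else {
    f <- function(th) spiral_arc(th, pitch_px) - total_arc
    theta_f <- stats::uniroot(f, c(1e-3, 1e9))$root
    if (pitch_px * theta_f > min(geom$width_px, geom$height_px) / 2) {
      stop("config error: spiral exceeds the screen at this duration/pitch",
           call. = FALSE)
    }
  }
  n <- floor(duration_ms * rate_hz / 1000)
  t <- (seq_len(n) - 1) * 1000 / rate_hz
  # invert arc length -> angle on a fine grid for constant path speed
  grid <- seq(0, theta_f, length.out = max(10000L, 4L * n))
  theta <- stats::approx(spiral_arc(grid, pitch_px), grid,
                         xout = max_speed * t, rule = 2)$y
  r <- pitch_px * theta
  gaze_recording(t, geom$width_px / 2 + r * cos(theta),
                 geom$height_px / 2 + r * sin(theta),
                 subject_id = subject_id, sampling_rate_hz = rate_hz)
}

# add one blink (null run + flanking vertical excursions) to x/y/valid in
# place; returns the modified list. on_i = first invalid sample index.
add_blink <- function(tr, on_i, len_n, exc_n, excursion_px, sign) {
  n <- length(tr$valid)
  null_idx <- on_i:min(on_i + len_n - 1, n)
  pre_idx <- if (on_i > 1) seq.int(max(1, on_i - exc_n), on_i - 1)
             else integer(0)
  post0 <- min(on_i + len_n, n)
  post_idx <- seq.int(post0, min(post0 + exc_n - 1, n))
  if (length(pre_idx)) {
    ramp <- seq_along(pre_idx) / length(pre_idx)
    tr$y[pre_idx] <- tr$y[pre_idx] + sign * excursion_px * ramp
  }
  if (length(post_idx) && post0 > on_i + len_n - 1) {
    ramp <- rev(seq_along(post_idx)) / length(post_idx)
    tr$y[post_idx] <- tr$y[post_idx] + sign * excursion_px * ramp
  }
  tr$x[null_idx] <- NA; tr$y[null_idx] <- NA; tr$valid[null_idx] <- FALSE
  tr
}

#' Blink validation protocol
#'
#' The continuous-blinking validation protocol: central fixation with roughly
#' one blink per second. Each blink is a run of null samples flanked by sharp
#' vertical excursions of the recorded gaze (~0.1 s on each side, the tracker
#' losing the pupil as the lid closes). Returns the dirty trace together with
#' the clean fixation and the ground-truth blink list.
#'
#' @param duration_ms protocol length (default 20 s).
#' @param blink_rate_hz blink frequency (default 1/s).
#' @param blink_len_ms null-run length per blink.
#' @param excursion_px amplitude of the flanking vertical excursions.
#' @param excursion_ms duration of each flanking excursion.
#' @param noise_sd fixation jitter SD in pixels.
#' @param target fixation point.
#' @param rate_hz sampling rate.
#' @param seed RNG seed.
#' @return An `injection_truth` (fields `clean`, `dirty`, `artifacts`,
#'   `seed`).
#' @export
generate_blink_protocol <- function(duration_ms = 20000, blink_rate_hz = 1,
                                    blink_len_ms = 150, excursion_px = 300,
                                    excursion_ms = 100, noise_sd = 0,
                                    target = c(840, 525), rate_hz = 1000,
                                    seed = 1) {
  period <- 1000 / blink_rate_hz
  n_blinks <- floor(duration_ms / period)
  if (blink_rate_hz * blink_len_ms / 1000 > 0.5) {
    stop("blink rate x length leaves < 50% valid samples", call. = FALSE)
  }
  clean <- generate_fixation_trace(duration_ms, target, noise_sd, rate_hz,
                                   seed, "blink_protocol")
  dt <- 1000 / rate_hz
  len_n <- max(1L, round(blink_len_ms / dt))
  exc_n <- max(1L, round(excursion_ms / dt))
  n <- length(clean)
  with_seed(seed + 1, {
    jitter <- stats::runif(n_blinks, -period / 10, period / 10)
    signs <- sample(c(-1, 1), n_blinks, replace = TRUE)
    tr <- list(x = clean$x, y = clean$y, valid = clean$valid)
    rows <- vector("list", n_blinks)
    for (k in seq_len(n_blinks)) {
      on_ms <- (k - 1) * period + period / 2 + jitter[k]
      on_i <- min(max(1L, round(on_ms / dt) + 1L), n - len_n)
      tr <- add_blink(tr, on_i, len_n, exc_n, excursion_px, signs[k])
      rows[[k]] <- artifact_row("blink", clean$t[on_i],
                                clean$t[min(on_i + len_n - 1, n)])
    }
    dirty <- gaze_recording(clean$t, tr$x, tr$y, tr$valid,
                            subject_id = clean$subject_id,
                            sampling_rate_hz = rate_hz)
    new_injection_truth(clean, dirty, do.call(rbind, rows), seed)
  })
}

#' Inject ground-truth artifacts into a clean recording
#'
#' Places the requested artifacts uniformly at random without overlap
#' (including guard pads, so corrections never interact), recording every
#' injected interval as ground truth:
#' * transient spikes — excursions of 1 to `spike_len_ms` samples, amplitude
#'   `spike_amp_px` in a random direction;
#' * spatial displacements — an additive constant offset of `disp_offset_px`
#'   (random direction unless `disp_direction` is given) held for
#'   `disp_len_ms`, with the implied entry/exit jumps;
#' * blinks — null runs of `blink_len_ms` flanked by vertical excursions.
#'
#' Truth intervals use the detector's conventions: half-open
#' `[first corrupted sample, first correct sample)` for sensor artifacts,
#' closed over invalid samples for blinks.
#'
#' @param clean a [gaze_recording()] (fully valid).
#' @param spec named list: `n_spikes`, `spike_amp_px` (default 200),
#'   `spike_len_ms` (default 3), `n_displacements`, `disp_offset_px`
#'   (default 150), `disp_len_ms` (default 100), `disp_direction` (optional
#'   unit vector), `n_blinks`, `blink_len_ms` (default 150).
#' @param seed RNG seed.
#' @param guard_ms exclusion margin around each artifact (default 250 ms,
#'   larger than the blink correction pad).
#' @param excursion_px,excursion_ms blink flanking excursion shape.
#' @param max_tries placement retries before giving up.
#' @return An `injection_truth`.
#' @export
inject_artifacts <- function(clean, spec = list(), seed = 1, guard_ms = 250,
                             excursion_px = 300, excursion_ms = 100,
                             max_tries = 1000) {
  stopifnot(inherits(clean, "gaze_recording"), all(clean$valid))
  defaults <- list(n_spikes = 0, spike_amp_px = 200, spike_len_ms = 3,
                   n_displacements = 0, disp_offset_px = 150,
                   disp_len_ms = 100, disp_direction = NULL,
                   n_blinks = 0, blink_len_ms = 150)
  spec <- utils::modifyList(defaults, spec)
  n <- length(clean)
  dt <- 1000 / clean$sampling_rate_hz
  guard_n <- ceiling(guard_ms / dt)
  exc_n <- max(1L, round(excursion_ms / dt))
  kinds <- c(rep("blink", spec$n_blinks),
             rep("spatial_displacement", spec$n_displacements),
             rep("transient_spike", spec$n_spikes))
  tr <- list(x = clean$x, y = clean$y, valid = clean$valid)
  rows <- list()
  with_seed(seed, {
    taken <- matrix(numeric(0), ncol = 2)  # sample-index exclusion windows
    for (kind in kinds) {
      len_n <- switch(kind,
        transient_spike = sample(seq_len(max(1L, round(spec$spike_len_ms / dt))),
                                 1),
        spatial_displacement = max(2L, round(spec$disp_len_ms / dt)),
        blink = max(1L, round(spec$blink_len_ms / dt)))
      extra <- if (kind == "blink") exc_n else 0L
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        on_i <- sample(seq.int(guard_n + extra + 2L,
                               n - len_n - extra - guard_n - 1L), 1)
        win <- c(on_i - extra - guard_n, on_i + len_n - 1 + extra + guard_n)
        if (nrow(taken) == 0 ||
            all(win[2] < taken[, 1] | win[1] > taken[, 2])) {
          taken <- rbind(taken, win)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("config error: could not place artifacts without overlap",
             call. = FALSE)
      }
      run <- on_i:(on_i + len_n - 1)
      if (kind == "transient_spike") {
        ang <- stats::runif(1, 0, 2 * pi)
        tr$x[run] <- tr$x[run] + spec$spike_amp_px * cos(ang)
        tr$y[run] <- tr$y[run] + spec$spike_amp_px * sin(ang)
        rows[[length(rows) + 1]] <-
          artifact_row("transient_spike", clean$t[on_i],
                       clean$t[on_i + len_n])
      } else if (kind == "spatial_displacement") {
        dir <- spec$disp_direction
        if (is.null(dir)) {
          ang <- stats::runif(1, 0, 2 * pi)
          dir <- c(cos(ang), sin(ang))
        }
        tr$x[run] <- tr$x[run] + spec$disp_offset_px * dir[1]
        tr$y[run] <- tr$y[run] + spec$disp_offset_px * dir[2]
        rows[[length(rows) + 1]] <-
          artifact_row("spatial_displacement", clean$t[on_i],
                       clean$t[on_i + len_n])
      } else {
        sign <- sample(c(-1, 1), 1)
        tr <- add_blink(tr, on_i, len_n, exc_n, excursion_px, sign)
        rows[[length(rows) + 1]] <-
          artifact_row("blink", clean$t[on_i], clean$t[on_i + len_n - 1])
      }
    }
  })
  artifacts <- if (length(rows)) {
    out <- do.call(rbind, rows)
    out[order(out$start_ms), ]
  } else empty_artifacts()
  rownames(artifacts) <- NULL
  dirty <- gaze_recording(clean$t, tr$x, tr$y, tr$valid,
                          subject_id = clean$subject_id,
                          sampling_rate_hz = clean$sampling_rate_hz)
  new_injection_truth(clean, dirty, artifacts, seed)
}

#' Score detected artifacts against injected ground truth
#'
#' Greedy one-to-one matching in time order: a detected interval matches a
#' truth interval of the same kind when their midpoints lie within `tol_ms`.
#' Also computes the position RMSE between a cleaned recording and the clean
#' truth when both are supplied to [rmse_recordings()].
#'
#' @param detected,truth artifact tables.
#' @param tol_ms midpoint matching tolerance (default 10 ms).
#' @return List with `precision`, `recall`, `per_kind` (data frame:
#'   kind, n_truth, n_detected, n_matched, precision, recall) and
#'   `degenerate` (`TRUE` when `detected` is empty but truth is not;
#'   precision is then reported as 1 by convention).
#' @export
score_against_truth <- function(detected, truth, tol_ms = 10) {
  stopifnot(tol_ms >= 0)
  kinds <- union(unique(truth$kind), unique(detected$kind))
  per <- lapply(kinds, function(kind) {
    tm <- (truth$start_ms + truth$end_ms)[truth$kind == kind] / 2
    dm <- (detected$start_ms + detected$end_ms)[detected$kind == kind] / 2
    used <- rep(FALSE, length(dm))
    matched <- 0L
    for (m in sort(tm)) {
      cand <- which(!used & abs(dm - m) <= tol_ms)
      if (length(cand)) {
        used[cand[which.min(abs(dm[cand] - m))]] <- TRUE
        matched <- matched + 1L
      }
    }
    data.frame(kind = kind, n_truth = length(tm), n_detected = length(dm),
               n_matched = matched,
               precision = if (length(dm)) matched / length(dm) else 1,
               recall = if (length(tm)) matched / length(tm) else 1,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  n_det <- sum(per$n_detected); n_tru <- sum(per$n_truth)
  n_mat <- sum(per$n_matched)
  list(precision = if (n_det) n_mat / n_det else 1,
       recall = if (n_tru) n_mat / n_tru else 1,
       per_kind = per,
       degenerate = n_det == 0 && n_tru > 0)
}

#' Position RMSE between two recordings
#'
#' Root mean squared Euclidean distance between positions, over samples valid
#' in both recordings (timestamps must match).
#'
#' @param a,b [gaze_recording()]s on the same time base.
#' @return RMSE in pixels.
#' @export
rmse_recordings <- function(a, b) {
  stopifnot(length(a) == length(b), all(a$t == b$t))
  ok <- a$valid & b$valid
  if (!any(ok)) return(NA_real_)
  sqrt(mean((a$x[ok] - b$x[ok])^2 + (a$y[ok] - b$y[ok])^2))
}
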