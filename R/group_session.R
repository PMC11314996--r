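#' Simulate a multi-subject block-paradigm session cohort
#'
#' Generates one ground-truthed session per subject under a block schedule.
#' Gaze alternates between task-adherent looks (a point drawn uniformly
#' inside the trial's applicable AOI, inset from the box edge by ten noise
#' SDs) and non-adherent looks (uniform over the screen) in chunks of
#' `chunk_ms`, with Bernoulli(p) adherence per chunk. p is the condition's
#' adherence probability minus a per-trial-position linear decay,
#' `p = adherence[cond] - decay[cond] * (position - 1)`, clipped to \[0, 1\]
#' (for single-trial blocks such as Center the position is the block
#' occurrence). Transitions between looks are ramped at `speed_cap` px/ms so
#' simulated saccades stay below the artifact detection threshold, and
#' Gaussian jitter of `noise_sd` px is added throughout. Artifacts are then
#' injected per `artifact_spec` (see [inject_artifacts()]).
#'
#' @param n_subjects cohort size (default 16).
#' @param sched a [block_schedule()].
#' @param geom a [screen_geometry()].
#' @param aois an [aoi_set()].
#' @param adherence named per-condition adherence probabilities. The defaults
#'   mirror task-adherence levels typical of this paradigm (cross fixation
#'   ~0.70, object conditions ~0.46-0.47).
#' @param decay named per-condition linear decay per trial position.
#' @param artifact_spec `NULL` (no artifacts) or a spec list for
#'   [inject_artifacts()].
#' @param rate_hz sampling rate (reduce for large replicate batteries; all
#'   rate metrics are sampling-rate-invariant).
#' @param chunk_ms look duration.
#' @param noise_sd fixation jitter SD in pixels.
#' @param speed_cap transition speed in px/ms (default 32, under the 40 px/ms
#'   threshold).
#' @param seed RNG seed; subject s uses a stream derived from `seed`.
#' @return List of `injection_truth`, one per subject (`clean == dirty` when
#'   `artifact_spec` is `NULL`).
#' @export
generate_group_session <- function(n_subjects = 16,
                                   sched = build_default_schedule(),
                                   geom = screen_geometry(),
                                   aois = default_aois(geom),
                                   adherence = c(Center = 0.70, AJ = 0.46,
                                                 NOAJ = 0.47),
                                   decay = c(Center = 0, AJ = 0, NOAJ = 0),
                                   artifact_spec = NULL,
                                   rate_hz = 1000, chunk_ms = 250,
                                   noise_sd = 1, speed_cap = 32, seed = 1) {
  stopifnot(all(adherence >= 0), all(adherence <= 1))
  trials <- sched$trials
  conds <- unique(trials$condition)
  missing_p <- setdiff(conds, names(adherence))
  if (length(missing_p)) {
    stop("adherence probability missing for condition(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  # repeated-measure position per trial row (trial index, or block occurrence
  # for single-trial blocks)
  slot <- integer(nrow(trials))
  for (cond in conds) {
    sel <- trials$condition == cond
    if (max(trials$trial_index[sel]) > 1) {
      slot[sel] <- trials$trial_index[sel]
    } else {
      blocks <- sort(unique(trials$block_index[sel]))
      slot[sel] <- match(trials$block_index[sel], blocks)
    }
  }
  # applicable AOI box per trial row (first match on condition + side)
  box <- matrix(NA_real_, nrow(trials), 4)
  for (k in seq_len(nrow(trials))) {
    hit <- which(aois$condition == trials$condition[k] &
                   (is.na(aois$side) | (!is.na(trials$side[k]) &
                                          aois$side == trials$side[k])))
    if (!length(hit)) {
      stop("config error: no AOI applies to condition '",
           trials$condition[k], "'", call. = FALSE)
    }
    a <- aois[hit[1], ]
    box[k, ] <- c(a$x_min, a$x_max, a$y_min, a$y_max)
  }
  inset <- 10 * noise_sd
  dt <- 1000 / rate_hz
  n <- floor(sched$session_duration_ms * rate_hz / 1000)
  t <- (seq_len(n) - 1) * dt
  dec <- function(cond) if (cond %in% names(decay)) decay[[cond]] else 0
  subjects <- with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    tx <- numeric(n); ty <- numeric(n)
    prev_x <- geom$width_px / 2; prev_y <- geom$height_px / 2
    for (k in seq_len(nrow(trials))) {
      p <- min(1, max(0, adherence[[trials$condition[k]]] -
                           dec(trials$condition[k]) * (slot[k] - 1)))
      i0 <- floor(trials$start_ms[k] / dt) + 1
      i1 <- min(n, floor((trials$start_ms[k] + trials$duration_ms[k]) / dt))
      if (i0 > i1) next
      n_chunks <- max(1L, ceiling((i1 - i0 + 1) * dt / chunk_ms))
      bounds <- unique(round(seq(i0, i1 + 1, length.out = n_chunks + 1)))
      adhere <- stats::runif(length(bounds) - 1) < p
      for (ci in seq_len(length(bounds) - 1)) {
        lo <- bounds[ci]; hi <- bounds[ci + 1] - 1
        if (adhere[ci]) {
          gx <- stats::runif(1, box[k, 1] + inset, box[k, 2] - inset)
          gy <- stats::runif(1, box[k, 3] + inset, box[k, 4] - inset)
        } else {
          gx <- stats::runif(1, 0, geom$width_px - 1)
          gy <- stats::runif(1, 0, geom$height_px - 1)
        }
        tx[lo:hi] <- gx; ty[lo:hi] <- gy
        # ramp in from the previous look at sub-threshold speed
        dist <- sqrt((gx - prev_x)^2 + (gy - prev_y)^2)
        ramp_n <- min(hi - lo + 1, ceiling(dist / (speed_cap * dt)))
        if (ramp_n > 1) {
          w <- seq_len(ramp_n) / ramp_n
          idx <- lo:(lo + ramp_n - 1)
          tx[idx] <- prev_x + w * (gx - prev_x)
          ty[idx] <- prev_y + w * (gy - prev_y)
        }
        prev_x <- gx; prev_y <- gy
      }
    }
    if (noise_sd > 0) {
      tx <- tx + stats::rnorm(n, sd = noise_sd)
      ty <- ty + stats::rnorm(n, sd = noise_sd)
    }
    clean <- gaze_recording(t, tx, ty,
                            subject_id = sprintf("S%02d", s),
                            sampling_rate_hz = rate_hz)
    if (is.null(artifact_spec)) {
      new_injection_truth(clean, clean, empty_artifacts(), seed)
    } else {
      inject_artifacts(clean, artifact_spec,
                       seed = (seed * 131 + s) %% 2147483647)
    }
  }))
  subjects
}
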