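# index helpers for the interval conventions:
#   sensor artifacts are half-open [start_ms, end_ms) over sample times,
#   blinks are closed [start_ms, end_ms] over the invalid samples.
idx_inside_halfopen <- function(rec, iv) {
  which(rec$t >= iv$start_ms & rec$t < iv$end_ms)
}

#' Correct a transient spike
#'
#' Replaces the samples inside a spike interval. The default (`mode =
#' "post"`) substitutes the first trusted sample at/after the interval end —
#' the spike "returns to the correct trajectory", so the final moment's data
#' are correct. `mode = "pre"` holds the last trusted pre-onset sample;
#' `mode = "bridge"` interpolates linearly between the two anchors. All
#' samples outside the interval are returned bit-identical.
#'
#' @param rec a [gaze_recording()].
#' @param iv one artifact-table row with `kind == "transient_spike"`
#'   (a one-row data frame or a list with `start_ms`, `end_ms`).
#' @param mode replacement scheme, one of `"post"`, `"pre"`, `"bridge"`.
#' @return The corrected [gaze_recording()].
#' @export
correct_spike <- function(rec, iv, mode = c("post", "pre", "bridge")) {
  stopifnot(inherits(rec, "gaze_recording"))
  mode <- match.arg(mode)
  inside <- idx_inside_halfopen(rec, iv)
  if (!length(inside)) return(rec)
  pre <- if (min(inside) > 1) min(inside) - 1L else NA_integer_
  post <- if (max(inside) < length(rec)) max(inside) + 1L else NA_integer_
  if (is.na(pre) && is.na(post)) {
    stop("uncorrectable spike: interval touches both record boundaries",
         call. = FALSE)
  }
  if (mode == "post" && is.na(post)) {
    stop("uncorrectable spike: no trusted sample after interval (mode=post)",
         call. = FALSE)
  }
  if (mode == "pre" && is.na(pre)) {
    stop("uncorrectable spike: no trusted sample before interval (mode=pre)",
         call. = FALSE)
  }
  if (mode == "bridge" && (is.na(pre) || is.na(post))) {
    stop("uncorrectable spike: bridge mode needs both anchors", call. = FALSE)
  }
  if (mode == "post") {
    rec$x[inside] <- rec$x[post]; rec$y[inside] <- rec$y[post]
  } else if (mode == "pre") {
    rec$x[inside] <- rec$x[pre]; rec$y[inside] <- rec$y[pre]
  } else {
    w <- (rec$t[inside] - rec$t[pre]) / (rec$t[post] - rec$t[pre])
    rec$x[inside] <- rec$x[pre] + w * (rec$x[post] - rec$x[pre])
    rec$y[inside] <- rec$y[pre] + w * (rec$y[post] - rec$y[pre])
  }
  rec
}

#' Correct a spatial displacement
#'
#' During a spatial displacement the recorded position is offset but the
#' relative motion (first derivative) remains accurate, and the gaze returns
#' to the correct position at the interval end. The within-interval motion is
#' therefore kept and only the level is fixed: the entry and exit jumps are
#' both artifactual, so the offset removed from the interval is the mean of
#' the entry jump and the negated exit jump (per axis). This symmetric
#' boundary condition equals plain reintegration from the last pre-onset
#' position on a steady base and is exact for a constant-offset artifact on
#' any base with equal motion across the two jumps (constant or linear-ramp
#' trajectories included). Samples after the interval are the raw, trusted
#' positions.
#'
#' @param rec a [gaze_recording()].
#' @param iv one artifact-table row with `kind == "spatial_displacement"`;
#'   rows noted `"unterminated"` are uncorrectable.
#' @return The corrected [gaze_recording()].
#' @export
correct_displacement <- function(rec, iv) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (!is.null(iv$note) && identical(iv$note, "unterminated")) {
    stop("uncorrectable displacement: unterminated interval", call. = FALSE)
  }
  inside <- idx_inside_halfopen(rec, iv)
  if (!length(inside)) return(rec)
  i0 <- min(inside); i1 <- max(inside)
  if (i0 == 1 || i1 == length(rec)) {
    stop("uncorrectable displacement: interval touches record boundary",
         call. = FALSE)
  }
  entry_x <- rec$x[i0] - rec$x[i0 - 1]
  entry_y <- rec$y[i0] - rec$y[i0 - 1]
  exit_x <- rec$x[i1 + 1] - rec$x[i1]
  exit_y <- rec$y[i1 + 1] - rec$y[i1]
  off_x <- (entry_x - exit_x) / 2
  off_y <- (entry_y - exit_y) / 2
  rec$x[inside] <- rec$x[inside] - off_x
  rec$y[inside] <- rec$y[inside] - off_y
  rec
}

#' Correct a blink
#'
#' Deletes the blink's null run extended by `pad_ms` on each side (covering
#' the sharp vertical excursions that flank a blink) and refills the span by
#' per-axis linear interpolation between the last valid sample before and the
#' first valid sample after the padded gap. Refilled samples become
#' `valid = TRUE`. A gap touching a record boundary is filled by holding the
#' nearest valid value (no extrapolation).
#'
#' @param rec a [gaze_recording()].
#' @param iv one artifact-table row with `kind == "blink"`.
#' @param pad_ms padding in ms on each side (default 200).
#' @return The corrected [gaze_recording()].
#' @export
correct_blink <- function(rec, iv, pad_ms = 200) {
  interpolate_span(rec, iv$start_ms - pad_ms, iv$end_ms + pad_ms)
}

# refill [lo_ms, hi_ms] (closed) by linear interpolation between the
# bracketing valid samples; hold nearest value at record boundaries
interpolate_span <- function(rec, lo_ms, hi_ms) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (!any(rec$valid)) {
    stop("uncorrectable blink: recording has no valid samples", call. = FALSE)
  }
  span <- which(rec$t >= lo_ms & rec$t <= hi_ms)
  if (!length(span)) return(rec)
  pre_ok <- which(rec$valid & rec$t < lo_ms)
  post_ok <- which(rec$valid & rec$t > hi_ms)
  pre <- if (length(pre_ok)) max(pre_ok) else NA_integer_
  post <- if (length(post_ok)) min(post_ok) else NA_integer_
  if (is.na(pre) && is.na(post)) {
    stop("uncorrectable blink: no valid anchor outside the padded span",
         call. = FALSE)
  }
  if (is.na(pre)) {
    rec$x[span] <- rec$x[post]; rec$y[span] <- rec$y[post]
  } else if (is.na(post)) {
    rec$x[span] <- rec$x[pre]; rec$y[span] <- rec$y[pre]
  } else {
    w <- (rec$t[span] - rec$t[pre]) / (rec$t[post] - rec$t[pre])
    rec$x[span] <- rec$x[pre] + w * (rec$x[post] - rec$x[pre])
    rec$y[span] <- rec$y[pre] + w * (rec$y[post] - rec$y[pre])
  }
  rec$valid[span] <- TRUE
  rec
}

# merge overlapping/adjacent [lo, hi] spans (matrix with columns lo, hi)
merge_spans <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  out_lo <- lo[1]; out_hi <- hi[1]
  if (length(lo) > 1) {
    for (k in 2:length(lo)) {
      if (lo[k] <= out_hi[length(out_hi)]) {
        out_hi[length(out_hi)] <- max(out_hi[length(out_hi)], hi[k])
      } else {
        out_lo <- c(out_lo, lo[k]); out_hi <- c(out_hi, hi[k])
      }
    }
  }
  cbind(lo = out_lo, hi = out_hi)
}

#' Clean a gaze recording
#'
#' Full correction pass over the three artifact classes, in the order that
#' makes each step's preconditions hold:
#' 1. detect blinks (null runs);
#' 2. delete each padded blink window (overlapping windows merged) and refill
#'    by linear interpolation — removing the flanking excursions that would
#'    otherwise spawn spurious velocity detections;
#' 3. compute velocity on the now fully valid trace;
#' 4. segment sensor artifacts by threshold + opposite-direction pairing;
#' 5. correct transient spikes and terminated spatial displacements in time
#'    order (unterminated ones are left raw and counted).
#'
#' The output preserves length and timestamps (values are replaced, never
#' resampled), contains no invalid samples, and — outside unterminated spans —
#' no speed above the threshold. The pass is idempotent: cleaning a cleaned
#' recording reports all-zero counts and returns it unchanged.
#'
#' @param rec a [gaze_recording()] with at least 2 samples.
#' @param cfg a [detector_config()].
#' @param spike_mode replacement scheme passed to [correct_spike()].
#' @return A list with elements `recording` (the cleaned [gaze_recording()]),
#'   `report` (a `clean_report`: counts of artifacts and touched samples) and
#'   `artifacts` (the combined artifact table, blinks included).
#' @export
clean_recording <- function(rec, cfg = detector_config(), spike_mode = "post") {
  stopifnot(inherits(rec, "gaze_recording"))
  if (length(rec) < 2) stop("insufficient data: need >= 2 samples",
                            call. = FALSE)
  blinks <- detect_blink_intervals(rec)
  samples_interpolated <- 0L
  out <- rec
  if (nrow(blinks)) {
    spans <- merge_spans(blinks$start_ms - cfg$blink_pad_ms,
                         blinks$end_ms + cfg$blink_pad_ms)
    for (k in seq_len(nrow(spans))) {
      touched <- sum(out$t >= spans[k, "lo"] & out$t <= spans[k, "hi"])
      samples_interpolated <- samples_interpolated + touched
      out <- interpolate_span(out, spans[k, "lo"], spans[k, "hi"])
    }
  }
  vel <- compute_velocity(out)
  arts <- segment_sensor_artifacts(vel, cfg)
  samples_replaced <- 0L
  unterminated <- 0L
  if (nrow(arts)) {
    for (k in order(arts$start_ms)) {
      iv <- arts[k, ]
      if (identical(iv$note, "unterminated")) {
        unterminated <- unterminated + 1L
        next
      }
      samples_replaced <- samples_replaced + length(idx_inside_halfopen(out, iv))
      out <- if (iv$kind == "transient_spike") {
        correct_spike(out, iv, mode = spike_mode)
      } else {
        correct_displacement(out, iv)
      }
    }
  }
  report <- structure(
    list(n_spikes = sum(arts$kind == "transient_spike"),
         n_displacements = sum(arts$kind == "spatial_displacement" &
                                 arts$note != "unterminated"),
         n_blinks = nrow(blinks),
         samples_replaced = samples_replaced,
         samples_interpolated = samples_interpolated,
         unterminated = unterminated,
         config_used = cfg),
    class = "clean_report")
  list(recording = out, report = report,
       artifacts = rbind(blinks, arts)[order(c(blinks$start_ms,
                                               arts$start_ms)), ])
}

#' @export
print.clean_report <- function(x, ...) {
  cat(sprintf(paste0("Clean report: %d spike(s), %d displacement(s), ",
                     "%d blink(s); %d sample(s) replaced, %d interpolated, ",
                     "%d unterminated\n"),
              x$n_spikes, x$n_displacements, x$n_blinks,
              x$samples_replaced, x$samples_interpolated, x$unterminated))
  invisible(x)
}

#' @export
as.data.frame.clean_report <- function(x, ...) {
  data.frame(n_spikes = x$n_spikes, n_displacements = x$n_displacements,
             n_blinks = x$n_blinks, samples_replaced = x$samples_replaced,
             samples_interpolated = x$samples_interpolated,
             unterminated = x$unterminated)
}
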