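#' Detector configuration
#'
#' Parameters of the velocity-threshold artifact detector. The speed threshold
#' is the physiological upper limit of saccade speed expressed in pixel units:
#' 0.9 deg/ms, i.e. 40 px/ms under the default [screen_geometry()]. Genuine
#' saccades are by construction sub-threshold, so anything faster is a sensor
#' artifact. Durations separate the two sensor artifact classes: excursions
#' no longer than `max_spike_ms` are transient spikes, longer ones (up to
#' `max_displacement_ms`) are spatial displacements. `blink_pad_ms` is the
#' span deleted on each side of a blink's null run, covering the ~0.1 s sharp
#' vertical excursions that flank real blinks.
#'
#' @param speed_threshold detection threshold in px/ms (default 40). Pass a
#'   [screen_geometry()] via `geom` to derive it from `threshold_deg_per_ms`.
#' @param max_spike_ms longest duration still classified as a transient spike.
#' @param max_displacement_ms longest pairing window for a displacement.
#' @param blink_pad_ms padding removed around each blink (default 200 ms).
#' @param geom optional [screen_geometry()]; if given, `speed_threshold` is
#'   derived as `deg_per_ms_to_px_per_ms(threshold_deg_per_ms, geom)`.
#' @param threshold_deg_per_ms angular threshold used with `geom`.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(speed_threshold = 40, max_spike_ms = 10,
                            max_displacement_ms = 500, blink_pad_ms = 200,
                            geom = NULL, threshold_deg_per_ms = 0.9) {
  if (!is.null(geom)) {
    speed_threshold <- deg_per_ms_to_px_per_ms(threshold_deg_per_ms, geom)
  }
  if (speed_threshold <= 0) stop("speed_threshold must be > 0", call. = FALSE)
  if (!(max_spike_ms > 0 && max_spike_ms < max_displacement_ms)) {
    stop("need 0 < max_spike_ms < max_displacement_ms", call. = FALSE)
  }
  if (blink_pad_ms < 0) stop("blink_pad_ms must be >= 0", call. = FALSE)
  structure(list(speed_threshold = speed_threshold,
                 max_spike_ms = max_spike_ms,
                 max_displacement_ms = max_displacement_ms,
                 blink_pad_ms = blink_pad_ms),
            class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf(paste0("Detector config: threshold %.3g px/ms, spike <= %g ms, ",
                     "displacement <= %g ms, blink pad %g ms\n"),
              x$speed_threshold, x$max_spike_ms, x$max_displacement_ms,
              x$blink_pad_ms))
  invisible(x)
}

#' Per-sample gaze velocity
#'
#' Backward finite difference of position per axis divided by the actual time
#' step: `v[i] = (p[i] - p[i-1]) / (t[i] - t[i-1])`, in px/ms. The first
#' sample and any sample whose backward neighbour (or itself) is invalid have
#' `defined = FALSE`. A backward (not central) difference is used so that a
#' correction at sample i never depends on later corrected values during
#' displacement reintegration.
#'
#' @param rec a [gaze_recording()] with at least 2 samples.
#' @return An object of class `velocity_trace` with fields `t`, `vx`, `vy`,
#'   `speed` (Euclidean norm) and `defined`.
#' @export
compute_velocity <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  n <- length(rec)
  if (n < 2) stop("insufficient data: need >= 2 samples", call. = FALSE)
  dt <- c(NA, diff(rec$t))
  vx <- c(NA, diff(rec$x)) / dt
  vy <- c(NA, diff(rec$y)) / dt
  defined <- rec$valid & c(FALSE, rec$valid[-n])
  vx[!defined] <- NA; vy[!defined] <- NA
  structure(list(t = rec$t, vx = vx, vy = vy,
                 speed = sqrt(vx^2 + vy^2), defined = defined),
            class = "velocity_trace")
}

# canonical empty artifact table
empty_artifacts <- function() {
  data.frame(kind = character(), start_ms = numeric(), end_ms = numeric(),
             onset_vx = numeric(), onset_vy = numeric(),
             offset_vx = numeric(), offset_vy = numeric(),
             note = character(), stringsAsFactors = FALSE)
}

artifact_row <- function(kind, start_ms, end_ms, onset_vx = NA, onset_vy = NA,
                         offset_vx = NA, offset_vy = NA, note = "") {
  data.frame(kind = kind, start_ms = start_ms, end_ms = end_ms,
             onset_vx = onset_vx, onset_vy = onset_vy,
             offset_vx = offset_vx, offset_vy = offset_vy,
             note = note, stringsAsFactors = FALSE)
}

#' Detect blink intervals
#'
#' A blink manifests as a maximal run of null (`valid = FALSE`) samples. One
#' interval is returned per run, spanning the timestamps of its first and last
#' invalid sample (closed; a single-sample run has `start_ms == end_ms`).
#' These spans are pre-padding: the flanking excursions are handled by
#' [correct_blink()]'s `pad_ms`.
#'
#' @param rec a [gaze_recording()].
#' @return Artifact table (data frame) with `kind = "blink"`; zero rows if the
#'   recording is fully valid. The union of intervals covers all and only the
#'   invalid samples.
#' @export
detect_blink_intervals <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  r <- rle(!rec$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (!length(runs)) return(empty_artifacts())
  do.call(rbind, lapply(runs, function(k) {
    artifact_row("blink", rec$t[starts[k]], rec$t[ends[k]])
  }))
}

#' Segment sensor artifacts by velocity threshold and direction pairing
#'
#' Scans a velocity trace for samples faster than the saccade-speed ceiling.
#' Each super-threshold sample opens an artifact (onset); it is paired with
#' the next super-threshold sample whose velocity vector points the opposite
#' way (negative dot product with the onset velocity, the 2-D form of the
#' rule that gaze jumps out and later jumps back) within
#' `cfg$max_displacement_ms`. The enclosed half-open interval
#' `[t_onset, t_offset)` is classified `transient_spike` if its duration is
#' at most `cfg$max_spike_ms`, else `spatial_displacement`. Onsets that find
#' no return jump before the recording ends are reported with
#' `note = "unterminated"` and are not corrected downstream.
#'
#' The trace must come from a blink-free recording (blinks corrected first):
#' undefined velocity regions other than the first sample raise an error.
#'
#' @param vel a [compute_velocity()] trace.
#' @param cfg a [detector_config()].
#' @return Artifact table sorted by start time; intervals never overlap.
#' @export
segment_sensor_artifacts <- function(vel, cfg = detector_config()) {
  stopifnot(inherits(vel, "velocity_trace"))
  n <- length(vel$t)
  if (any(!vel$defined[-1])) {
    stop("velocity trace has undefined regions: correct blinks first",
         call. = FALSE)
  }
  hot <- which(vel$defined & vel$speed > cfg$speed_threshold)
  out <- empty_artifacts()
  i <- 1
  while (i <= length(hot)) {
    on <- hot[i]
    won <- c(vel$vx[on], vel$vy[on])
    js <- hot[hot > on & vel$t[hot] - vel$t[on] <= cfg$max_displacement_ms]
    off <- NA_integer_
    for (j in js) {
      if (vel$vx[j] * won[1] + vel$vy[j] * won[2] < 0) { off <- j; break }
    }
    if (is.na(off)) {
      end_t <- min(vel$t[on] + cfg$max_displacement_ms, vel$t[n])
      out <- rbind(out, artifact_row(
        "spatial_displacement", vel$t[on], end_t,
        won[1], won[2], note = "unterminated"))
      i <- i + 1
    } else {
      dur <- vel$t[off] - vel$t[on]
      kind <- if (dur <= cfg$max_spike_ms) "transient_spike"
              else "spatial_displacement"
      out <- rbind(out, artifact_row(kind, vel$t[on], vel$t[off],
                                     won[1], won[2],
                                     vel$vx[off], vel$vy[off]))
      i <- match(TRUE, hot > off)
      if (is.na(i)) break
    }
  }
  rownames(out) <- NULL
  out
}

#' Write / read the artifact table as TSV
#'
#' BED-like tab-separated dialect:
#' `start_ms  end_ms  kind  onset_vx  onset_vy  note` (with a header line).
#'
#' @param artifacts artifact table as returned by the detectors.
#' @param path file path.
#' @return `path` (write) or the artifact table (read).
#' @export
write_artifacts_tsv <- function(artifacts, path) {
  df <- data.frame(start_ms = artifacts$start_ms, end_ms = artifacts$end_ms,
                   kind = artifacts$kind,
                   onset_vx = artifacts$onset_vx,
                   onset_vy = artifacts$onset_vy,
                   note = artifacts$note)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_artifacts_tsv
#' @export
read_artifacts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(empty_artifacts())
  artifact_row(df$kind, df$start_ms, df$end_ms, df$onset_vx, df$onset_vy,
               note = ifelse(is.na(df$note), "", as.character(df$note)))
}
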