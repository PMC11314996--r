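#' Areas of interest
#'
#' Rectangular AOIs scored with half-open boxes: a sample is inside when
#' `x_min <= x < x_max` and `y_min <= y < y_max`. Each AOI applies to one
#' condition and optionally to one stimulus side (`"left"`/`"right"`): during
#' AJ/NOAJ trials only the AOI matching the trial's side counts.
#'
#' @param label,x_min,x_max,y_min,y_max,condition,side vectors defining one
#'   AOI per element; `side` may be `NA` (applies regardless of side).
#' @return Data frame of class `aoi_set`.
#' @export
aoi_set <- function(label, x_min, x_max, y_min, y_max, condition,
                    side = NA_character_) {
  df <- data.frame(label = label, x_min = x_min, x_max = x_max,
                   y_min = y_min, y_max = y_max, condition = condition,
                   side = side, stringsAsFactors = FALSE)
  if (any(df$x_min >= df$x_max) || any(df$y_min >= df$y_max)) {
    stop("invalid AOI: need x_min < x_max and y_min < y_max", call. = FALSE)
  }
  class(df) <- c("aoi_set", "data.frame")
  df
}

#' Default AOI layout
#'
#' Placeholder AOI geometry (the stimulus layout is study-specific and should
#' normally be supplied from a config): a 200 x 200 px box centered on the
#' screen for the fixation cross (Center condition) and 400 x 400 px object
#' boxes centered vertically at one quarter and three quarters of the screen
#' width for the left/right target objects (AJ and NOAJ conditions,
#' side-matched).
#'
#' @param geom a [screen_geometry()].
#' @return An [aoi_set()].
#' @export
default_aois <- function(geom = screen_geometry()) {
  cx <- geom$width_px / 2; cy <- geom$height_px / 2
  qx <- geom$width_px / 4
  obj <- 400 / 2; cross <- 200 / 2
  aoi_set(
    label = c("cross", "object_left", "object_left", "object_right",
              "object_right"),
    x_min = c(cx - cross, qx - obj, qx - obj, 3 * qx - obj, 3 * qx - obj),
    x_max = c(cx + cross, qx + obj, qx + obj, 3 * qx + obj, 3 * qx + obj),
    y_min = rep(c(cy - cross, cy - obj, cy - obj, cy - obj, cy - obj), 1),
    y_max = rep(c(cy + cross, cy + obj, cy + obj, cy + obj, cy + obj), 1),
    condition = c("Center", "AJ", "NOAJ", "AJ", "NOAJ"),
    side = c(NA, "left", "left", "right", "right"))
}

#' Load AOIs from a YAML/JSON config
#'
#' Expects an `aois` list with entries
#' `label, x_min, x_max, y_min, y_max, condition, side`.
#'
#' @param path YAML or JSON file path.
#' @return An [aoi_set()].
#' @export
read_aoi_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$aois)) stop("AOI config needs an 'aois' entry", call. = FALSE)
  a <- cfg$aois
  if (!is.data.frame(a)) {
    a <- do.call(rbind, lapply(a, function(b) {
      data.frame(label = b$label, x_min = b$x_min, x_max = b$x_max,
                 y_min = b$y_min, y_max = b$y_max, condition = b$condition,
                 side = if (is.null(b$side)) NA_character_ else b$side,
                 stringsAsFactors = FALSE)
    }))
  }
  aoi_set(a$label, a$x_min, a$x_max, a$y_min, a$y_max, a$condition,
          if ("side" %in% names(a)) a$side else NA_character_)
}

#' On-screen gaze rate for one condition
#'
#' Fraction of a condition's samples that are valid and fall inside the
#' screen (`0 <= x < width_px`, `0 <= y < height_px`, half-open). Lost
#' (`valid = FALSE`) samples count against the rate: a lost sample is not on
#' screen. The denominator is all samples labeled with the condition.
#'
#' @param rec a [gaze_recording()].
#' @param geom a [screen_geometry()].
#' @param labels output of [assign_condition()] for `rec`.
#' @param condition condition name to score.
#' @return Fraction in \[0, 1\].
#' @export
onscreen_rate <- function(rec, geom, labels, condition) {
  sel <- labels$condition == condition
  if (!any(sel)) stop("undefined rate: no samples in condition '", condition,
                      "'", call. = FALSE)
  hit <- rec$valid[sel] &
    rec$x[sel] >= 0 & rec$x[sel] < geom$width_px &
    rec$y[sel] >= 0 & rec$y[sel] < geom$height_px
  hit[is.na(hit)] <- FALSE
  mean(hit)
}

# logical vector: sample inside any AOI applicable to its condition and side
aoi_hit <- function(rec, aois, labels) {
  hit <- rep(FALSE, length(rec))
  for (k in seq_len(nrow(aois))) {
    a <- aois[k, ]
    applies <- labels$condition == a$condition &
      (is.na(a$side) | (!is.na(labels$side) & labels$side == a$side))
    inside <- rec$valid &
      rec$x >= a$x_min & rec$x < a$x_max &
      rec$y >= a$y_min & rec$y < a$y_max
    inside[is.na(inside)] <- FALSE
    hit <- hit | (applies & inside)
  }
  hit
}

#' AOI (task-adherence) gaze rate for one condition
#'
#' Fraction of a condition's samples falling inside any applicable AOI
#' (side-matched for AJ/NOAJ trials). As with [onscreen_rate()], the
#' denominator is all samples of the condition and lost samples count
#' against the rate.
#'
#' @inheritParams onscreen_rate
#' @param aois an [aoi_set()].
#' @return Fraction in \[0, 1\].
#' @export
aoi_rate <- function(rec, aois, labels, condition) {
  if (!any(aois$condition == condition)) {
    stop("config error: no AOI applies to condition '", condition, "'",
         call. = FALSE)
  }
  sel <- labels$condition == condition
  if (!any(sel)) stop("undefined rate: no samples in condition '", condition,
                      "'", call. = FALSE)
  mean(aoi_hit(rec, aois, labels)[sel])
}

#' Per-trial task-adherence rates
#'
#' One AOI rate per repeated trial position of each condition, averaged across
#' that position's occurrences over blocks. For conditions with several trials
#' per block (AJ/NOAJ: positions 1..5) the repeated measure is the
#' within-block trial position; for single-trial blocks (Center) it is the
#' block occurrence (1..4 in the default schedule), so the vector tracks the
#' task across session time in both cases.
#'
#' @param rec a [gaze_recording()].
#' @param sched a [block_schedule()].
#' @param aois an [aoi_set()].
#' @param labels optional precomputed [assign_condition()] labels.
#' @param t0_ms passed to [assign_condition()] when `labels` is `NULL`.
#' @return Data frame with columns `condition`, `trial`, `rate`.
#' @export
trial_rates <- function(rec, sched, aois, labels = NULL, t0_ms = NULL) {
  if (is.null(labels)) labels <- assign_condition(rec, sched, t0_ms)
  hit <- aoi_hit(rec, aois, labels)
  conds <- unique(sched$blocks$condition)
  out <- lapply(conds, function(cond) {
    sel <- which(labels$condition == cond)
    if (!length(sel)) stop("undefined rate: no samples in condition '", cond,
                           "'", call. = FALSE)
    per_block_trials <- max(sched$trials$trial_index[
      sched$trials$condition == cond])
    slot <- if (per_block_trials > 1) {
      labels$trial[sel]
    } else {
      # single trial per block: occurrence index of the block
      match(labels$block[sel],
            sort(unique(sched$blocks$block_index[
              sched$blocks$condition == cond])))
    }
    # mean of per-occurrence rates: rate per (block, slot), then mean per slot
    occ <- paste(labels$block[sel], slot)
    occ_rate <- tapply(hit[sel], occ, mean)
    occ_slot <- as.numeric(vapply(strsplit(names(occ_rate), " "),
                                  `[`, character(1), 2))
    rate <- tapply(occ_rate, occ_slot, mean)
    data.frame(condition = cond, trial = as.integer(names(rate)),
               rate = as.numeric(rate), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$condition, out$trial), , drop = FALSE]
}

#' Original-vs-filtered adherence table
#'
#' Computes on-screen and task (AOI) rates per condition for a raw recording
#' and its cleaned counterpart, the per-subject summary used by the group
#' statistics.
#'
#' @param original,filtered raw and cleaned [gaze_recording()]s sharing
#'   timestamps.
#' @param geom a [screen_geometry()].
#' @param sched a [block_schedule()].
#' @param aois an [aoi_set()].
#' @param t0_ms session start, passed to [assign_condition()].
#' @return Data frame with one row per (condition, variant):
#'   `subject_id`, `condition`, `variant` (`"original"`/`"filtered"`),
#'   `onscreen_rate`, `task_rate`.
#' @export
adherence_table <- function(original, filtered, geom, sched, aois,
                            t0_ms = NULL) {
  labels <- assign_condition(original, sched, t0_ms)
  conds <- unique(sched$blocks$condition)
  rows <- lapply(conds, function(cond) {
    data.frame(
      subject_id = original$subject_id,
      condition = cond,
      variant = c("original", "filtered"),
      onscreen_rate = c(onscreen_rate(original, geom, labels, cond),
                        onscreen_rate(filtered, geom, labels, cond)),
      task_rate = c(aoi_rate(original, aois, labels, cond),
                    aoi_rate(filtered, aois, labels, cond)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
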