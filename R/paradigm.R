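#' Block schedule
#'
#' Ordered condition blocks and trials mapping session time to experimental
#' condition. Blocks are contiguous and non-overlapping; trial spans tile
#' their block exactly. All spans are half-open `[start, end)` milliseconds
#' from session start.
#'
#' @param blocks data frame with columns `condition`, `duration_ms` and
#'   optionally `n_trials` (default 1) and `sides` (comma-separated per-trial
#'   `"left"`/`"right"` attributes, or `NA`).
#' @return An object of class `block_schedule` with components `blocks`
#'   (block_index, condition, start_ms, duration_ms), `trials` (block_index,
#'   condition, trial_index, start_ms, duration_ms, side) and
#'   `session_duration_ms`.
#' @seealso [build_default_schedule()]
#' @export
block_schedule <- function(blocks) {
  stopifnot(is.data.frame(blocks),
            all(c("condition", "duration_ms") %in% names(blocks)))
  if (any(blocks$duration_ms <= 0)) {
    stop("block durations must be positive", call. = FALSE)
  }
  n_trials <- if ("n_trials" %in% names(blocks)) blocks$n_trials
              else rep(1L, nrow(blocks))
  n_trials[is.na(n_trials)] <- 1L
  starts <- cumsum(c(0, blocks$duration_ms[-nrow(blocks)]))
  btab <- data.frame(block_index = seq_len(nrow(blocks)),
                     condition = as.character(blocks$condition),
                     start_ms = starts, duration_ms = blocks$duration_ms,
                     stringsAsFactors = FALSE)
  trials <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
    k <- n_trials[b]
    if (blocks$duration_ms[b] %% k != 0) {
      stop("trials must tile block ", b, " exactly", call. = FALSE)
    }
    len <- blocks$duration_ms[b] / k
    sides <- rep(NA_character_, k)
    if ("sides" %in% names(blocks) && !is.na(blocks$sides[b])) {
      sides <- strsplit(blocks$sides[b], ",")[[1]]
      if (length(sides) != k) {
        stop("sides must list one side per trial in block ", b, call. = FALSE)
      }
    }
    data.frame(block_index = b, condition = as.character(blocks$condition[b]),
               trial_index = seq_len(k),
               start_ms = starts[b] + (seq_len(k) - 1) * len,
               duration_ms = len, side = sides, stringsAsFactors = FALSE)
  }))
  rownames(trials) <- NULL
  structure(list(blocks = btab, trials = trials,
                 session_duration_ms = sum(blocks$duration_ms)),
            class = "block_schedule")
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("Block schedule: %d blocks, %d trials, %.0f s total\n",
              nrow(x$blocks), nrow(x$trials), x$session_duration_ms / 1000))
  tab <- table(x$blocks$condition)
  cat("  blocks per condition:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Default joint-attention session schedule
#'
#' The block paradigm of the joint-attention task: the unit sequence
#' 25 s AJ (5 videos of 5 s), 25 s NOAJ (5 videos), 20 s central cross,
#' repeated four times — 12 blocks (4 AJ, 4 NOAJ, 4 Center), 44 trials
#' (20 AJ, 20 NOAJ, 4 Center), 280 s per session. AJ/NOAJ trials carry a
#' left/right side attribute (the target object's side), balanced to 10 left
#' and 10 right per condition across the session, alternating within blocks.
#'
#' @return A [block_schedule()].
#' @export
build_default_schedule <- function() {
  side_pat <- c("left,right,left,right,left", "right,left,right,left,right")
  unit <- function(rep) {
    data.frame(condition = c("AJ", "NOAJ", "Center"),
               duration_ms = c(25000, 25000, 20000),
               n_trials = c(5L, 5L, 1L),
               sides = c(side_pat[(rep - 1) %% 2 + 1],
                         side_pat[rep %% 2 + 1], NA),
               stringsAsFactors = FALSE)
  }
  block_schedule(do.call(rbind, lapply(1:4, unit)))
}

#' Load a schedule from a YAML/JSON config
#'
#' The config must carry a `blocks` list, each entry with `condition`,
#' `duration_ms`, optional `n_trials` and `sides`.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file path.
#' @return A [block_schedule()].
#' @export
read_schedule_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$blocks)) stop("schedule config needs a 'blocks' entry",
                                call. = FALSE)
  blocks <- cfg$blocks
  if (!is.data.frame(blocks)) {
    blocks <- do.call(rbind, lapply(blocks, function(b) {
      data.frame(condition = b$condition, duration_ms = b$duration_ms,
                 n_trials = if (is.null(b$n_trials)) 1L else b$n_trials,
                 sides = if (is.null(b$sides)) NA_character_ else b$sides,
                 stringsAsFactors = FALSE)
    }))
  }
  block_schedule(blocks)
}

#' Label samples with condition, block and trial
#'
#' Maps each sample of a recording onto the schedule using half-open
#' `[start, end)` spans: a sample exactly on a boundary belongs to the later
#' block. Samples before `t0_ms` or at/after session end get condition
#' `"none"`.
#'
#' @param rec a [gaze_recording()].
#' @param sched a [block_schedule()].
#' @param t0_ms recording time of session start; defaults to the first
#'   timestamp (override for trigger-based alignment).
#' @return Data frame with columns `time_ms`, `condition`, `block`, `trial`,
#'   `side`, one row per sample.
#' @export
assign_condition <- function(rec, sched, t0_ms = NULL) {
  stopifnot(inherits(rec, "gaze_recording"), inherits(sched, "block_schedule"))
  if (is.null(t0_ms)) t0_ms <- rec$t[1]
  rel <- rec$t - t0_ms
  tr <- sched$trials
  idx <- findInterval(rel, tr$start_ms)
  in_session <- rel >= 0 & rel < sched$session_duration_ms
  if (!any(in_session)) {
    warning("recording lies entirely outside the session", call. = FALSE)
  }
  idx[!in_session] <- NA
  data.frame(
    time_ms = rec$t,
    condition = ifelse(in_session, tr$condition[idx], "none"),
    block = ifelse(in_session, tr$block_index[idx], NA),
    trial = ifelse(in_session, tr$trial_index[idx], NA),
    side = ifelse(in_session, tr$side[idx], NA),
    stringsAsFactors = FALSE)
}
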