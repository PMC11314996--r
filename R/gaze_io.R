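#' Read a gaze recording from CSV
#'
#' Reads the package's sample CSV dialect: header
#' `time_ms,x_px,y_px,valid`, UTF-8, one row per sample. The `valid` column is
#' optional. A sample is marked invalid when any of: the `valid` cell is
#' 0/false, a position cell is empty, `NA`, `NaN`, or the EyeLink missing-data
#' token `"."`. Timestamps must be strictly increasing; non-uniform sampling
#' is tolerated (velocity computations use the actual time step).
#'
#' @param path CSV file path.
#' @param subject_id subject identifier to attach; defaults to the file stem.
#' @param sampling_rate_hz nominal rate stored on the recording.
#' @return A [gaze_recording()].
#' @seealso [write_samples_csv()], [read_eyelink_asc()]
#' @export
read_samples_csv <- function(path, subject_id = NULL, sampling_rate_hz = 1000) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(), check.names = FALSE)
  needed <- c("time_ms", "x_px", "y_px")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  t <- suppressWarnings(as.numeric(df$time_ms))
  if (any(is.na(t))) {
    stop("format error: non-numeric timestamp", call. = FALSE)
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("format error: timestamps not strictly increasing", call. = FALSE)
  }
  x <- parse_position(df$x_px)
  y <- parse_position(df$y_px)
  valid <- is.finite(x) & is.finite(y)
  if ("valid" %in% names(df)) {
    v <- trimws(df$valid)
    valid <- valid & !(v %in% c("0", "false", "FALSE", "False"))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  gaze_recording(t, x, y, valid, subject_id = subject_id,
                 sampling_rate_hz = sampling_rate_hz)
}

# empty cells, NA/NaN tokens and the ASC '.' all normalize to NA
parse_position <- function(cell) {
  cell <- trimws(cell)
  cell[cell %in% c("", ".", "NA", "NaN", "nan")] <- NA_character_
  suppressWarnings(as.numeric(cell))
}

#' Write a gaze recording to CSV
#'
#' Writes the dialect read by [read_samples_csv()]. Invalid samples are
#' serialized with empty position cells and `valid = 0`, so a read/write
#' round trip is lossless on `t`, `x`, `y`, `valid` (invalid positions are
#' not preserved: they carry no information).
#'
#' @param rec a [gaze_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(rec, path) {
  stopifnot(inherits(rec, "gaze_recording"))
  x_cell <- ifelse(rec$valid, format_num(rec$x), "")
  y_cell <- ifelse(rec$valid, format_num(rec$y), "")
  lines <- c("time_ms,x_px,y_px,valid",
             if (length(rec)) paste(format_num(rec$t), x_cell, y_cell,
                                    as.integer(rec$valid), sep = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path, call. = FALSE)
  invisible(path)
}

# canonical numeric formatting: plain decimal, trailing zeros stripped
format_num <- function(v) {
  out <- formatC(v, format = "fg", digits = 15, width = 1)
  ifelse(grepl("\\.", out), sub("\\.?0+$", "", out), out)
}

#' Read EyeLink ASC sample lines
#'
#' Parses the sample-line subset of an EyeLink ASC export (monocular):
#' lines of the form `<time> <x> <y> <pupil> ...` where the first token is
#' numeric. Position fields equal to the missing-data token `"."` yield
#' `valid = FALSE`. Event lines (`SFIX`, `SSACC`, `EBLINK`, `MSG`, ...) are
#' ignored: artifact classification is recomputed downstream, never trusted
#' from the tracker's own parser. Unparseable sample lines are skipped with a
#' warning and counted in the attached parse report
#' (`attr(rec, "parse_report")`).
#'
#' @param path ASC text file path.
#' @param subject_id subject identifier; defaults to the file stem.
#' @param sampling_rate_hz nominal rate stored on the recording.
#' @return A [gaze_recording()] with a `parse_report` attribute
#'   (`n_samples`, `n_skipped`, `n_event_lines`).
#' @export
read_eyelink_asc <- function(path, subject_id = NULL, sampling_rate_hz = 1000) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  first <- vapply(toks, `[`, character(1), 1L)
  is_sample <- suppressWarnings(!is.na(as.numeric(first)))
  n_event <- sum(!is_sample)
  toks <- toks[is_sample]
  if (!length(toks)) {
    stop("empty recording: no sample lines in ", path, call. = FALSE)
  }
  n_skipped <- 0L
  t <- x <- y <- numeric(length(toks))
  valid <- logical(length(toks))
  keep <- logical(length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) < 3) { n_skipped <- n_skipped + 1L; next }
    ti <- suppressWarnings(as.numeric(tk[1]))
    xi <- if (tk[2] == ".") NA_real_ else suppressWarnings(as.numeric(tk[2]))
    yi <- if (tk[3] == ".") NA_real_ else suppressWarnings(as.numeric(tk[3]))
    miss <- tk[2] == "." || tk[3] == "."
    if (is.na(ti) || (!miss && (is.na(xi) || is.na(yi)))) {
      n_skipped <- n_skipped + 1L; next
    }
    keep[i] <- TRUE
    t[i] <- ti; x[i] <- xi; y[i] <- yi; valid[i] <- !miss
  }
  if (n_skipped > 0) {
    warning(n_skipped, " unparseable sample line(s) skipped in ", path,
            call. = FALSE)
  }
  if (!any(keep)) {
    stop("empty recording: no parseable sample lines in ", path, call. = FALSE)
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  rec <- gaze_recording(t[keep], ifelse(valid[keep], x[keep], NA),
                        ifelse(valid[keep], y[keep], NA), valid[keep],
                        subject_id = subject_id,
                        sampling_rate_hz = sampling_rate_hz)
  attr(rec, "parse_report") <- list(n_samples = sum(keep),
                                    n_skipped = n_skipped,
                                    n_event_lines = n_event)
  rec
}
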