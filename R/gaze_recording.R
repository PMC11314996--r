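#' Sample-level gaze recording
#'
#' A uniformly (or near-uniformly) sampled monocular gaze time series with an
#' explicit validity mask. Missing data (tracker loss during blinks) are kept
#' as `valid = FALSE` samples rather than sentinel coordinates, because
#' `(0, 0)` is a legal on-screen corner position. Coordinates follow the
#' screen convention: origin at the top-left, x rightward, y downward, pixels.
#'
#' @param t timestamps in milliseconds, strictly increasing.
#' @param x,y gaze position in pixels; may be `NA` where `valid` is `FALSE`.
#' @param valid logical mask, `FALSE` marking lost/null samples. Defaults to
#'   samples where both coordinates are finite.
#' @param subject_id subject identifier string.
#' @param sampling_rate_hz nominal sampling rate (samples per second).
#' @return An object of class `gaze_recording`.
#' @examples
#' rec <- gaze_recording(t = 0:9, x = rep(840, 10), y = rep(525, 10))
#' summary(rec)
#' @export
gaze_recording <- function(t, x, y, valid = NULL, subject_id = "unknown",
                           sampling_rate_hz = 1000) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(t)
  if (length(x) != n || length(y) != n) {
    stop("t, x, y must have equal length", call. = FALSE)
  }
  if (is.null(valid)) valid <- is.finite(x) & is.finite(y)
  valid <- as.logical(valid)
  if (length(valid) != n) stop("valid must match sample count", call. = FALSE)
  valid[is.na(valid)] <- FALSE
  if (n > 1 && any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be positive", call. = FALSE)
  }
  if (any(valid & (!is.finite(x) | !is.finite(y)))) {
    stop("valid samples must have finite positions", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id),
         sampling_rate_hz = sampling_rate_hz,
         t = t, x = x, y = y, valid = valid),
    class = "gaze_recording"
  )
}

#' @export
length.gaze_recording <- function(x) length(x$t)

#' @export
print.gaze_recording <- function(x, ...) {
  n <- length(x)
  dur <- if (n > 1) (x$t[n] - x$t[1]) / 1000 else 0
  cat(sprintf("Gaze recording '%s': %d samples, %.1f s at %g Hz, %d invalid (%.1f%%)\n",
              x$subject_id, n, dur, x$sampling_rate_hz,
              sum(!x$valid), if (n) 100 * mean(!x$valid) else 0))
  invisible(x)
}

#' @export
summary.gaze_recording <- function(object, ...) {
  print(object)
  if (any(object$valid)) {
    cat(sprintf("  x: [%.1f, %.1f] px   y: [%.1f, %.1f] px (valid samples)\n",
                min(object$x[object$valid]), max(object$x[object$valid]),
                min(object$y[object$valid]), max(object$y[object$valid])))
  }
  invisible(object)
}

#' @export
as.data.frame.gaze_recording <- function(x, ...) {
  data.frame(time_ms = x$t, x_px = x$x, y_px = x$y, valid = x$valid)
}

#' Plot a gaze recording
#'
#' Two-panel quick-look: the 2-D trajectory and per-axis position over time.
#' Invalid samples appear as gaps.
#'
#' @param x a [gaze_recording()].
#' @param geom optional [screen_geometry()] used to draw the screen bounds.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.gaze_recording <- function(x, geom = NULL, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  xs <- ifelse(x$valid, x$x, NA)
  ys <- ifelse(x$valid, x$y, NA)
  graphics::plot(xs, ys, type = "l", xlab = "x (px)", ylab = "y (px)",
                 main = x$subject_id, ylim = rev(range(ys, na.rm = TRUE)), ...)
  if (!is.null(geom)) {
    graphics::rect(0, geom$height_px, geom$width_px, 0, border = "grey50",
                   lty = 2)
  }
  graphics::matplot(x$t / 1000, cbind(xs, ys), type = "l", lty = 1,
                    col = c("black", "grey40"),
                    xlab = "time (s)", ylab = "position (px)")
  graphics::legend("topright", c("x", "y"), lty = 1,
                   col = c("black", "grey40"), bty = "n")
  invisible(x)
}
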