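#' Screen and viewing geometry
#'
#' Describes the stimulus screen (pixel grid and physical size) and the
#' viewing distance, the basis of all conversions between visual degrees and
#' pixel units. Pixels are assumed square: the horizontal pixel pitch
#' (`width_m / width_px`) must agree with the vertical pitch within 1% unless
#' `allow_nonsquare = TRUE`.
#'
#' The default geometry is a 1680 x 1050 px screen viewed at 1 m. The physical
#' width (0.6604 m) is a back-derived assumption chosen so that the
#' saccade-speed ceiling of 0.9 deg/ms converts to 40 px/ms (nearest integer);
#' it is not a measured panel size and every field can be overridden, e.g.
#' from a `geometry:` config block.
#'
#' @param width_px,height_px screen resolution in pixels.
#' @param width_m,height_m physical screen size in meters.
#' @param viewing_distance_m eye-to-screen path length in meters.
#' @param allow_nonsquare skip the square-pixel consistency check.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' px_per_degree(geom)
#' @export
screen_geometry <- function(width_px = 1680L, height_px = 1050L,
                            width_m = 0.6604, height_m = 0.4128,
                            viewing_distance_m = 1.0,
                            allow_nonsquare = FALSE) {
  fields <- c(width_px = width_px, height_px = height_px,
              width_m = width_m, height_m = height_m,
              viewing_distance_m = viewing_distance_m)
  if (any(!is.finite(fields)) || any(fields <= 0)) {
    stop("invalid geometry: all fields must be finite and strictly positive",
         call. = FALSE)
  }
  pitch_x <- width_m / width_px
  pitch_y <- height_m / height_px
  if (!allow_nonsquare && abs(pitch_x - pitch_y) / pitch_x > 0.01) {
    stop("invalid geometry: pixel pitch differs by >1% between axes ",
         "(non-square pixels); set allow_nonsquare = TRUE to override",
         call. = FALSE)
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         width_m = width_m, height_m = height_m,
         viewing_distance_m = viewing_distance_m),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  ext <- angular_extent(x)
  cat(sprintf("Screen geometry: %d x %d px, %.4f x %.4f m, viewed at %.3f m\n",
              x$width_px, x$height_px, x$width_m, x$height_m,
              x$viewing_distance_m))
  cat(sprintf("  %.2f px/deg at center; angular extent %.1f x %.1f deg\n",
              px_per_degree(x), ext[["width_deg"]], ext[["height_deg"]]))
  invisible(x)
}

#' Pixels subtending one degree of visual angle
#'
#' Number of pixels spanned by 1 degree of visual angle at the screen center
#' along the horizontal axis: `distance * tan(1 deg) / pixel_pitch`. Used to
#' express velocity thresholds given in deg/ms in pixel units.
#'
#' @param geom a [screen_geometry()].
#' @return Pixels per degree (scalar).
#' @export
px_per_degree <- function(geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  pitch <- geom$width_m / geom$width_px
  geom$viewing_distance_m * tan(pi / 180) / pitch
}

#' Convert angular velocity to pixel velocity
#'
#' Small-angle (screen-center) conversion between deg/ms and px/ms. Under the
#' default geometry the physiological saccade-speed ceiling of 0.9 deg/ms
#' maps to 40 px/ms (nearest integer), the default detection threshold.
#'
#' @param v velocity in deg/ms (`deg_per_ms_to_px_per_ms`) or px/ms
#'   (`px_per_ms_to_deg_per_ms`); vectorized, must be non-negative.
#' @param geom a [screen_geometry()].
#' @return Velocity in the other unit.
#' @export
deg_per_ms_to_px_per_ms <- function(v, geom) {
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("velocity must be finite and non-negative", call. = FALSE)
  }
  v * px_per_degree(geom)
}

#' @rdname deg_per_ms_to_px_per_ms
#' @export
px_per_ms_to_deg_per_ms <- function(v, geom) {
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("velocity must be finite and non-negative", call. = FALSE)
  }
  v / px_per_degree(geom)
}

#' Full-screen angular extent
#'
#' Visual angle subtended by the whole screen per axis,
#' `2 * atan(size / 2 / distance)`, in degrees.
#'
#' @param geom a [screen_geometry()].
#' @return Named numeric vector `c(width_deg, height_deg)`.
#' @export
angular_extent <- function(geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  d <- geom$viewing_distance_m
  c(width_deg = 2 * atan(geom$width_m / 2 / d) * 180 / pi,
    height_deg = 2 * atan(geom$height_m / 2 / d) * 180 / pi)
}

#' Build a screen geometry from a config list
#'
#' Accepts the `geometry:` block of a YAML/JSON run config
#' (`width_px, height_px, width_m, height_m, viewing_distance_m`); missing
#' entries fall back to the package defaults.
#'
#' @param config a named list (possibly partial); `NULL` gives the default.
#' @return A [screen_geometry()].
#' @export
geometry_from_config <- function(config = NULL) {
  if (is.null(config)) return(screen_geometry())
  args <- config[intersect(names(config),
                           c("width_px", "height_px", "width_m", "height_m",
                             "viewing_distance_m", "allow_nonsquare"))]
  do.call(screen_geometry, args)
}
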