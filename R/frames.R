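#' Imaging frame metadata
#'
#' An `image_frame` describes one square fundus imaging frame: its angular
#' field of view, its pixel dimensions, and the retinal scale used to convert
#' visual degrees to micrometers on the retina. The pixel scale follows from
#' the three: `um_per_pixel = field_of_view_deg / pixel_dims * um_per_degree`.
#'
#' Coordinate conventions used throughout the package:
#' \itemize{
#'   \item Pixel coordinates are 0-based, x rightward, y downward, origin at
#'     the top-left pixel corner.
#'   \item Micrometer frame coordinates share the pixel orientation (x
#'     rightward, y downward), scaled by `um_per_pixel`.
#'   \item Fovea-centered degree coordinates are x rightward, y upward
#'     (converting to an image frame therefore flips the y sign).
#' }
#'
#' The degree-to-micrometer scale is not a device constant; the emmetropic
#' schematic-eye convention of 291 um per degree is the default and is
#' surfaced in all reports. Only square fields are supported; anisotropic
#' metadata is rejected.
#'
#' @param field_of_view_deg angular field of view in degrees (scalar > 0;
#'   applies to both axes).
#' @param pixel_dims number of pixels along each axis (scalar positive
#'   integer).
#' @param um_per_degree micrometers of retina per visual degree (scalar > 0).
#' @return An object of class `image_frame`.
#' @examples
#' faf <- image_frame(30, 768)        # 30 x 30 degrees, 768 x 768 pixels
#' um_per_pixel(faf)                  # ~11.37 um per pixel
#' @export
image_frame <- function(field_of_view_deg, pixel_dims, um_per_degree = 291) {
  if (length(field_of_view_deg) != 1L || !is.finite(field_of_view_deg) ||
      field_of_view_deg <= 0)
    stop("'field_of_view_deg' must be a single positive number (square field)",
         call. = FALSE)
  if (length(pixel_dims) != 1L || !is.finite(pixel_dims) || pixel_dims <= 0 ||
      pixel_dims != round(pixel_dims))
    stop("'pixel_dims' must be a single positive integer (square field)",
         call. = FALSE)
  if (length(um_per_degree) != 1L || !is.finite(um_per_degree) ||
      um_per_degree <= 0)
    stop("'um_per_degree' must be a single positive number", call. = FALSE)
  structure(
    list(field_of_view_deg = as.numeric(field_of_view_deg),
         pixel_dims = as.integer(pixel_dims),
         um_per_degree = as.numeric(um_per_degree)),
    class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("image frame: %g x %g deg, %d x %d px, %g um/deg (%.4f um/px)\n",
              x$field_of_view_deg, x$field_of_view_deg,
              x$pixel_dims, x$pixel_dims,
              x$um_per_degree, um_per_pixel(x)))
  invisible(x)
}

#' Micrometers per pixel of an imaging frame
#'
#' @param frame an [image_frame].
#' @return Scalar retinal scale in micrometers per pixel.
#' @export
um_per_pixel <- function(frame) {
  stopifnot(inherits(frame, "image_frame"))
  frame$field_of_view_deg / frame$pixel_dims * frame$um_per_degree
}

#' Frame center (the fovea anchor) in frame coordinates
#'
#' Frames are fovea-centered acquisitions, so the fovea anchor defaults to
#' the geometric frame center.
#'
#' @param frame an [image_frame].
#' @return Length-2 numeric vector, in pixels (`frame_center_px`) or
#'   micrometers (`frame_center_um`).
#' @export
frame_center_px <- function(frame) {
  stopifnot(inherits(frame, "image_frame"))
  rep(frame$pixel_dims / 2, 2L)
}

#' @rdname frame_center_px
#' @export
frame_center_um <- function(frame) {
  frame_center_px(frame) * um_per_pixel(frame)
}

as_xy <- function(xy, arg = "xy") {
  if (is.null(dim(xy))) {
    if (length(xy) != 2L)
      stop(sprintf("'%s' must be an n x 2 matrix or a length-2 vector", arg),
           call. = FALSE)
    xy <- matrix(as.numeric(xy), ncol = 2L)
  }
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L)
    stop(sprintf("'%s' must have exactly 2 columns (x, y)", arg),
         call. = FALSE)
  storage.mode(xy) <- "double"
  dimnames(xy) <- NULL
  xy
}

#' Convert pixel coordinates to micrometers
#'
#' Scales 0-based pixel coordinates of an imaging frame to micrometers on the
#' retina using the frame's `um_per_pixel`. The inverse,
#' `micrometers_to_pixels`, round-trips to within 1e-9.
#'
#' @param xy an n x 2 matrix (or length-2 vector) of coordinates.
#' @param frame the [image_frame] the coordinates live in.
#' @return An n x 2 numeric matrix in the target unit.
#' @export
pixels_to_micrometers <- function(xy, frame) {
  stopifnot(inherits(frame, "image_frame"))
  xy <- as_xy(xy)
  if (any(!is.finite(xy)))
    stop("pixel coordinates must be finite", call. = FALSE)
  if (any(xy < 0) || any(xy > frame$pixel_dims))
    stop(sprintf("pixel coordinates must lie within [0, %d]",
                 frame$pixel_dims), call. = FALSE)
  xy * um_per_pixel(frame)
}

#' @rdname pixels_to_micrometers
#' @export
micrometers_to_pixels <- function(xy, frame) {
  stopifnot(inherits(frame, "image_frame"))
  xy <- as_xy(xy)
  if (any(!is.finite(xy)))
    stop("micrometer coordinates must be finite", call. = FALSE)
  xy / um_per_pixel(frame)
}

#' Convert fovea-centered degree coordinates to frame micrometers
#'
#' Maps fovea-centered visual-degree coordinates (x rightward, y upward) into
#' an imaging frame's micrometer coordinates (x rightward, y downward),
#' anchored at the frame's fovea position. `micrometers_to_degrees` is the
#' exact inverse.
#'
#' @param xy an n x 2 matrix (or length-2 vector) of coordinates.
#' @param frame the target [image_frame].
#' @param fovea_um position of the fovea in the frame's micrometer
#'   coordinates; defaults to the frame center.
#' @return An n x 2 numeric matrix in the target unit.
#' @export
degrees_to_micrometers <- function(xy, frame, fovea_um = frame_center_um(frame)) {
  stopifnot(inherits(frame, "image_frame"))
  xy <- as_xy(xy)
  if (any(!is.finite(xy)))
    stop("degree coordinates must be finite", call. = FALSE)
  if (length(fovea_um) != 2L || any(!is.finite(fovea_um)))
    stop("'fovea_um' anchor must be a finite length-2 vector", call. = FALSE)
  k <- frame$um_per_degree
  cbind(fovea_um[1L] + xy[, 1L] * k,
        fovea_um[2L] - xy[, 2L] * k)  # degree y is up, image y is down
}

#' @rdname degrees_to_micrometers
#' @export
micrometers_to_degrees <- function(xy, frame, fovea_um = frame_center_um(frame)) {
  stopifnot(inherits(frame, "image_frame"))
  xy <- as_xy(xy)
  if (any(!is.finite(xy)))
    stop("micrometer coordinates must be finite", call. = FALSE)
  k <- frame$um_per_degree
  cbind((xy[, 1L] - fovea_um[1L]) / k,
        (fovea_um[2L] - xy[, 2L]) / k)
}
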