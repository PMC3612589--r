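#' Pinhole camera model
#'
#' A pinhole camera with focal length `f` and a rectangular image plane of
#' metric size `width` x `height`, centred on the optical axis. The image
#' coordinate frame is right-handed with x positive to the left, y positive
#' upward, and z along the optical axis; an image point is `(x, y, f)`.
#'
#' Either `focal_length` or a horizontal field of view `fov_deg` must be
#' given; with `fov_deg` the focal length is `width / (2 tan(fov/2))`.
#'
#' @param focal_length Focal length in metres.
#' @param width,height Image-plane extent in metres. `height` defaults to
#'   `width` (square display).
#' @param fov_deg Optional horizontal field of view in degrees, used to derive
#'   the focal length when `focal_length` is missing.
#' @return An object of class `pinhole_camera`.
#' @examples
#' cam <- pinhole_camera(fov_deg = 32, width = 0.01)
#' camera_fov(cam)
#' @export
pinhole_camera <- function(focal_length = NULL, width = 0.01, height = width,
                           fov_deg = NULL) {
  if (is.null(focal_length)) {
    if (is.null(fov_deg)) {
      abort("supply either `focal_length` or `fov_deg`")
    }
    focal_length <- width / (2 * tan(deg2rad(fov_deg) / 2))
  }
  if (focal_length <= 0 || width <= 0 || height <= 0) {
    abort("focal length and image extents must be positive")
  }
  structure(
    list(f = focal_length, width = width, height = height),
    class = "pinhole_camera"
  )
}

#' @export
print.pinhole_camera <- function(x, ...) {
  cat(sprintf(
    "<pinhole_camera> f = %.4g m, image %.4g x %.4g m, fov %.2f x %.2f deg\n",
    x$f, x$width, x$height, camera_fov(x)[1], camera_fov(x)[2]
  ))
  invisible(x)
}

#' Field of view of a camera
#'
#' @param camera A [pinhole_camera()].
#' @return Horizontal and vertical field of view in degrees.
#' @export
camera_fov <- function(camera) {
  c(
    horizontal = 2 * rad2deg(atan(camera$width / (2 * camera$f))),
    vertical = 2 * rad2deg(atan(camera$height / (2 * camera$f)))
  )
}

#' Degree/metric conversions on the image plane
#'
#' Positions, lengths and velocities may be specified in degrees of visual
#' angle; these helpers convert them to the metric image-plane quantities the
#' flow equations use. A position at eccentricity `a` maps to `f tan(a)`, a
#' length subtending `l` maps to `2 f tan(l/2)`, and a velocity of `a` degrees
#' per second against a surface approached at `v_z` maps to `v_z tan(a)`.
#'
#' @param angle_deg Eccentricity in degrees (position) or angular size in
#'   degrees (length).
#' @param camera A [pinhole_camera()].
#' @return Metres (or metres per second for the velocity form).
#' @examples
#' cam <- pinhole_camera(focal_length = 0.0174)
#' angle_to_position(16, cam) # about half of a 1 cm display
#' @export
angle_to_position <- function(angle_deg, camera) {
  if (any(abs(angle_deg) >= 90)) {
    abort("positions at or beyond +/-90 degrees do not project onto the image plane")
  }
  camera$f * tan(deg2rad(angle_deg))
}

#' @rdname angle_to_position
#' @param x Metric image position in metres.
#' @export
position_to_angle <- function(x, camera) {
  rad2deg(atan(x / camera$f))
}

#' @rdname angle_to_position
#' @export
angle_to_length <- function(angle_deg, camera) {
  if (any(angle_deg < 0) || any(angle_deg >= 180)) {
    abort("angular sizes must lie in [0, 180) degrees")
  }
  2 * camera$f * tan(deg2rad(angle_deg) / 2)
}

#' @rdname angle_to_position
#' @param v_angle_deg Angular velocity in degrees per second.
#' @param v_z Velocity along the optical axis in metres per second.
#' @export
angular_velocity_to_metric <- function(v_angle_deg, v_z) {
  if (any(abs(v_angle_deg) >= 90)) {
    abort("angular velocities at or beyond +/-90 deg/s are outside the conversion domain")
  }
  v_z * tan(deg2rad(v_angle_deg))
}
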