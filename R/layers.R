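#' Rigid 3D motion
#'
#' Constant linear velocity `v = (v_x, v_y, v_z)` in metres per second and
#' rotational velocity `omega = (pitch, yaw, roll)` in radians per second,
#' relative to a stationary camera at the origin. A point `X` moves as
#' `dX/dt = -v - omega x X`.
#'
#' @param v Linear velocity, length-3 numeric (m/s).
#' @param omega Rotational velocity, length-3 numeric (rad/s).
#' @return An object of class `rigid_motion`.
#' @export
rigid_motion <- function(v = c(0, 0, 0), omega = c(0, 0, 0)) {
  stopifnot(length(v) == 3, length(omega) == 3)
  if (!all(is.finite(v)) || !all(is.finite(omega))) {
    abort("motion components must be finite")
  }
  structure(list(v = as.numeric(v), omega = as.numeric(omega)),
            class = "rigid_motion")
}

#' Scene layers bound to a motion
#'
#' A *flow layer* couples a planar scene element to a 3D motion and supports
#' closed-form evaluation of its instantaneous flow, the spatial Jacobian of
#' the flow, and its Eulerian temporal derivatives (at a fixed image point).
#' Three model instances are provided:
#'
#' * `translational_layer()`: linear motion `v` toward a static plane given in
#'   Hessian normal form (`normal`, initial distance `d0`). The viewed depth
#'   is `Z(x, y, t) = f (d0 - t v.n) / (p.n)` with `p = (x, y, f)`.
#' * `curvilinear_fronto_layer()`: circular-path motion (yaw rate `omega`,
#'   radius `radius`, tangential speed `omega * radius`) toward a plane that
#'   is fronto-parallel at `t = 0` and co-rotates in view:
#'   `n(t) = (-sin wt, 0, cos wt)`, `d(t) = d0 - radius sin wt`.
#' * `curvilinear_ground_layer()`: the same motion over a ground plane with
#'   normal `(0, 1, 0)` at signed height `height` (negative when the ground
#'   is below the camera); the resulting flow is time-invariant.
#'
#' @param d0 Initial plane distance (m), positive.
#' @param v Linear velocity, length-3 numeric (m/s).
#' @param normal Unit plane normal, length-3 numeric.
#' @param omega Yaw angular velocity (rad/s).
#' @param radius Signed path radius (m), nonzero.
#' @param height Signed camera height over the ground plane (m), nonzero.
#' @return An object of classes `<subtype>`/`flow_layer`.
#' @seealso [layer_flow()], [layered_scene()]
#' @export
translational_layer <- function(d0, v, normal = c(0, 0, 1)) {
  stopifnot(length(v) == 3, length(normal) == 3)
  if (d0 <= 0) abort("`d0` must be positive")
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-12) {
    abort("`normal` must be a unit vector")
  }
  structure(list(d0 = d0, v = as.numeric(v), normal = as.numeric(normal)),
            class = c("translational_layer", "flow_layer"))
}

#' @rdname translational_layer
#' @export
curvilinear_fronto_layer <- function(d0, omega, radius) {
  if (d0 <= 0) abort("`d0` must be positive")
  if (radius == 0) abort("`radius` must be nonzero")
  structure(list(d0 = d0, omega = omega, radius = radius),
            class = c("curvilinear_fronto_layer", "flow_layer"))
}

#' @rdname translational_layer
#' @export
curvilinear_ground_layer <- function(height, omega, radius) {
  if (height == 0) abort("`height` must be nonzero")
  if (radius == 0) abort("`radius` must be nonzero")
  structure(list(height = height, omega = omega, radius = radius),
            class = c("curvilinear_ground_layer", "flow_layer"))
}

#' Rectangular image region occupied by an IMO
#'
#' The region `A_I = [x - w/2, x + w/2] x [y - h/2, y + h/2]` in metric image
#' coordinates. The region is closed: boundary samples belong to the IMO.
#'
#' @param x,y Centre of the region (m).
#' @param width,height Extent of the region (m), positive.
#' @return An object of class `imo_region`.
#' @export
imo_region <- function(x, y, width, height) {
  if (width <= 0 || height <= 0) abort("region extents must be positive")
  structure(list(x = x, y = y, width = width, height = height),
            class = "imo_region")
}

#' @rdname imo_region
#' @param x_deg,y_deg Centre in degrees of eccentricity.
#' @param width_deg,height_deg Angular size in degrees.
#' @param camera A [pinhole_camera()].
#' @export
imo_region_deg <- function(x_deg, y_deg, width_deg, height_deg, camera) {
  imo_region(
    x = angle_to_position(x_deg, camera),
    y = angle_to_position(y_deg, camera),
    width = angle_to_length(width_deg, camera),
    height = angle_to_length(height_deg, camera)
  )
}

in_region <- function(region, x, y) {
  x >= region$x - region$width / 2 & x <= region$x + region$width / 2 &
    y >= region$y - region$height / 2 & y <= region$y + region$height / 2
}

#' Two-layer scene: background plus one IMO
#'
#' Combines a background layer with an independently moving object (IMO):
#' a second flow layer visible inside a rectangular image region. Inside the
#' region the IMO's flow replaces the background's (the IMO occludes the
#' background); the region is closed, so boundary points take the IMO label.
#'
#' @param camera A [pinhole_camera()].
#' @param background A `flow_layer` for the rigid background.
#' @param imo Optional [imo_region()] for the object, with `imo_layer` its
#'   flow layer. Both or neither must be given.
#' @param imo_layer Flow layer of the object.
#' @return An object of class `layered_scene`.
#' @export
layered_scene <- function(camera, background, imo = NULL, imo_layer = NULL) {
  stopifnot(inherits(camera, "pinhole_camera"),
            inherits(background, "flow_layer"))
  if (xor(is.null(imo), is.null(imo_layer))) {
    abort("supply both `imo` and `imo_layer`, or neither")
  }
  if (!is.null(imo)) {
    stopifnot(inherits(imo, "imo_region"), inherits(imo_layer, "flow_layer"))
  }
  structure(
    list(camera = camera, background = background,
         imo = imo, imo_layer = imo_layer),
    class = "layered_scene"
  )
}
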