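#' Instantaneous flow of a rigid motion at known depth
#'
#' The general motion-field equation for a pinhole camera: at image point
#' `p = (x, y, f)` viewing a 3D point at depth `Z`, a rigid motion with
#' linear velocity `v` and rotational velocity `omega` induces
#' \deqn{(\dot x, \dot y) = \frac{1}{Z} \begin{pmatrix} -f & 0 & x \\ 0 & -f & y \end{pmatrix} v
#'  + \frac{1}{f} \begin{pmatrix} xy & -(f^2+x^2) & fy \\ f^2+y^2 & -xy & -fx \end{pmatrix} \omega.}
#' The translational part scales with inverse depth; the rotational part is
#' depth-independent; the two superimpose linearly. For pure translation the
#' flow vanishes at the focus of expansion `(f v_x/v_z, f v_y/v_z)`.
#'
#' @param x,y Image coordinates (m), vectorised.
#' @param Z Depth along the optical axis (m), positive; recycled.
#' @param motion A [rigid_motion()].
#' @param camera A [pinhole_camera()].
#' @return A tibble with columns `x`, `y`, `u`, `v` (flow in m/s).
#' @export
general_flow <- function(x, y, Z, motion, camera) {
  stopifnot(inherits(motion, "rigid_motion"))
  if (any(Z <= 0)) abort("`Z` must be positive (point in front of the camera)")
  f <- camera$f
  v <- motion$v
  w <- motion$omega
  u_t <- (-f * v[1] + x * v[3]) / Z
  v_t <- (-f * v[2] + y * v[3]) / Z
  u_r <- (x * y * w[1] - (f^2 + x^2) * w[2] + f * y * w[3]) / f
  v_r <- ((f^2 + y^2) * w[1] - x * y * w[2] - f * x * w[3]) / f
  tibble(x = x, y = y, u = u_t + u_r, v = v_t + v_r)
}

#' Depth of a moving plane along a view ray
#'
#' For a static plane `n . X = d(t)` with `d(t) = d0 - t v.n` approached with
#' linear velocity `v`, the viewed depth at image point `(x, y)` is
#' `Z = f (d0 - t v.n) / (p . n)`, `p = (x, y, f)`. Rays parallel to the
#' plane (`p.n = 0`) and samples behind the camera (`Z <= 0`) are degenerate.
#'
#' @inheritParams general_flow
#' @param t Time (s), scalar.
#' @param layer A [translational_layer()].
#' @param on_degenerate `"error"` to fail on degenerate samples, `"na"` to
#'   return `NA` for them (used by whole-field renders, where isolated
#'   degenerate grid points must not halt a sweep).
#' @return Depth in metres, same length as `x`.
#' @export
plane_depth <- function(x, y, t, layer, camera,
                        on_degenerate = c("error", "na")) {
  stopifnot(inherits(layer, "translational_layer"))
  on_degenerate <- match.arg(on_degenerate)
  f <- camera$f
  n <- layer$normal
  pn <- x * n[1] + y * n[2] + f * n[3]
  num <- f * (layer$d0 - t * sum(layer$v * n))
  Z <- num / pn
  bad <- pn == 0 | Z <= 0
  if (any(bad)) {
    if (on_degenerate == "error") {
      abort("degenerate plane depth: ray parallel to plane or point behind camera")
    }
    Z[bad] <- NA_real_
  }
  Z
}

## ---- internal layer evaluators -------------------------------------------
## All are vectorised over x, y with scalar t, and return plain lists of
## numeric vectors; `ok` flags samples with a valid (positive) depth.

flow_uv <- function(layer, f, x, y, t = 0) UseMethod("flow_uv")
jacobian_uv <- function(layer, f, x, y, t = 0) UseMethod("jacobian_uv")
dflow_uv <- function(layer, f, x, y, t = 0, order = 1) UseMethod("dflow_uv")

# a(v) = (-f v_x + x v_z, -f v_y + y v_z): the translational direction field.
a_field <- function(f, x, y, v) {
  list(ax = -f * v[1] + x * v[3], ay = -f * v[2] + y * v[3])
}

#' @export
flow_uv.translational_layer <- function(layer, f, x, y, t = 0) {
  n <- layer$normal
  v <- layer$v
  D <- layer$d0 - t * sum(v * n)
  pn <- x * n[1] + y * n[2] + f * n[3]
  g <- pn / (f * D)
  a <- a_field(f, x, y, v)
  ok <- pn != 0 & (D / pn) > 0
  list(u = g * a$ax, v = g * a$ay, ok = ok)
}

#' @export
jacobian_uv.translational_layer <- function(layer, f, x, y, t = 0) {
  n <- layer$normal
  v <- layer$v
  D <- layer$d0 - t * sum(v * n)
  g <- (x * n[1] + y * n[2] + f * n[3]) / (f * D)
  a <- a_field(f, x, y, v)
  list(
    jxx = n[1] / (f * D) * a$ax + g * v[3],
    jxy = n[2] / (f * D) * a$ax,
    jyx = n[1] / (f * D) * a$ay,
    jyy = n[2] / (f * D) * a$ay + g * v[3]
  )
}

#' @export
dflow_uv.translational_layer <- function(layer, f, x, y, t = 0, order = 1) {
  n <- layer$normal
  v <- layer$v
  vn <- sum(v * n)
  D <- layer$d0 - t * vn
  pn <- x * n[1] + y * n[2] + f * n[3]
  a <- a_field(f, x, y, v)
  fac <- if (order == 1) pn * vn / (f * D^2) else 2 * pn * vn^2 / (f * D^3)
  list(u = fac * a$ax, v = fac * a$ay)
}

# G(t) = (x sin wt + f cos wt) / (f (d0 - r sin wt)) and its time derivatives,
# the depth-geometry factor of the co-rotating fronto-parallel plane.
curvi_G <- function(layer, f, x, t) {
  w <- layer$omega
  r <- layer$radius
  s <- sin(w * t)
  cth <- cos(w * t)
  N <- x * s + f * cth
  D <- f * (layer$d0 - r * s)
  N1 <- w * (x * cth - f * s)
  N2 <- -w^2 * N
  D1 <- -f * w * r * cth
  D2 <- f * w^2 * r * s
  list(
    G = N / D,
    G1 = (N1 * D - N * D1) / D^2,
    G2 = N2 / D - 2 * N1 * D1 / D^2 - N * D2 / D^2 + 2 * N * D1^2 / D^3,
    D = D
  )
}

#' @export
flow_uv.curvilinear_fronto_layer <- function(layer, f, x, y, t = 0) {
  g <- curvi_G(layer, f, x, t)
  wr <- layer$omega * layer$radius
  w <- layer$omega
  list(
    u = g$G * wr * x - (w / f) * (f^2 + x^2),
    v = g$G * wr * y - (w / f) * x * y,
    ok = rep(g$D > 0, length.out = length(x)) & (g$G * f) > 0
  )
}

#' @export
jacobian_uv.curvilinear_fronto_layer <- function(layer, f, x, y, t = 0) {
  w <- layer$omega
  r <- layer$radius
  s <- sin(w * t)
  g <- curvi_G(layer, f, x, t)
  dGdx <- s / (f * (layer$d0 - r * s))
  wr <- w * r
  list(
    jxx = dGdx * wr * x + g$G * wr - 2 * w * x / f,
    jxy = rep(0, length(x)),
    jyx = dGdx * wr * y - w * y / f,
    jyy = g$G * wr - w * x / f
  )
}

#' @export
dflow_uv.curvilinear_fronto_layer <- function(layer, f, x, y, t = 0, order = 1) {
  g <- curvi_G(layer, f, x, t)
  wr <- layer$omega * layer$radius
  fac <- if (order == 1) g$G1 else g$G2
  list(u = fac * wr * x, v = fac * wr * y)
}

#' @export
flow_uv.curvilinear_ground_layer <- function(layer, f, x, y, t = 0) {
  w <- layer$omega
  k <- w * layer$radius * y / (f * layer$height)
  # the ground-plane flow expression is a polynomial defined at every image
  # point; inverting it for depth is what requires y/h > 0, not evaluation
  list(
    u = k * x - (w / f) * (f^2 + x^2),
    v = k * y - (w / f) * x * y,
    ok = rep(TRUE, length(x))
  )
}

#' @export
jacobian_uv.curvilinear_ground_layer <- function(layer, f, x, y, t = 0) {
  w <- layer$omega
  r <- layer$radius
  h <- layer$height
  list(
    jxx = w * r * y / (f * h) - 2 * w * x / f,
    jxy = w * r * x / (f * h),
    jyx = -w * y / f,
    jyy = 2 * w * r * y / (f * h) - w * x / f
  )
}

#' @export
dflow_uv.curvilinear_ground_layer <- function(layer, f, x, y, t = 0, order = 1) {
  list(u = rep(0, length(x)), v = rep(0, length(x)))
}

## ---- public layer interface ----------------------------------------------

#' Evaluate a flow layer
#'
#' `layer_flow()` evaluates the layer's analytic flow; `layer_jacobian()` its
#' spatial derivatives; `layer_acceleration()` its Eulerian temporal
#' derivative of given order (the flow's rate of change at a fixed image
#' location). The ground-plane layer is time-invariant, so its temporal
#' derivatives vanish identically.
#'
#' @param layer A `flow_layer`.
#' @param x,y Image coordinates (m), vectorised.
#' @param camera A [pinhole_camera()].
#' @param t Time (s), scalar.
#' @param order 1 or 2 (temporal derivative order).
#' @return A tibble: `x`, `y` plus `u`, `v` (flow or temporal derivative) or
#'   `jxx`, `jxy`, `jyx`, `jyy` (Jacobian entries `d(u,v)/d(x,y)`).
#' @export
layer_flow <- function(layer, x, y, camera, t = 0) {
  z <- flow_uv(layer, camera$f, x, y, t)
  tibble(x = x, y = y, u = z$u, v = z$v)
}

#' @rdname layer_flow
#' @export
layer_jacobian <- function(layer, x, y, camera, t = 0) {
  z <- jacobian_uv(layer, camera$f, x, y, t)
  tibble(x = x, y = y, jxx = z$jxx, jxy = z$jxy, jyx = z$jyx, jyy = z$jyy)
}

#' @rdname layer_flow
#' @export
layer_acceleration <- function(layer, x, y, camera, t = 0, order = 1) {
  z <- dflow_uv(layer, camera$f, x, y, t, order = order)
  tibble(x = x, y = y, u = z$u, v = z$v)
}

## ---- model-instance convenience wrappers ---------------------------------

#' Model-instance flow fields
#'
#' Convenience wrappers for the three scene/motion instances; each is an
#' algebraic specialisation of [general_flow()] with the appropriate depth
#' function substituted.
#'
#' @inheritParams layer_flow
#' @param d0 Initial plane distance (m).
#' @param v Linear velocity, length-3 (m/s).
#' @param normal Plane unit normal.
#' @param omega Yaw rate (rad/s).
#' @param radius Path radius (m).
#' @param height Camera height over ground (m, signed).
#' @return A tibble with `x`, `y`, `u`, `v`.
#' @export
translational_plane_flow <- function(x, y, camera, d0, v,
                                     normal = c(0, 0, 1), t = 0) {
  layer_flow(translational_layer(d0, v, normal), x, y, camera, t)
}

#' @rdname translational_plane_flow
#' @export
curvilinear_fronto_flow <- function(x, y, camera, d0, omega, radius, t = 0) {
  if (d0 - radius * sin(omega * t) <= 0) {
    abort("plane has passed the camera: d0 - r sin(wt) must be positive")
  }
  layer_flow(curvilinear_fronto_layer(d0, omega, radius), x, y, camera, t)
}

#' @rdname translational_plane_flow
#' @export
curvilinear_ground_flow <- function(x, y, camera, omega, radius, height) {
  layer_flow(curvilinear_ground_layer(height, omega, radius), x, y, camera)
}

## ---- layered scenes and rasterisation ------------------------------------

#' Flow of a two-layer scene
#'
#' Evaluates the composite flow of background plus IMO: points inside the
#' (closed) IMO region take the IMO layer's flow and the label `"I"`, all
#' others the background's and `"B"`.
#'
#' @param scene A [layered_scene()].
#' @param x,y Image coordinates (m), vectorised.
#' @param t Time (s), scalar.
#' @return A tibble `x`, `y`, `u`, `v`, `layer`, `ok` (`ok` flags samples
#'   with valid positive depth).
#' @export
layered_flow <- function(scene, x, y, t = 0) {
  f <- scene$camera$f
  B <- flow_uv(scene$background, f, x, y, t)
  u <- B$u
  v <- B$v
  ok <- B$ok
  lab <- rep("B", length(x))
  if (!is.null(scene$imo)) {
    inside <- in_region(scene$imo, x, y)
    if (any(inside)) {
      I <- flow_uv(scene$imo_layer, f, x[inside], y[inside], t)
      u[inside] <- I$u
      v[inside] <- I$v
      ok[inside] <- I$ok
      lab[inside] <- "I"
    }
  }
  tibble(x = x, y = y, u = u, v = v, layer = lab, ok = ok)
}

#' Rasterise a scene into a flow field
#'
#' Samples [layered_flow()] on a regular, cell-centred grid covering the
#' image plane `[-w/2, w/2] x [-h/2, h/2]`. Cell centres are at
#' `-w/2 + (i - 1/2) dx`. The result is deterministic. Degenerate samples
#' (invalid depth) keep `ok = FALSE` and are excluded from downstream
#' integrals; their count is reported via the `n_degenerate` attribute.
#'
#' @param scene A [layered_scene()].
#' @param t Time (s).
#' @param nx,ny Grid resolution (cells across width and height).
#' @return A tibble of class `flow_field` with attributes `camera`, `t`,
#'   `nx`, `ny`, `dx`, `dy`, `n_degenerate`.
#' @export
render_flow_field <- function(scene, t = 0, nx = 65, ny = nx) {
  stopifnot(nx >= 1, ny >= 1)
  cam <- scene$camera
  dx <- cam$width / nx
  dy <- cam$height / ny
  xs <- -cam$width / 2 + (seq_len(nx) - 0.5) * dx
  ys <- -cam$height / 2 + (seq_len(ny) - 0.5) * dy
  g <- tidyr::expand_grid(y = ys, x = xs)[, c("x", "y")]
  out <- layered_flow(scene, g$x, g$y, t)
  structure(
    out,
    class = c("flow_field", class(out)),
    camera = cam, t = t, nx = nx, ny = ny, dx = dx, dy = dy,
    n_degenerate = sum(!out$ok)
  )
}
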