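#' Inverse time-to-contact of an approached plane
#'
#' For a fronto-parallel plane at initial distance `d0` approached at speed
#' `v_z`, the time to contact is `t_c = d0 / v_z` and the flow model's scale
#' factor at time `t` is `gamma = 1 / (t_c - t)`. The name distinguishes this
#' quantity from the temporal-curvature cue, which shares its conventional
#' symbol.
#'
#' @param d0 Initial distance (m).
#' @param v_z Approach speed (m/s), positive.
#' @param t Evaluation time (s), before contact.
#' @return `gamma` in 1/s.
#' @export
inverse_ttc <- function(d0, v_z, t = 0) {
  if (v_z <= 0) abort("`v_z` must be positive for a defined time-to-contact")
  tc <- d0 / v_z
  if (any(t >= tc)) abort("evaluation time is at or past contact")
  1 / (tc - t)
}

## reciprocal-depth factor mu = 1/(d0 - t v_z) of a fronto-parallel
## translational layer
layer_mu <- function(layer, t) {
  d <- layer$d0 - t * layer$v[3]
  if (d <= 0) abort("layer has passed the camera at this time")
  1 / d
}

assert_fronto <- function(layer, what) {
  if (!inherits(layer, "translational_layer") ||
      any(layer$normal != c(0, 0, 1))) {
    abort(paste0(what, " must be a fronto-parallel translational layer"))
  }
}

## Integrals of (x - xdot/gamma) over a centred rectangle for a layer with
## reciprocal depth mu and velocity v: the integrand is linear, so the
## rectangle integral is area times the midpoint value.
i1_rect <- function(xc, yc, area, mu, v, gamma, f) {
  k <- 1 - mu * v[3] / gamma
  list(
    x = area * (xc * k + f * mu * v[1] / gamma),
    y = area * (yc * k + f * mu * v[2] / gamma)
  )
}

#' Least-squares estimate of the focus of expansion
#'
#' Minimises the squared residual between the registered flow and the
#' linear-motion model `gamma (-f eta + x, -f zeta + y)` over the image
#' plane, giving
#' `eta_hat = integral(x - u/gamma) / (f integral(1))` (and symmetrically
#' `zeta_hat`). With an IMO present, the integration splits into background
#' and object regions and the object region is weighted by `(1 - s)`, where
#' `s` is the segmentation signal: `s = 0` integrates everything, `s = 1`
#' discounts the object region entirely and removes its bias.
#'
#' `estimate_foe()` evaluates the integrals in closed form for analytic
#' fronto-parallel translational layers (the integrands are linear in x and
#' y). `estimate_foe_field()` integrates a rasterised [render_flow_field()]
#' by cell-centred sums, weighting whole cells whose centres fall inside the
#' IMO region; it converges to the analytic value at second order in the
#' grid spacing.
#'
#' @param scene A [layered_scene()] whose layers are fronto-parallel
#'   translational layers.
#' @param t Snapshot time (s).
#' @param gamma Inverse time-to-contact of the background; defaults to the
#'   background layer's true `v_z mu_B(t)` (assumed known, e.g. from
#'   binocular disparity).
#' @param s Segmentation weight in `[0, 1]`.
#' @return An object of class `foe_fit` with elements `eta_hat`, `zeta_hat`,
#'   `eta_true`, `zeta_true`, `bias`, `bias_deg` (difference of the
#'   arctangent headings, degrees), `s`, `gamma`, `method`.
#' @export
estimate_foe <- function(scene, t = 0, gamma = NULL, s = 0) {
  stopifnot(inherits(scene, "layered_scene"), s >= 0, s <= 1)
  bg <- scene$background
  cam <- scene$camera
  assert_fronto(bg, "background")
  mu_b <- layer_mu(bg, t)
  if (is.null(gamma)) gamma <- bg$v[3] * mu_b
  if (gamma <= 0) abort("`gamma` must be positive")
  f <- cam$f
  W <- cam$width * cam$height
  i_bg <- i1_rect(0, 0, W, mu_b, bg$v, gamma, f)
  num_x <- i_bg$x
  num_y <- i_bg$y
  den <- f * W
  if (!is.null(scene$imo)) {
    assert_fronto(scene$imo_layer, "IMO layer")
    reg <- scene$imo
    A <- reg$width * reg$height
    mu_i <- layer_mu(scene$imo_layer, t)
    i_bg_reg <- i1_rect(reg$x, reg$y, A, mu_b, bg$v, gamma, f)
    i_imo_reg <- i1_rect(reg$x, reg$y, A, mu_i, scene$imo_layer$v, gamma, f)
    num_x <- num_x - i_bg_reg$x + (1 - s) * i_imo_reg$x
    num_y <- num_y - i_bg_reg$y + (1 - s) * i_imo_reg$y
    den <- f * (W - s * A)
  }
  if (den == 0) abort("zero integration area")
  new_foe_fit(num_x / den, num_y / den, bg$v, s, gamma, "analytic")
}

#' @rdname estimate_foe
#' @param field A `flow_field` from [render_flow_field()].
#' @param region Optional [imo_region()] to weight by `(1 - s)`.
#' @param v_background Optional true background velocity (length 3) used to
#'   report the bias.
#' @export
estimate_foe_field <- function(field, gamma, region = NULL, s = 0,
                               v_background = NULL) {
  stopifnot(inherits(field, "flow_field"))
  ok <- field$ok
  w <- as.numeric(ok)
  if (!is.null(region)) {
    inside <- in_region(region, field$x, field$y)
    w[inside] <- w[inside] * (1 - s)
  }
  f <- attr(field, "camera")$f
  den <- f * sum(w)
  if (den == 0) abort("zero integration area")
  eta <- sum(w * (field$x - field$u / gamma), na.rm = TRUE) / den
  zeta <- sum(w * (field$y - field$v / gamma), na.rm = TRUE) / den
  new_foe_fit(eta, zeta, v_background, s, gamma, "raster")
}

new_foe_fit <- function(eta, zeta, v_bg, s, gamma, method) {
  eta_true <- if (is.null(v_bg)) NA_real_ else v_bg[1] / v_bg[3]
  zeta_true <- if (is.null(v_bg)) NA_real_ else v_bg[2] / v_bg[3]
  structure(
    list(
      eta_hat = eta, zeta_hat = zeta,
      eta_true = eta_true, zeta_true = zeta_true,
      bias = eta - eta_true,
      bias_deg = rad2deg(atan(eta) - atan(eta_true)),
      s = s, gamma = gamma, method = method
    ),
    class = "foe_fit"
  )
}

#' Closed-form heading bias of the unsegmented estimator
#'
#' Exact evaluation of the split least-squares integrals for a two-layer
#' translational scene: the horizontal FOE bias is
#' \deqn{\Delta\eta = \frac{(1-s)\, w_I h_I}{w_B h_B - s\, w_I h_I}
#'   \left(-\eta_B + \frac{x_I}{f}\Bigl(1 - \frac{\mu_I v_{z,I}}{\mu_B v_{z,B}}\Bigr)
#'   + \frac{\mu_I v_{x,I}}{\mu_B v_{z,B}}\right)}
#' with `mu = 1/(d0 - t v_z)` the reciprocal depths. The bias vanishes for
#' full segmentation (`s = 1`) or a zero-area object, is proportional to the
#' object's area at `s = 0`, and is independent of the object's vertical
#' position and of all vertical velocity components.
#'
#' @param mu_B,mu_I Reciprocal depths of background and object (1/m).
#' @param v_B,v_I Velocities of background and object (m/s): length-3
#'   vectors, or n-by-3 matrices for vectorised evaluation.
#' @param x_I Horizontal object-centre position (m).
#' @param w_I,h_I Object extent (m).
#' @param w_B,h_B Image extent (m).
#' @param f Focal length (m).
#' @param s Segmentation weight in `[0, 1]`.
#' @return Dimensionless horizontal FOE bias.
#' @export
heading_bias <- function(mu_B, mu_I, v_B, v_I, x_I, w_I, h_I,
                         w_B, h_B, f, s = 0) {
  comp <- function(v, i) if (is.matrix(v)) v[, i] else v[i]
  if (any(comp(v_B, 3) == 0)) {
    abort("background must approach: v_z,B must be nonzero")
  }
  A <- w_I * h_I
  W <- w_B * h_B
  (1 - s) * A / (W - s * A) *
    (-comp(v_B, 1) / comp(v_B, 3) +
       (x_I / f) * (1 - mu_I * comp(v_I, 3) / (mu_B * comp(v_B, 3))) +
       mu_I * comp(v_I, 1) / (mu_B * comp(v_B, 3)))
}

#' Local radius of a curvilinear path from a single flow sample
#'
#' For curvilinear motion over a ground plane at height `h`, each
#' nondegenerate flow sample determines the path radius linearly:
#' `r_hat = h (u x y - (f^2 + x^2) v) / (u y^2 - x y v)`. The estimate is
#' invariant to any common rescaling of `(u, v)` (the yaw rate cancels) and
#' degenerates on the horizon (`y = 0`) and wherever the denominator
#' vanishes; such samples return `NA`.
#'
#' @param x,y Image coordinates (m), vectorised.
#' @param u,v Flow components (m/s).
#' @param height Camera height over ground (m, signed).
#' @param camera A [pinhole_camera()].
#' @return Radius estimates (m), `NA` where degenerate.
#' @export
estimate_radius_local <- function(x, y, u, v, height, camera) {
  f <- camera$f
  num <- u * x * y - (f^2 + x^2) * v
  den <- u * y^2 - x * y * v
  out <- height * num / den
  out[den == 0] <- NA_real_
  out
}

## integral of y^2 over a centred rectangle
s2_rect <- function(yc, area, h_r) area * (yc^2 + h_r^2 / 12)

#' Integrated radius estimate for curvilinear motion
#'
#' Improves on the pointwise constraint by integrating numerator and
#' denominator separately over the image:
#' `r_hat = h I3 / I4` with `I3 = integral(u x y - (f^2+x^2) v)` and
#' `I4 = integral(u y^2 - x y v)`, the IMO region weighted by `(1 - s)`.
#' For a rigid ground-plane flow both integrands share the factor `r`, so
#' the ratio `rho_r = r_hat / r_B` equals one exactly; an IMO with its own
#' path parameters biases it. `estimate_radius()` uses the closed-form
#' rectangle integrals (the integrands are polynomial);
#' `estimate_radius_field()` integrates a rasterised field.
#'
#' @param scene A [layered_scene()] with a ground-plane background and,
#'   optionally, a fronto-parallel curvilinear IMO layer.
#' @param s Segmentation weight in `[0, 1]`.
#' @return An object of class `radius_fit` with `r_hat`, `r_true`, `ratio`,
#'   `s`, `method`.
#' @export
estimate_radius <- function(scene, s = 0) {
  stopifnot(inherits(scene, "layered_scene"), s >= 0, s <= 1)
  bg <- scene$background
  cam <- scene$camera
  if (!inherits(bg, "curvilinear_ground_layer")) {
    abort("background must be a curvilinear ground-plane layer")
  }
  f <- cam$f
  h <- bg$height
  S2_img <- s2_rect(0, cam$width * cam$height, cam$height)
  ## background integrands: I3 = -r w f y^2 / h, I4 = -w f y^2
  i3 <- -bg$radius * bg$omega * f / h * S2_img
  i4 <- -bg$omega * f * S2_img
  if (!is.null(scene$imo)) {
    il <- scene$imo_layer
    if (!inherits(il, "curvilinear_fronto_layer")) {
      abort("IMO layer must be a curvilinear fronto-parallel layer")
    }
    reg <- scene$imo
    A <- reg$width * reg$height
    S2_reg <- s2_rect(reg$y, A, reg$height)
    ## IMO integrands at t = 0: I3 = -w_I r_I f^2 y / d_I, I4 = -w_I f y^2
    i3 <- i3 - (-bg$radius * bg$omega * f / h * S2_reg) +
      (1 - s) * (-il$omega * il$radius * f^2 / il$d0 * A * reg$y)
    i4 <- i4 - (-bg$omega * f * S2_reg) +
      (1 - s) * (-il$omega * f * S2_reg)
  }
  if (i4 == 0) abort("degenerate radius estimate: zero denominator integral")
  new_radius_fit(h * i3 / i4, bg$radius, s, "analytic")
}

#' @rdname estimate_radius
#' @param field A `flow_field` from [render_flow_field()].
#' @param height Camera height over ground (m, signed).
#' @param region Optional [imo_region()] to weight by `(1 - s)`.
#' @param r_true Optional true background radius for the ratio.
#' @export
estimate_radius_field <- function(field, height, region = NULL, s = 0,
                                  r_true = NA_real_) {
  stopifnot(inherits(field, "flow_field"))
  f <- attr(field, "camera")$f
  w <- as.numeric(field$ok)
  if (!is.null(region)) {
    inside <- in_region(region, field$x, field$y)
    w[inside] <- w[inside] * (1 - s)
  }
  i3 <- sum(w * (field$u * field$x * field$y -
                   (f^2 + field$x^2) * field$v), na.rm = TRUE)
  i4 <- sum(w * (field$u * field$y^2 -
                   field$x * field$y * field$v), na.rm = TRUE)
  if (i4 == 0) abort("degenerate radius estimate: zero denominator integral")
  new_radius_fit(height * i3 / i4, r_true, s, "raster")
}

new_radius_fit <- function(r_hat, r_true, s, method) {
  structure(
    list(r_hat = r_hat, r_true = r_true,
         ratio = r_hat / r_true, s = s, method = method),
    class = "radius_fit"
  )
}

#' Closed-form radius-ratio bias
#'
#' Exact evaluation of the split radius integrals for a ground-plane
#' background (yaw `omega_B`, radius `r_B`, camera height `height`) with a
#' fronto-parallel IMO (distance `d_I`, yaw `omega_I`, radius `r_I`) in the
#' region centred at height `y_I` with extent `w_I x h_I`:
#' \deqn{\rho_r = \frac{(\omega_B/\omega_I)\, r_B\, Q + (1-s)\, f h\, (r_I/d_I)\, w_I h_I y_I}
#'  {r_B \left[(\omega_B/\omega_I)\, Q + (1-s)\, S_I\right]}}
#' where `Q = w_B h_B^3/12 - S_I` and `S_I = w_I h_I (y_I^2 + h_I^2/12)` are
#' the `y^2` moments of the background and object regions. The ratio is one
#' for full segmentation or a zero-area object, and is independent of the
#' object's horizontal position.
#'
#' @param omega_B,omega_I Yaw rates (rad/s).
#' @param r_B,r_I Path radii (m).
#' @param d_I Object-plane distance (m).
#' @param y_I Object-centre height in the image (m).
#' @param w_I,h_I Object extent (m).
#' @param w_B,h_B Image extent (m).
#' @param height Camera height over ground (m, signed).
#' @param f Focal length (m).
#' @param s Segmentation weight in `[0, 1]`.
#' @return Dimensionless ratio `r_hat / r_B`.
#' @export
radius_ratio <- function(omega_B, omega_I, r_B, r_I, d_I, y_I, w_I, h_I,
                         w_B, h_B, height, f, s = 0) {
  S_img <- w_B * h_B^3 / 12
  S_I <- w_I * h_I * (y_I^2 + h_I^2 / 12)
  Q <- S_img - S_I
  wr <- omega_B / omega_I
  num <- wr * r_B * Q + (1 - s) * f * height * (r_I / d_I) * w_I * h_I * y_I
  den <- r_B * (wr * Q + (1 - s) * S_I)
  if (any(den == 0)) abort("degenerate radius ratio: zero denominator")
  num / den
}

#' Predicted image-plane path under curvilinear motion
#'
#' Assuming heading tangent to a circular path of radius `r` at yaw rate
#' `omega` and camera height `h`, the future path projects onto the image as
#' `x(t) = f (1/sin(wt) - tan(wt))`, `y(t) = -f (h/r) / |sin(wt)|` for
#' `wt` in `(0, pi/2)`. As `wt` approaches `pi/2` the y-component tends to
#' `-f h/r` (the point of the orbit furthest from its centre); the absolute
#' value makes the curve independent of the sign of `omega`.
#'
#' @param t Times (s), vectorised.
#' @param omega Yaw rate (rad/s).
#' @param radius Path radius (m).
#' @param height Camera height (m, signed).
#' @param camera A [pinhole_camera()].
#' @return A tibble `t`, `x`, `y` (m).
#' @export
predicted_path <- function(t, omega, radius, height, camera) {
  th <- omega * t
  if (any(abs(th) <= 0) || any(abs(th) >= pi / 2)) {
    abort("`omega * t` must lie in (0, pi/2) in magnitude")
  }
  f <- camera$f
  tibble(
    t = t,
    x = f * (1 / sin(th) - tan(th)),
    y = -f * (height / radius) / abs(sin(th))
  )
}

## ---- broom-style methods --------------------------------------------------

#' @export
print.foe_fit <- function(x, ...) {
  cat(sprintf(
    "<foe_fit (%s)> eta_hat = %.6g, zeta_hat = %.6g, s = %.3g\n",
    x$method, x$eta_hat, x$zeta_hat, x$s
  ))
  if (!is.na(x$eta_true)) {
    cat(sprintf("  true eta = %.6g, bias = %.3g (%.3g deg)\n",
                x$eta_true, x$bias, x$bias_deg))
  }
  invisible(x)
}

#' @export
print.radius_fit <- function(x, ...) {
  cat(sprintf("<radius_fit (%s)> r_hat = %.6g m, ratio = %.6g, s = %.3g\n",
              x$method, x$r_hat, x$ratio, x$s))
  invisible(x)
}

#' Tidy estimator results
#'
#' @param x A `foe_fit` or `radius_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated quantity (`tidy`) or a
#'   one-row model summary (`glance`).
#' @export
tidy.foe_fit <- function(x, ...) {
  tibble(
    term = c("eta", "zeta"),
    estimate = c(x$eta_hat, x$zeta_hat),
    truth = c(x$eta_true, x$zeta_true),
    bias = c(x$eta_hat - x$eta_true, x$zeta_hat - x$zeta_true)
  )
}

#' @rdname tidy.foe_fit
#' @export
glance.foe_fit <- function(x, ...) {
  tibble(
    eta_hat = x$eta_hat, zeta_hat = x$zeta_hat, bias = x$bias,
    bias_deg = x$bias_deg, s = x$s, gamma = x$gamma, method = x$method
  )
}

#' @rdname tidy.foe_fit
#' @export
tidy.radius_fit <- function(x, ...) {
  tibble(term = "radius", estimate = x$r_hat, truth = x$r_true,
         ratio = x$ratio)
}

#' @rdname tidy.foe_fit
#' @export
glance.radius_fit <- function(x, ...) {
  tibble(r_hat = x$r_hat, r_true = x$r_true, ratio = x$ratio, s = x$s,
         method = x$method)
}
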