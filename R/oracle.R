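#' Three-snapshot flow stack
#'
#' Renders a scene at `t - dt`, `t`, `t + dt` on a shared grid, the minimal
#' stack supporting central temporal differences of the flow at a fixed
#' image location.
#'
#' @param scene A [layered_scene()].
#' @param t Centre time (s).
#' @param dt Snapshot spacing (s); defaults to one frame at 25 Hz.
#' @param nx,ny Grid resolution.
#' @return A list of class `flow_stack` with elements `before`, `centre`,
#'   `after` (each a `flow_field`) and `dt`.
#' @export
flow_stack <- function(scene, t = 0, dt = 1 / 25, nx = 65, ny = nx) {
  if (dt <= 0) abort("`dt` must be positive")
  structure(
    list(
      before = render_flow_field(scene, t - dt, nx, ny),
      centre = render_flow_field(scene, t, nx, ny),
      after = render_flow_field(scene, t + dt, nx, ny),
      dt = dt
    ),
    class = "flow_stack"
  )
}

field_index <- function(field, i, j) {
  ## column i (x index), row j (y index) of the rendered grid
  nx <- attr(field, "nx")
  (j - 1) * nx + i
}

#' Finite-difference spatial Jacobian of a rendered field
#'
#' Central differences on the rendered grid; second-order accurate, exact
#' for fields linear in x and y. Border cells have no neighbours and raise
#' an error.
#'
#' @param field A `flow_field` from [render_flow_field()].
#' @param i,j Column/row indices of the evaluation cell (1-based).
#' @return A one-row tibble `x`, `y`, `jxx`, `jxy`, `jyx`, `jyy`.
#' @export
fd_jacobian <- function(field, i, j) {
  nx <- attr(field, "nx")
  ny <- attr(field, "ny")
  if (i <= 1 || i >= nx || j <= 1 || j >= ny) {
    abort("finite differences need one interior cell of margin")
  }
  dx <- attr(field, "dx")
  dy <- attr(field, "dy")
  c0 <- field_index(field, i, j)
  xm <- field_index(field, i - 1, j)
  xp <- field_index(field, i + 1, j)
  ym <- field_index(field, i, j - 1)
  yp <- field_index(field, i, j + 1)
  tibble(
    x = field$x[c0], y = field$y[c0],
    jxx = (field$u[xp] - field$u[xm]) / (2 * dx),
    jxy = (field$u[yp] - field$u[ym]) / (2 * dy),
    jyx = (field$v[xp] - field$v[xm]) / (2 * dx),
    jyy = (field$v[yp] - field$v[ym]) / (2 * dy)
  )
}

#' Finite-difference temporal derivatives of a flow stack
#'
#' Central first difference and three-point second difference of the flow at
#' every fixed grid location (Eulerian derivatives).
#'
#' @param stack A [flow_stack()].
#' @return A tibble `x`, `y`, `du`, `dv` (first derivative, m/s^2), `ddu`,
#'   `ddv` (second derivative, m/s^3).
#' @export
fd_time <- function(stack) {
  b <- stack$before
  c0 <- stack$centre
  a <- stack$after
  dt <- stack$dt
  tibble(
    x = c0$x, y = c0$y,
    du = (a$u - b$u) / (2 * dt),
    dv = (a$v - b$v) / (2 * dt),
    ddu = (a$u - 2 * c0$u + b$u) / dt^2,
    ddv = (a$v - 2 * c0$v + b$v) / dt^2
  )
}

#' Composite numeric contour integral
#'
#' Independent cross-check for [contour_cue_strength()]: composite
#' Gauss-Legendre quadrature with `panels` subintervals per edge (rather
#' than a single high-order rule), identical absolute-value edge
#' combination.
#'
#' @inheritParams contour_cue_strength
#' @param panels Number of subintervals per edge.
#' @param nodes_per_panel Gauss-Legendre nodes per subinterval.
#' @return Nonnegative strength.
#' @export
numeric_contour_strength <- function(cue_fun, region, panels = 16,
                                     nodes_per_panel = 4) {
  edge_integral <- function(fixed, from, to, beta, vertical) {
    breaks <- seq(from, to, length.out = panels + 1)
    total <- 0
    for (k in seq_len(panels)) {
      gl <- pracma::gaussLegendre(nodes_per_panel, breaks[k], breaks[k + 1])
      val <- if (vertical) {
        cue_fun(rep(fixed, nodes_per_panel), gl$x, beta)
      } else {
        cue_fun(gl$x, rep(fixed, nodes_per_panel), beta)
      }
      total <- total + sum(gl$w * val)
    }
    total
  }
  xl <- region$x - region$width / 2
  xr <- region$x + region$width / 2
  yb <- region$y - region$height / 2
  yt <- region$y + region$height / 2
  abs(edge_integral(xr, yb, yt, 0, TRUE)) +
    abs(edge_integral(yt, xl, xr, pi / 2, FALSE)) +
    abs(edge_integral(xl, yb, yt, pi, TRUE)) +
    abs(edge_integral(yb, xl, xr, 3 * pi / 2, FALSE))
}

## built-in validation scenarios for fixture generation
fixture_scene <- function(scenario) {
  cam <- pinhole_camera(focal_length = 0.0174, width = 0.01)
  switch(scenario,
    translation_background = list(
      scene = layered_scene(
        cam, translational_layer(10, c(0.35, 0, 2))
      ),
      truth = list(eta = 0.35 / 2, zeta = 0)
    ),
    translation_imo = list(
      scene = layered_scene(
        cam, translational_layer(10, c(0.35, 0, 2)),
        imo = imo_region_deg(-6, 0, 10, 10, cam),
        imo_layer = translational_layer(10, c(-0.2, 0, 3))
      ),
      truth = list(eta = 0.35 / 2, zeta = 0)
    ),
    curvilinear_ground = list(
      scene = layered_scene(
        cam, curvilinear_ground_layer(-1.65, 13.2 / 120, 120)
      ),
      truth = list(radius = 120)
    ),
    abort(sprintf("unknown fixture scenario '%s'", scenario))
  )
}

#' Generate a validation fixture
#'
#' Renders a named scenario into a three-snapshot [flow_stack()], optionally
#' adds isotropic Gaussian noise to the flow vectors (a robustness probe;
#' the analytic models themselves are noise-free), and attaches the
#' ground-truth metadata. Deterministic for a fixed seed.
#'
#' @param scenario One of `"translation_background"`, `"translation_imo"`,
#'   `"curvilinear_ground"`.
#' @param nx,ny Grid resolution.
#' @param dt Temporal spacing (s).
#' @param noise_sd Standard deviation of additive flow noise (m/s).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return A list of class `flow_fixture`: `stack`, `scene`, `truth`,
#'   `scenario`, `noise_sd`, `seed`.
#' @export
generate_fixture <- function(scenario, nx = 65, ny = nx, dt = 1 / 25,
                             noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative")
  fx <- fixture_scene(scenario)
  stack <- flow_stack(fx$scene, t = 0, dt = dt, nx = nx, ny = ny)
  if (noise_sd > 0) {
    rng <- local({
      set.seed(seed)
      lapply(1:3, function(k) {
        n <- nrow(stack$centre)
        list(u = stats::rnorm(n, 0, noise_sd),
             v = stats::rnorm(n, 0, noise_sd))
      })
    })
    parts <- c("before", "centre", "after")
    for (k in seq_along(parts)) {
      stack[[parts[k]]]$u <- stack[[parts[k]]]$u + rng[[k]]$u
      stack[[parts[k]]]$v <- stack[[parts[k]]]$v + rng[[k]]$v
    }
  }
  structure(
    list(stack = stack, scene = fx$scene, truth = fx$truth,
         scenario = scenario, noise_sd = noise_sd, seed = seed),
    class = "flow_fixture"
  )
}
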