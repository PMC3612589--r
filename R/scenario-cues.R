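#' Closed-form per-layer cue terms for the three model instances
#'
#' For each scene/motion instance the five cues admit closed forms in the
#' layer parameters; the layer-difference cue is obtained by subtracting the
#' background term from the IMO term (or, for accretion/deletion, background
#' minus IMO). These expressions were derived independently of the generic
#' operators in [cue_field()] and serve as their algebraic cross-check.
#'
#' Per layer at `t = 0`, with `a(v) = (-f v_x + x v_z, -f v_y + y v_z)`,
#' `bvec = (f^2 + x^2, x y)` and `n = (cos b, sin b)`:
#'
#' * translation/plane (fronto-parallel, distance `d0`, velocity `v`):
#'   flow-normal term `a(v).n / d0`, divergence `2 v_z / d0`, acceleration
#'   term `v_z a(v).n / d0^2`, both curvatures 0.
#' * curvilinear/fronto-parallel (distance `d0`, yaw `w`, radius `r`):
#'   flow-normal term `(w r / d0) p.n - (w/f) bvec.n`, divergence
#'   `w (2 r/d0 - 3 x/f)`, acceleration term
#'   `(x d0 + r f)/(f d0^2) w^2 r p.n`, spatial curvature
#'   `sign(w) y (x r/d0 - (f^2+x^2)/f) / |q|^3`, temporal curvature
#'   `-sign(w) r y (x d0 + f r)/d0^2 / |q|^3`, where
#'   `q = (r x/d0 - (f^2+x^2)/f, y (r/d0 - x/f))` and `p = (x, y)`.
#' * curvilinear/ground (height `h`, yaw `w`, radius `r`): flow-normal term
#'   `(y r w/(f h)) p.n - (w/f) bvec.n`, divergence `3 w (y r/(f h) - x/f)`,
#'   zero acceleration and temporal curvature, spatial curvature
#'   `-sign(w) (y/f) ((y r/h - x)^2 + f^2) / |q_g|^3` with
#'   `q_g = ((x y r/h - f^2 - x^2)/f, y (y r/h - x)/f)`.
#'
#' @param scenario One of `"translation_plane"`, `"curvilinear_fronto"`,
#'   `"curvilinear_ground"`.
#' @param cue One of `r cue_kinds`: `"accretion_deletion"`,
#'   `"expansion_contraction"`, `"acceleration"`, `"spatial_curvature"`,
#'   `"temporal_curvature"`.
#' @param x,y Image coordinates (m), vectorised.
#' @param beta Edge-normal direction (radians).
#' @param f Focal length (m).
#' @param params Named list of layer parameters: `d0`, `v` (length 3) for
#'   translation; `d0` or `height`, `omega`, `radius` for the curvilinear
#'   instances.
#' @return Numeric vector of per-layer cue terms.
#' @export
scenario_cue <- function(scenario, cue, x, y, beta, f, params) {
  scenario <- match.arg(scenario, c("translation_plane", "curvilinear_fronto",
                                    "curvilinear_ground"))
  cue <- match.arg(cue, cue_kinds)
  cb <- cos(beta)
  sb <- sin(beta)
  pn <- x * cb + y * sb
  bn <- (f^2 + x^2) * cb + x * y * sb
  if (scenario == "translation_plane") {
    d0 <- params$d0
    v <- params$v
    an <- (-f * v[1] + x * v[3]) * cb + (-f * v[2] + y * v[3]) * sb
    return(switch(cue,
      accretion_deletion = an / d0,
      expansion_contraction = rep(2 * v[3] / d0, length(x)),
      acceleration = v[3] * an / d0^2,
      spatial_curvature = ,
      temporal_curvature = rep(0, length(x))
    ))
  }
  w <- params$omega
  r <- params$radius
  if (scenario == "curvilinear_fronto") {
    d0 <- params$d0
    qx <- r * x / d0 - (f^2 + x^2) / f
    qy <- y * (r / d0 - x / f)
    q3 <- (qx^2 + qy^2)^1.5
    switch(cue,
      accretion_deletion = (w * r / d0) * pn - (w / f) * bn,
      expansion_contraction = w * (2 * r / d0 - 3 * x / f),
      acceleration = (x * d0 + r * f) / (f * d0^2) * w^2 * r * pn,
      spatial_curvature = sign_or_nan(w) * y *
        (x * r / d0 - (f^2 + x^2) / f) / q3,
      temporal_curvature = -sign_or_nan(w) * r * y *
        (x * d0 + f * r) / d0^2 / q3
    )
  } else {
    h <- params$height
    qx <- (x * y * r / h - f^2 - x^2) / f
    qy <- y * (y * r / h - x) / f
    q3 <- (qx^2 + qy^2)^1.5
    switch(cue,
      accretion_deletion = (y * r * w / (f * h)) * pn - (w / f) * bn,
      expansion_contraction = 3 * w * (y * r / (f * h) - x / f),
      acceleration = rep(0, length(x)),
      spatial_curvature = -sign_or_nan(w) * (y / f) *
        ((y * r / h - x)^2 + f^2) / q3,
      temporal_curvature = rep(0, length(x))
    )
  }
}

# curvature is undefined for a zero flow field (zero yaw): flag, not zero
sign_or_nan <- function(w) ifelse(w == 0, NaN, sign(w))

## layer-pair cue (I vs B) from per-layer closed forms; Delta is B - I,
## the others are I - B.
pair_cue <- function(cue, term_b, term_i) {
  if (cue == "accretion_deletion") term_b - term_i else term_i - term_b
}

#' Static-versus-dynamic discontinuity sweeps
#'
#' A *static discontinuity* is a pure depth step: the object layer sits
#' nearer than the background but moves consistently with it. A *dynamic
#' discontinuity* (an IMO) additionally moves with its own parameters. For
#' every point of a parameter grid both cue values are computed and a case
#' counts as a *hit* when the dynamic cue differs from the static cue by
#' more than `threshold` (default 30%) of the static cue's magnitude,
#' using a strict inequality. A case whose static cue is exactly zero counts
#' as a hit whenever the dynamic cue differs from it (the criterion
#' degenerates gracefully: `0.3 * 0 = 0`); a case where the static cue is
#' zero *and* the dynamic difference is zero carries no information and is
#' excluded from the denominator (counted as degenerate), as are samples
#' where a cue is undefined (zero-speed curvature).
#'
#' `sweep_translational()` sweeps linear motion toward two fronto-parallel
#' planes: background at `d0` with velocity `(v_x, v_y, 2)` m/s, object at
#' `d0 - delta_d` adding `(dv_x, dv_y, dv_z)`. Horizontal/vertical
#' velocities given in degrees convert via `v_z tan()` with the background's
#' `v_z = 2` m/s; `dv_z` defaults to 1 m/s (the Warren & Saunders
#' object-minus-background approach-speed difference).
#'
#' `sweep_curvilinear()` sweeps curvilinear motion (speed `v`, radius `r`,
#' yaw `w = v/r`) over a ground plane, with the object a fronto-parallel
#' plane at `d_I` moving with `(w + dw, r + dr)`; the static reference keeps
#' the depth discontinuity with `dr = dw = 0`.
#'
#' @param cues Cue kinds to evaluate (default: all five).
#' @param x,y Image-position grids (m).
#' @param beta_deg Edge-normal direction (degrees).
#' @param v_deg,dv_deg Background velocity / velocity-delta grids (degrees,
#'   applied to both the x- and y-components).
#' @param d0 Background-distance grid (m).
#' @param depth_frac Grid of `delta_d / d0` depth-step fractions.
#' @param v_z,dv_z Background approach speed and object approach-speed
#'   delta (m/s).
#' @param camera A [pinhole_camera()]; defaults to the 32-degree, 1 cm
#'   display used by the linear-motion study.
#' @param threshold Relative-difference criterion (fraction of the static
#'   cue magnitude).
#' @param keep_cases Return the per-case table (can be large) in `$cases`.
#' @return A list of class `cue_sweep`: `$summary` (tibble with `cue`,
#'   `percent`, `n_hit`, `n_eval`, `n_degenerate`, `n_undefined`, `n_total`)
#'   and optionally `$cases`.
#' @export
sweep_translational <- function(cues = cue_kinds,
                                x = c(-5, -2.5, 0, 2.5, 5) * 1e-3,
                                y = c(-5, -2.5, 0, 2.5, 5) * 1e-3,
                                v_deg = c(-15, -10, -5, 0, 5, 10, 15),
                                dv_deg = c(-5, -3, -1, 1, 3, 5),
                                d0 = c(5, 10, 15, 20, 25, 30),
                                depth_frac = c(0.5, 0.75, 0.875),
                                v_z = 2, dv_z = 1,
                                camera = pinhole_camera(focal_length = 0.0174),
                                beta_deg = 0,
                                threshold = 0.3,
                                keep_cases = FALSE) {
  cues <- match.arg(cues, cue_kinds, several.ok = TRUE)
  f <- camera$f
  g <- tidyr::expand_grid(
    x = x, y = y, vx_deg = v_deg, vy_deg = v_deg,
    dvx_deg = dv_deg, dvy_deg = dv_deg, d0 = d0, depth_frac = depth_frac
  )
  beta <- deg2rad(beta_deg)
  cb <- cos(beta)
  sb <- sin(beta)
  vx <- angular_velocity_to_metric(g$vx_deg, v_z)
  vy <- angular_velocity_to_metric(g$vy_deg, v_z)
  dvx <- angular_velocity_to_metric(g$dvx_deg, v_z)
  dvy <- angular_velocity_to_metric(g$dvy_deg, v_z)
  dI <- g$d0 - g$depth_frac * g$d0
  aB_n <- (-f * vx + g$x * v_z) * cb + (-f * vy + g$y * v_z) * sb
  aI_s <- aB_n # static object: same motion as background
  aI_d <- (-f * (vx + dvx) + g$x * (v_z + dv_z)) * cb +
    (-f * (vy + dvy) + g$y * (v_z + dv_z)) * sb
  vals <- list()
  for (cue in cues) {
    sd <- switch(cue,
      accretion_deletion = list(
        s = aB_n / g$d0 - aI_s / dI,
        d = aB_n / g$d0 - aI_d / dI
      ),
      expansion_contraction = list(
        s = 2 * v_z / dI - 2 * v_z / g$d0,
        d = 2 * (v_z + dv_z) / dI - 2 * v_z / g$d0
      ),
      acceleration = list(
        s = v_z * aI_s / dI^2 - v_z * aB_n / g$d0^2,
        d = (v_z + dv_z) * aI_d / dI^2 - v_z * aB_n / g$d0^2
      ),
      spatial_curvature = ,
      temporal_curvature = list(
        s = rep(0, nrow(g)), d = rep(0, nrow(g))
      )
    )
    vals[[cue]] <- sd
  }
  finish_sweep(g, vals, threshold, keep_cases)
}

#' @rdname sweep_translational
#' @param dr Object radius-delta grid (m).
#' @param dw Object yaw-delta grid (rad/s); `domega_literal = TRUE` replaces
#'   the 0.1 entry by the literal value 1.
#' @param v Background speed grid (m/s).
#' @param r Background radius grid (m).
#' @param d_I Object-plane distance (m).
#' @param height Camera height over ground (m, signed).
#' @param domega_literal Use the literal value 1 instead of 0.1 in `dw`.
#' @export
sweep_curvilinear <- function(cues = cue_kinds,
                              x = c(-5, -2.5, 0, 2.5, 5) * 1e-3,
                              y = c(-5, -2.5, 0, 2.5, 5) * 1e-3,
                              dr = c(-10, -8, -5, -1, 1, 5, 8, 10),
                              dw = c(-0.2, -0.15, -0.1, -0.05,
                                     0.05, 0.1, 0.15, 0.2),
                              v = c(-15, -14, -13, -12, -10,
                                    10, 12, 13, 14, 15),
                              r = c(80, 120, 160, 320),
                              d_I = 5, height = -1.65,
                              camera = pinhole_camera(focal_length = 0.0174),
                              beta_deg = 0,
                              threshold = 0.3,
                              domega_literal = FALSE,
                              keep_cases = FALSE) {
  cues <- match.arg(cues, cue_kinds, several.ok = TRUE)
  if (domega_literal) dw[dw == 0.1] <- 1
  f <- camera$f
  g <- tidyr::expand_grid(x = x, y = y, dr = dr, dw = dw, v = v, r = r)
  beta <- deg2rad(beta_deg)
  w <- g$v / g$r
  wI <- w + g$dw
  rI <- g$r + g$dr
  vals <- list()
  for (cue in cues) {
    tb <- scenario_cue("curvilinear_ground", cue, g$x, g$y, beta, f,
                       list(height = height, omega = w, radius = g$r))
    ts <- scenario_cue("curvilinear_fronto", cue, g$x, g$y, beta, f,
                       list(d0 = d_I, omega = w, radius = g$r))
    td <- scenario_cue("curvilinear_fronto", cue, g$x, g$y, beta, f,
                       list(d0 = d_I, omega = wI, radius = rI))
    vals[[cue]] <- list(s = pair_cue(cue, tb, ts), d = pair_cue(cue, tb, td))
  }
  finish_sweep(g, vals, threshold, keep_cases)
}

finish_sweep <- function(grid, vals, threshold, keep_cases) {
  rows <- vector("list", length(vals))
  for (i in seq_along(vals)) {
    cue <- names(vals)[i]
    s <- vals[[cue]]$s
    d <- vals[[cue]]$d
    undef <- !is.finite(s) | !is.finite(d)
    degen <- !undef & s == 0 & d == s
    eval_ok <- !undef & !degen
    hit <- eval_ok & abs(d - s) > threshold * abs(s)
    rows[[i]] <- tibble(
      cue = cue,
      percent = 100 * sum(hit) / sum(eval_ok),
      n_hit = sum(hit),
      n_eval = sum(eval_ok),
      n_degenerate = sum(degen),
      n_undefined = sum(undef),
      n_total = length(s)
    )
    if (keep_cases) {
      grid[[paste0(cue, "_static")]] <- s
      grid[[paste0(cue, "_dynamic")]] <- d
      grid[[paste0(cue, "_hit")]] <- hit
    }
  }
  out <- list(summary = dplyr::bind_rows(rows), threshold = threshold)
  if (keep_cases) out$cases <- grid
  structure(out, class = "cue_sweep")
}

#' @export
print.cue_sweep <- function(x, ...) {
  cat(sprintf("<cue_sweep> threshold = %g\n", x$threshold))
  print(x$summary)
  invisible(x)
}
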