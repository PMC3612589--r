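#' Pointwise segmentation-cue operators
#'
#' Five local cues measure how the flow of an object layer differs from the
#' background layer at a shared image point; all are vectorised.
#'
#' * `accretion_deletion()`: `Delta = (flow_B - flow_I) . n_beta`, the flow
#'   difference along the outward edge normal `n_beta = (cos b, sin b)`.
#'   Positive values mean background texture is uncovered (accretion) at that
#'   edge, negative values covered (deletion). Unit m/s.
#' * `expansion_contraction()`: `delta = trace(J_I) - trace(J_B)`, the
#'   divergence difference; positive for a relative source (expansion).
#'   Unit 1/s.
#' * `acceleration_cue()`: `alpha = (accel_I - accel_B) . n_beta` where
#'   `accel` is the Eulerian temporal derivative of the flow at a fixed
#'   image location. Unit m/s^2.
#' * `spatial_curvature()`: per layer, the curvature of the local integral
#'   curve of the flow field, `det(fl, J fl) / |fl|^3` (second-order Taylor
#'   approximation of the streamline); the cue is the layer difference
#'   `theta_I - theta_B`. Unit 1/m. Undefined (NaN) at zero-speed samples.
#' * `temporal_curvature()`: per layer, `(u a_v - v a_u) / |fl|^3` with
#'   `(a_u, a_v)` the flow's temporal derivative: the curvature of the path
#'   traced by the flow vector at one fixed location. Unit 1/m. Undefined at
#'   zero-speed samples.
#'
#' @param u_b,v_b,u_i,v_i Flow components of background/IMO layers (m/s).
#' @param beta Edge-normal direction in radians (0 = right vertical edge).
#' @param trace_b,trace_i Jacobian traces of the two layers (1/s).
#' @param au_b,av_b,au_i,av_i Temporal flow derivatives (m/s^2).
#' @param u,v Single-layer flow components.
#' @param jxx,jxy,jyx,jyy Single-layer Jacobian entries.
#' @param au,av Single-layer temporal flow derivatives.
#' @return Numeric vector of cue values (for the curvature helpers, per-layer
#'   values to be differenced as `I - B`).
#' @export
accretion_deletion <- function(u_b, v_b, u_i, v_i, beta) {
  (u_b - u_i) * cos(beta) + (v_b - v_i) * sin(beta)
}

#' @rdname accretion_deletion
#' @export
expansion_contraction <- function(trace_b, trace_i) {
  trace_i - trace_b
}

#' @rdname accretion_deletion
#' @export
acceleration_cue <- function(au_b, av_b, au_i, av_i, beta) {
  (au_i - au_b) * cos(beta) + (av_i - av_b) * sin(beta)
}

#' @rdname accretion_deletion
#' @export
spatial_curvature <- function(u, v, jxx, jxy, jyx, jyy) {
  speed2 <- u^2 + v^2
  lam2x <- jxx * u + jxy * v
  lam2y <- jyx * u + jyy * v
  out <- (u * lam2y - v * lam2x) / speed2^1.5
  out[speed2 == 0] <- NaN
  out
}

#' @rdname accretion_deletion
#' @export
temporal_curvature <- function(u, v, au, av) {
  speed2 <- u^2 + v^2
  out <- (u * av - v * au) / speed2^1.5
  out[speed2 == 0] <- NaN
  out
}

cue_kinds <- c("accretion_deletion", "expansion_contraction",
               "acceleration", "spatial_curvature", "temporal_curvature")

## Evaluate all five cues between two analytic layers at (x, y, t, beta).
## Returns a list of numeric vectors keyed by cue kind.
layer_cues <- function(background, imo_layer, f, x, y, t = 0, beta = 0) {
  B <- flow_uv(background, f, x, y, t)
  I <- flow_uv(imo_layer, f, x, y, t)
  JB <- jacobian_uv(background, f, x, y, t)
  JI <- jacobian_uv(imo_layer, f, x, y, t)
  AB <- dflow_uv(background, f, x, y, t, order = 1)
  AI <- dflow_uv(imo_layer, f, x, y, t, order = 1)
  list(
    accretion_deletion = accretion_deletion(B$u, B$v, I$u, I$v, beta),
    expansion_contraction = expansion_contraction(JB$jxx + JB$jyy,
                                                  JI$jxx + JI$jyy),
    acceleration = acceleration_cue(AB$u, AB$v, AI$u, AI$v, beta),
    spatial_curvature =
      spatial_curvature(I$u, I$v, JI$jxx, JI$jxy, JI$jyx, JI$jyy) -
      spatial_curvature(B$u, B$v, JB$jxx, JB$jxy, JB$jyx, JB$jyy),
    temporal_curvature =
      temporal_curvature(I$u, I$v, AI$u, AI$v) -
      temporal_curvature(B$u, B$v, AB$u, AB$v)
  )
}

#' Segmentation cues between the layers of a scene
#'
#' Evaluates all five cues (IMO layer against background) of a
#' [layered_scene()] at given image points, as if the object/background edge
#' passed through each point with outward-normal direction `beta`.
#'
#' @param scene A [layered_scene()] with an IMO.
#' @param x,y Image coordinates (m).
#' @param t Time (s).
#' @param beta_deg Edge-normal direction in degrees (0 = right edge normal).
#' @return A tibble with `x`, `y` and one column per cue.
#' @export
cue_field <- function(scene, x, y, t = 0, beta_deg = 0) {
  if (is.null(scene$imo_layer)) abort("scene has no IMO layer")
  cues <- layer_cues(scene$background, scene$imo_layer, scene$camera$f,
                     x, y, t, beta = deg2rad(beta_deg))
  dplyr::bind_cols(tibble(x = x, y = y), as_tibble(cues))
}
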