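#' Contour-integrated segmentation-cue strengths
#'
#' A cue evaluated along the four edges of the IMO's rectangular contour,
#' with the edge normal pointing outward (`beta` = 0, 90, 180, 270 degrees
#' for the right, top, left and bottom edge). Each edge contributes the
#' absolute value of its line integral, so that accretion on one edge and
#' deletion on the opposite edge cannot cancel to a zero net cue; the total
#' strength is therefore nonnegative and invariant under the traversal
#' direction of the contour.
#'
#' Integration uses Gauss-Legendre quadrature per edge. All scenario cue
#' terms entering the combined cue are polynomial or rational-polynomial
#' along an edge; `n_nodes = 16` integrates polynomials up to degree 31
#' exactly, which makes the strengths bit-stable.
#'
#' @param cue_fun Vectorised function `(x, y, beta) -> cue value` giving the
#'   layer-difference cue at image point `(x, y)` for an edge with outward
#'   normal `beta` (radians).
#' @param region An [imo_region()].
#' @param n_nodes Gauss-Legendre nodes per edge.
#' @return Nonnegative scalar strength (cue unit times metres).
#' @export
contour_cue_strength <- function(cue_fun, region, n_nodes = 16) {
  xl <- region$x - region$width / 2
  xr <- region$x + region$width / 2
  yb <- region$y - region$height / 2
  yt <- region$y + region$height / 2
  gy <- pracma::gaussLegendre(n_nodes, yb, yt)
  gx <- pracma::gaussLegendre(n_nodes, xl, xr)
  e_right <- sum(gy$w * cue_fun(rep(xr, n_nodes), gy$x, 0))
  e_top <- sum(gx$w * cue_fun(gx$x, rep(yt, n_nodes), pi / 2))
  e_left <- sum(gy$w * cue_fun(rep(xl, n_nodes), gy$x, pi))
  e_bottom <- sum(gx$w * cue_fun(gx$x, rep(yb, n_nodes), 3 * pi / 2))
  abs(e_right) + abs(e_top) + abs(e_left) + abs(e_bottom)
}

#' Cue strengths along a scene's IMO contour
#'
#' Computes the contour-integrated strengths of the accretion/deletion,
#' expansion/contraction and acceleration/deceleration cues between the two
#' layers of a scene (optionally also the two curvature cues, which are
#' reported but never enter the combined signal).
#'
#' @param scene A [layered_scene()] with an IMO.
#' @param t Time (s).
#' @param cues Cue kinds to integrate.
#' @param n_nodes Gauss-Legendre nodes per edge.
#' @return A one-row tibble with one column per requested cue strength.
#' @export
cue_strengths <- function(scene,
                          t = 0,
                          cues = c("accretion_deletion",
                                   "expansion_contraction", "acceleration"),
                          n_nodes = 16) {
  if (is.null(scene$imo)) abort("scene has no IMO")
  cues <- match.arg(cues, cue_kinds, several.ok = TRUE)
  f <- scene$camera$f
  out <- lapply(cues, function(cue) {
    fun <- function(x, y, beta) {
      layer_cues(scene$background, scene$imo_layer, f, x, y, t,
                 beta = beta)[[cue]]
    }
    contour_cue_strength(fun, scene$imo, n_nodes = n_nodes)
  })
  names(out) <- cues
  as_tibble(out)
}

#' Combined segmentation signal
#'
#' Linear superposition of the three contour strengths, clipped to `[0, 1]`:
#' `s = clip(c_acc * s_acc + c_exp * s_exp + c_accel * s_accel, 0, 1)`.
#' The coefficients are study-specific constants (the curvature strengths
#' never enter; closed-form line integrals for them are not available).
#' `s = 1` means full segmentation: the IMO region is discounted entirely
#' by the estimators, which removes its bias.
#'
#' @param strengths One-row tibble (or named list) with
#'   `accretion_deletion`, `expansion_contraction`, `acceleration`.
#' @param coefficients Length-3 numeric `c(c_accretion, c_expansion,
#'   c_acceleration)`.
#' @return Scalar `s` in `[0, 1]`.
#' @export
combined_segmentation <- function(strengths, coefficients) {
  stopifnot(length(coefficients) == 3)
  raw <- coefficients[1] * strengths$accretion_deletion +
    coefficients[2] * strengths$expansion_contraction +
    coefficients[3] * strengths$acceleration
  pmin(pmax(raw, 0), 1)
}
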