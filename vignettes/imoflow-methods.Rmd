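---
title: "Analytic optic flow, segmentation cues, and self-motion estimation with moving objects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic optic flow, segmentation cues, and self-motion estimation with moving objects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imoflow)
```

## The problem

An observer moving through a rigid world registers an optic-flow field that
is fully determined by the observer's linear velocity $v$, rotational
velocity $\omega$, and the depth map $Z(x, y, t)$. Humans estimate heading
(for straight travel) or future path (for travel on a circular arc) from
this flow with striking robustness, even when an independently moving
object (IMO) occupies part of the visual field and contributes flow that no
single rigid-motion model can explain. `imoflow` implements an analytic
account of that robustness: a linear least-squares estimator of heading or
path radius that integrates flow over the image, plus five local
segmentation cues whose contour-integrated strengths down-weight the IMO
region before integration.

Everything in the package is closed-form and deterministic. A separate
oracle layer (rasterised fields, finite differences, composite quadrature)
re-derives every closed form numerically, so each analytic expression is
covered by an independent computational route.

## Flow model

The instantaneous image velocity of a projected 3D point at image position
$p = (x, y, f)$ and depth $Z$ is

$$\begin{pmatrix}\dot x\\ \dot y\end{pmatrix}
 = \frac{1}{Z}\begin{pmatrix}-f & 0 & x\\ 0 & -f & y\end{pmatrix} v
 + \frac{1}{f}\begin{pmatrix}xy & -(f^2+x^2) & fy\\ f^2+y^2 & -xy & -fx\end{pmatrix}\omega ,$$

with the frame convention x positive leftward, y upward, z along the
optical axis (right handed). Linear and rotational contributions
superimpose; only the linear part carries depth; for pure translation the
flow vanishes at the focus of expansion (FOE)
$(\eta, \zeta) = (v_x/v_z,\; v_y/v_z)$ scaled by $f$ on the image plane.

Three scene/motion instances specialise this equation, each implemented as
a *flow layer* with analytic flow, spatial Jacobian, and Eulerian temporal
derivatives:

* **translation toward a plane** in Hessian normal form, depth
  $Z = f\,(d_0 - t\,v^\top n)/(p^\top n)$;
* **curvilinear motion toward an initially fronto-parallel plane**: travel
  on a circle of radius $r$ at yaw rate $\omega$, tangential speed
  $\omega r$, with the plane's normal co-rotating in view;
* **curvilinear motion over a ground plane** at camera height $h$ (negative
  when the ground lies below), which yields the time-invariant field
  $\dot p = \tfrac{y}{f}\tfrac{r}{h}\omega\,(x, y)^\top - \tfrac{\omega}{f}(f^2+x^2,\; xy)^\top.$

A `layered_scene()` composes a background layer with one IMO: a rectangular
image region $A_I$ (closed, so boundary samples belong to the object)
inside which a second layer's flow replaces the background's. One IMO
suffices for every configuration studied here; the data model would extend
to several regions but deliberately does not, to keep the closed-form
integrals transparent.

Angles are accepted in degrees only at the configuration boundary
(`*_deg` arguments and config-file keys) and converted once — positions via
$f\tan(\cdot)$, lengths via $2f\tan(\cdot/2)$, velocities via
$v_z\tan(\cdot)$; all internal mathematics is in radians and metres.

## Heading and radius estimators

For translational scenes the least-squares functional
$F(\eta,\zeta)=\iint \lVert(\dot x,\dot y) - \gamma(-f\eta + x,\; -f\zeta + y)\rVert^2\,dx\,dy$
has the closed-form minimiser
$\hat\eta = \iint (x - \dot x/\gamma)\,dx\,dy \,/\, (f \iint dx\,dy)$,
where $\gamma = 1/(t_c - t)$ is the background's inverse time-to-contact.
$\gamma$ is supplied from the background's ground truth (in a biological
setting it would come from, e.g., binocular disparity); the package builds
no disparity machinery. With an IMO, the integral splits into background
and object regions and the object region is weighted by $(1-s)$, where
$s \in [0,1]$ is the segmentation signal. All integrands are polynomial, so
`estimate_foe()` evaluates the rectangle integrals exactly;
`estimate_foe_field()` is the rasterised counterpart (cell-centred sums,
whole-cell region weighting, no partial-cell antialiasing — resolution is
under the caller's control and the error decays at second order for
cell-aligned regions).

The exact bias of the unsegmented estimator, obtained by evaluating the
split integrals, is

$$\Delta\eta \;=\; \frac{(1-s)\,w_I h_I}{w_B h_B - s\,w_I h_I}
 \left(-\eta_B + \frac{x_I}{f}\Bigl(1 - \frac{\mu_I v_{z,I}}{\mu_B v_{z,B}}\Bigr)
 + \frac{\mu_I v_{x,I}}{\mu_B v_{z,B}}\right),
 \qquad \mu = \frac{1}{d_0 - t\,v_z}.$$

It vanishes at $s = 1$, is proportional to the object's area at $s = 0$,
and is independent of the object's vertical position and of all vertical
velocity components. Note the denominator: the full-image area is reduced
by $s\,w_I h_I$ because the discounted object area also leaves the
normalising integral. `heading_bias()` implements this expression;
agreement with the split-integral estimator to $10^{-8}$ relative error on
random draws is part of the acceptance suite, and the rasterised route
provides the code-independent cross-check.

For curvilinear motion over a ground plane, eliminating the yaw rate from
the flow model leaves a constraint that is linear in the radius:
$\hat r = h\,(\dot x\,xy - (f^2+x^2)\dot y)\,/\,(\dot x\,y^2 - xy\,\dot y)$
pointwise (`estimate_radius_local()`; degenerate on the horizon), and in
integrated form $\hat r = h\,I_3/I_4$ with numerator and denominator
integrated separately and the IMO region weighted by $(1-s)$
(`estimate_radius()`). On rigid ground flow both integrands share the
factor $r$, so the ratio $\rho_r = \hat r / r_B$ is exactly one. With a
fronto-parallel IMO orbiting at its own $(\omega_I, r_I)$, the exact ratio
is

$$\rho_r = \frac{(\omega_B/\omega_I)\,r_B\,Q + (1-s)\,f h\,(r_I/d_I)\,w_I h_I y_I}
 {r_B\left[(\omega_B/\omega_I)\,Q + (1-s)\,S_I\right]},$$

with $S_I = w_I h_I (y_I^2 + h_I^2/12)$ and $Q = w_B h_B^3/12 - S_I$ the
$y^2$ moments of the two regions (`radius_ratio()`). It is one at $s = 1$
or zero object area and independent of the object's horizontal position.
The predicted future path in the image follows from the estimated radius
alone: $x(t) = f(1/\sin\omega t - \tan\omega t)$,
$y(t) = -f\,(h/r)/\lvert\sin\omega t\rvert$ for
$\omega t \in (0, \pi/2)$.

## Segmentation cues

Five local cues compare the object layer against the background at a shared
image point, with $n_\beta = (\cos\beta, \sin\beta)$ the outward edge
normal:

| cue | definition | unit |
|---|---|---|
| accretion/deletion | $\Delta = (\dot p_B - \dot p_I)^\top n_\beta$ | m/s |
| expansion/contraction | $\delta = \mathrm{tr}\,J_I - \mathrm{tr}\,J_B$ | 1/s |
| acceleration/deceleration | $\alpha = (\ddot p_I - \ddot p_B)^\top n_\beta$ | m/s² |
| local spatial curvature | $\vartheta_{I} - \vartheta_B$, $\vartheta = \det(\dot\lambda, J\dot\lambda)/\lVert\dot\lambda\rVert^3$ | 1/m |
| local temporal curvature | $\gamma_I - \gamma_B$, $\gamma = (\dot x\,\ddot y - \dot y\,\ddot x)/\lVert(\dot x,\dot y)\rVert^3$ | 1/m |

Temporal derivatives are Eulerian: the image location is held fixed while
$t$ varies, matching the analytic layers' $\partial_t$ of the flow (no
feature tracking anywhere). Zero-speed curvature samples are undefined and
returned as `NaN`, never silently as zero; sweeps count and exclude them.
The cue operators exist in two independent forms — the generic route
(`cue_field()`, assembling flow, Jacobian, and temporal derivatives of any
layer pair) and per-scenario closed forms (`scenario_cue()`, simplified by
hand) — which the test suite holds together to $10^{-9}$.

Two structural zeroes follow immediately and are asserted over random
parameters: translational motion toward *any* plane has straight
streamlines and a time-fixed flow direction, so both curvature cues vanish
identically; the ground-plane field is time-invariant, so its acceleration
and temporal-curvature terms vanish.

Along the IMO's rectangular contour, each cue is line-integrated edge by
edge ($\beta = 0°, 90°, 180°, 270°$) and the **absolute values** of the
four edge integrals are summed (`contour_cue_strength()`); otherwise
accretion on one edge and deletion on the opposite edge would cancel to a
useless zero net signal. The integrands of the three non-curvature cues are
polynomial along an edge, so a single 16-node Gauss–Legendre rule per edge
is exact (it integrates polynomials to degree 31) and the strengths are
bit-stable; a composite rule (`numeric_contour_strength()`) serves as the
independent check. The combined signal is the clipped linear combination

$$s = \mathrm{clip}\bigl(c_\Delta s_\Delta + c_\delta s_\delta + c_\alpha s_\alpha,\; 0,\; 1\bigr),$$

with study-specific constant coefficients (they are treated as fixed
constants here, not fitted). The curvature strengths are computed on
request and reported, but never enter $s$: their contour integrals have no
tractable antiderivative, and their static-versus-dynamic contrast is weak
(below). The same symbol $\gamma$ is conventional both for the inverse
time-to-contact and for temporal curvature; the package names them
`inverse_ttc` and `temporal_curvature` to keep them apart.

## Static-versus-dynamic sweeps

A *static discontinuity* is a pure depth step: an object plane nearer than
the background that moves consistently with it. A *dynamic discontinuity*
(an IMO) moves with its own parameters. For a cue to be useful the two must
be distinguishable, so the sweeps (`sweep_translational()`,
`sweep_curvilinear()`) evaluate each cue over a full parameter grid and
count a case when
$\lvert \text{cue}_{\text{static}} - \text{cue}_{\text{dynamic}}\rvert >
0.3\,\lvert\text{cue}_{\text{static}}\rvert$, a strict inequality. The 30%
threshold is the conventional contrast criterion for this comparison and is
exposed as a parameter. When the static cue is exactly zero the criterion
degenerates gracefully ($0.3 \cdot 0 = 0$): any nonzero dynamic difference
counts. A case with zero static cue *and* zero difference carries no
information at all (for example the $x = 0$ grid column of cues carrying an
$x\cos\beta$ factor); such cases, and undefined curvature samples, are
flagged, counted, and excluded from the percentage's denominator.

Default grids for the translational sweep: image positions
$x, y \in \{-5, -2.5, 0, 2.5, 5\}$ mm on the 32°/1 cm display, background
direction angles $\pm\{0,5,10,15\}°$, object direction deltas
$\pm\{1,3,5\}°$, $d_0 \in \{5,\dots,30\}$ m, depth-step fractions
$\{0.5, 0.75, 0.875\}$, $v_{z,B} = 2$ m/s and $\Delta v_z = 1$ m/s, edge
normal $\beta = 0°$. Degree-valued velocities convert via
$v_{z,B}\tan(\cdot)$. The curvilinear sweep uses $\Delta r$ up to
$\pm 10$ m, $\Delta\omega$ up to $\pm 0.2$ rad/s, speeds
$\pm\{10,\dots,15\}$ m/s and radii $\{80,120,160,320\}$ m over the same
position grid; the symmetric $\Delta\omega$ grid is the default and a
literal asymmetric variant (one entry at $1$ rad/s) is selectable via
`domega_literal`. Because the position sampling of the curvilinear sweeps
is a modelling choice, the resulting percentages can shift by a few points
under other defensible samplings; the defaults reuse the translational
grid.

Two structural observations explain the curvature results and motivated
excluding those cues from $s$. The spatial-curvature contrast is bounded by
twice the object layer's curvature, yet the reference magnitude is
dominated by the ground plane's own streamline curvature (two orders of
magnitude larger at these grid points), so the 30% criterion essentially
never fires. The temporal-curvature contrast, in turn, fires almost exactly
when the object's yaw rate changes sign relative to the background's
(curvature is odd in the yaw sign), so its hit rate tracks the sign-flip
fraction of the $(\Delta\omega, v/r)$ grid (about a third) rather than any
graded motion difference.

## Replicated study configurations

Three classic psychophysics configurations are frozen as `study_config`
objects. Values not fixed by the published designs were chosen once, as
follows, and are recorded here rather than revisited.

**Linear motion, two fronto-parallel planes** (`config_warren_saunders()`;
cf. Warren & Saunders, *heading in the presence of moving objects*):
background and object both start at 10 m, approached at 2 and 3 m/s; the
flow snapshot is the instantaneous field at the end of the 1.5 s
presentation (no temporal integration anywhere in the model), when the
looming object subtends 16°×16°. Heading probes at 4–10° with offsets
0.5–4° give the 16 probe/heading combinations; the design is evaluated on
the positive-probe side with positive (peripheral) offsets, which the
model's left/right antisymmetry makes fully general and which keeps the two
visibility groups clean: with the object on the opposite side of the probe
the FOE is always visible, with it on the probe's side (centred at 6°, 16°
wide) the FOE is always covered. The object's image position is set to
±6° at the snapshot. The "blanked object" control of the original study
corresponds to forcing $s = 1$: an untextured region carries no measurable
flow, so full discounting is the model's representation of it.

**Linear motion, sideways-moving object** (`config_royden_hildreth()`):
background at 10 m approaching at 2 m/s; the object rides with the observer
at a constant 5 m and translates sideways at 0.71 m/s (8.1°/s at 25 Hz
against 5 m). Its approach speed is zero, so its layer is time-invariant —
its acceleration cue contribution is pure background. In the non-crossing
condition the object starts at 0.6° and moves outward (away from the
observer's path); in the crossing condition it starts at 10.7° and moves
toward and across it. The crossing start places about 0.7° of the object
beyond the 30° display edge; the integrals deliberately keep the full
object rectangle, since the closed forms assume it, rather than clipping to
the display. Per-subject idiosyncrasies in bias direction reported for this
design are not modelled; the package reports the model curve only.

**Curvilinear path over a ground plane** (`config_fajen_kim()`): speed
13.2 m/s, radii 80–320 m (yaw $v/r$ ≈ 9.5–2.4°/s), eye height −1.65 m,
gaze parallel to the ground and tangent to the path. The object is a
fronto-parallel plane at 5 m subtending 5°×5°, centred 5° below the
horizon, orbiting 2.86°/s slower than the background. Its horizontal centre
is not fixed by the original design; the default is 0°, immaterial for the
radius ratio (which is $x_I$-independent) and noted in reports. Paths A and
B keep $r_I = r_B$ from the right/left side respectively and are identical
under the model; path C uses $r_I = r_B - 7.2$ m and path D
$r_I = r_B + 7.2$ m.

`run_heading_experiment()` and `run_path_experiment()` evaluate every
condition, optionally deriving $s$ from the contour strengths with the
study's coefficient triple, and report tidy per-condition tables. The
models are deterministic; reported standard deviations span the condition
set of a group, not injected noise. Heading errors are reported both as the
dimensionless $\Delta\eta$ and in degrees as
$\arctan\hat\eta - \arctan\eta_B$, since both conventions are common.

## Oracle layer and fixtures

`flow_stack()` renders a scene at $t \pm \Delta t$ (default one frame at
25 Hz) so that `fd_time()` can form central first and three-point second
temporal differences at fixed image locations; `fd_jacobian()` applies the
analogous spatial stencil. Because every flow model here is at most
quadratic in the image coordinates, the spatial stencil is *exact* up to
rounding — it meets the second-order bound trivially — whereas the flows
are genuinely non-polynomial in time, and the temporal stencil's error is
verified empirically to decay at order two (log–log slope $2 \pm 0.2$).

`generate_fixture()` packages named validation scenarios (rigid
translational background, translational background plus IMO, rigid ground
plane) as flow stacks with ground-truth metadata, optionally perturbed by
isotropic additive Gaussian noise on the flow vectors. The noise is a
robustness probe for the estimators — the analytic models themselves are
noise-free and all acceptance computations run without it. Fixtures are
deterministic given a seed. What the fixtures do *not* emulate about real
data: flow-detector error structure (which is spatially correlated and
outlier-prone, not isotropic Gaussian), occlusion dynamics at the object
boundary, texture and aperture effects, multiple objects, and any temporal
integration over a stimulus; passing tests therefore validate the
mathematics of the estimators and cues, not their behaviour on detected
flow from video.

## Numerical choices and problem sizes

* Rectangle integrals of polynomial integrands are evaluated in closed form
  (midpoint value × area for linear integrands, explicit $y^2$ moments for
  the radius integrals); nothing iterative is involved, so results are
  bit-reproducible.
* Contour quadrature: 16-node Gauss–Legendre per edge, exact for the
  polynomial cue integrands; composite 16×4-node rule as the oracle.
* Rasterised integration: cell-centred sums with whole-cell $(1-s)$
  weighting; second-order convergence verified on cell-aligned regions at
  $n_x \in \{16, 32, 64, 128\}$.
* Degenerate flow samples (ray parallel to a plane, surfaces behind the
  camera) are flagged per sample and excluded from raster integrals with a
  logged count, so whole-field renders and sweeps survive isolated
  degenerate grid points; scalar evaluation of `plane_depth()` errors
  instead.
* Randomised identity and duality checks use 10,000 closed-form draws and
  500–2,000 split-integral draws per identity; sweep acceptance runs the
  full printed grids (793,800 translational and 64,000 curvilinear cases
  per cue). The complete suite runs in well under a minute on one core.

## Known limitations

* Rotational self-motion is not estimated; the curvilinear estimators
  assume gaze tangent to the path (zero-elevation gaze), and eye-movement
  compensation is out of scope.
* The heading estimator requires fronto-parallel translational layers (the
  configurations above); the radius estimator requires a ground-plane
  background. General plane orientations are supported by the flow layers
  and oracle but not by the closed-form estimators.
* $s$ is a single scalar per scene: segmentation is all-or-nothing over the
  object rectangle, with no spatial profile.
* The cue coefficients $c_\Delta, c_\delta, c_\alpha$ are constants taken
  per study; no fitting machinery is provided, and with these constants the
  combined signal can saturate at 0 or 1 for conditions outside each
  study's regime.
* Single IMO per scene; no photometric rendering, no lens distortion, no
  discrete-frame temporal sampling beyond the one velocity-conversion rule.
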