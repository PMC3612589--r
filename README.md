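# imoflow

Analytic optic flow, flow-based segmentation cues, and least-squares
estimation of heading and path radius in the presence of independently
moving objects (IMOs).

Self-motion through a rigid scene induces an optic-flow field
$$(\dot x, \dot y)^\top = \tfrac{1}{Z}\begin{pmatrix}-f&0&x\\0&-f&y\end{pmatrix}v
 \;+\; \tfrac{1}{f}\begin{pmatrix}xy&-(f^2+x^2)&fy\\f^2+y^2&-xy&-fx\end{pmatrix}\omega$$
from which heading — the focus of expansion $(\eta,\zeta)=(v_x/v_z, v_y/v_z)$
— or the radius $r$ of a curvilinear path can be recovered by linear least
squares. An IMO injects flow that violates the rigid-motion model and
biases those estimates. This package implements, in closed form:

* **flow generators** for three scene/motion models (translation toward a
  plane; curvilinear motion toward a fronto-parallel plane; curvilinear
  motion over a ground plane), composable into two-layer background + IMO
  scenes, with rasterisation and a Middlebury `.flo` codec;
* **five segmentation cues** between the layers — accretion/deletion
  $\Delta=(\dot p_B-\dot p_I)^\top n_\beta$, expansion/contraction
  $\delta=\mathrm{tr}J_I-\mathrm{tr}J_B$, acceleration/deceleration
  $\alpha=(\ddot p_I-\ddot p_B)^\top n_\beta$, and local spatial/temporal
  flow curvatures — plus contour-integrated strengths and the combined,
  clipped signal $s = \mathrm{clip}(c_\Delta s_\Delta + c_\delta s_\delta +
  c_\alpha s_\alpha, 0, 1)$;
* **estimators** of the FOE and of the path radius with the IMO region
  weighted by $(1-s)$, their exact closed-form bias terms
  ($\Delta\eta$ and the radius ratio $\rho_r=\hat r/r_B$), and the
  predicted image-plane path;
* **replications** of three classic heading/path psychophysics
  configurations (two-plane heading displays, a sideways-moving object at
  fixed depth, and curvilinear travel over a ground plane with an orbiting
  object), and **static-versus-dynamic sweeps** that quantify how often
  each cue distinguishes a moving object from a mere depth step;
* an **oracle layer** (finite differences, composite quadrature, fixture
  generation) giving every closed form an independent numerical
  cross-check.

It is aimed at researchers in visual motion perception and computational
modelling who want transparent, fully analytic baselines rather than a
flow-detection pipeline.

## Worked example

One condition of the sideways-moving-object configuration: the background
plane at 10 m is approached at 2 m/s with heading 6° to the side; the
object rides along at a constant 5 m, 10°×10°, starting near the observer's
path and translating outward at 0.71 m/s.

```r
library(imoflow)

cam <- pinhole_camera(focal_length = 0.0187, width = 0.01)  # 30 deg display
scene <- layered_scene(
  cam,
  background = translational_layer(10, c(angular_velocity_to_metric(6, 2), 0, 2)),
  imo        = imo_region_deg(0.6, 0, 10, 10, cam),
  imo_layer  = translational_layer(5, c(-0.71, 0, 0))
)

glance(estimate_foe(scene))           # unsegmented estimate
#>   eta_hat zeta_hat    bias bias_deg     s gamma method
#> 1  0.0190        0 -0.0861    -4.91     0   0.2 analytic
```

Integrating the object's flow as if it were background drags the heading
estimate from the true 6° down to about 1.1° — a 4.9° bias, far larger than
human errors in this display. The contour cue strengths segment the object:

```r
st <- cue_strengths(scene)
st
#>   accretion_deletion expansion_contraction acceleration
#> 1          0.0000218               0.00524  0.000000891
s <- combined_segmentation(st, c(3.5e5, -10.5e2, 3e5))
s
#> [1] 1
glance(estimate_foe(scene, s = s))
#>   eta_hat zeta_hat      bias  bias_deg     s gamma method
#> 1   0.105        0 -1.39e-17 -7.95e-16     1   0.2 analytic
```

With full segmentation ($s = 1$) the object region is discounted and the
bias vanishes to machine precision. `run_heading_experiment()` and
`run_path_experiment()` do this over entire study designs;
`sweep_translational()` / `sweep_curvilinear()` run the cue-contrast
parameter sweeps; `autoplot()` on a rendered field and
`plot_heading_bias()` / `plot_radius_ratio()` on reports draw the standard
figures. A thin command-line dispatcher (`exec/imoflow`) exposes `sweep`,
`estimate`, `replicate`, `cues`, and `fixtures` subcommands over the same
functions.

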