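## Shared generators for randomised property tests. All draws go through
## these helpers so parameter ranges stay physically valid (objects in front
## of the camera, nonzero approach speeds, IMO inside reasonable bounds).

ws_camera <- function() pinhole_camera(focal_length = 0.0174, width = 0.01)

random_translational_pair <- function(n = 1) {
  ## background + IMO fronto-parallel layer parameters, vectorised draws
  tibble::tibble(
    d0_B = runif(n, 4, 30),
    d0_I = runif(n, 2, 25),
    v_x_B = runif(n, -1, 1),
    v_y_B = runif(n, -1, 1),
    v_z_B = runif(n, 0.5, 4),
    v_x_I = runif(n, -1, 1),
    v_y_I = runif(n, -1, 1),
    v_z_I = runif(n, -1, 3),
    x_I = runif(n, -3e-3, 3e-3),
    y_I = runif(n, -3e-3, 3e-3),
    w_I = runif(n, 5e-4, 4e-3),
    h_I = runif(n, 5e-4, 4e-3),
    s = runif(n)
  )
}

translational_scene_from_row <- function(p, camera = ws_camera()) {
  layered_scene(
    camera,
    background = translational_layer(p$d0_B, c(p$v_x_B, p$v_y_B, p$v_z_B)),
    imo = imo_region(p$x_I, p$y_I, p$w_I, p$h_I),
    imo_layer = translational_layer(p$d0_I, c(p$v_x_I, p$v_y_I, p$v_z_I))
  )
}

random_curvilinear_pair <- function(n = 1) {
  tibble::tibble(
    height = -runif(n, 1, 2),
    r_B = runif(n, 60, 350) * sample(c(-1, 1), n, replace = TRUE),
    omega_B = runif(n, 0.02, 0.2) * sample(c(-1, 1), n, replace = TRUE),
    d_I = runif(n, 3, 10),
    r_I = NA_real_,
    omega_I = NA_real_,
    x_I = runif(n, -3e-3, 3e-3),
    y_I = runif(n, -4e-3, -5e-4), # below the horizon
    w_I = runif(n, 5e-4, 4e-3),
    h_I = runif(n, 5e-4, 4e-3),
    s = runif(n)
  ) -> out
  ## object orbits in the background's rotation sense, on a nearby radius
  out$omega_I <- out$omega_B * runif(n, 0.5, 1.5)
  out$r_I <- out$r_B + runif(n, -10, 10)
  out
}

curvilinear_scene_from_row <- function(p, camera = ws_camera()) {
  layered_scene(
    camera,
    background = curvilinear_ground_layer(p$height, p$omega_B, p$r_B),
    imo = imo_region(p$x_I, p$y_I, p$w_I, p$h_I),
    imo_layer = curvilinear_fronto_layer(p$d_I, p$omega_I, p$r_I)
  )
}

## per-layer generic cue evaluation straight from the layer derivatives,
## used as the independent route against the scenario closed forms
generic_layer_cue <- function(layer, cue, x, y, beta, camera, t = 0) {
  f <- camera$f
  fl <- imoflow:::flow_uv(layer, f, x, y, t)
  switch(cue,
    accretion_deletion = fl$u * cos(beta) + fl$v * sin(beta),
    expansion_contraction = {
      J <- imoflow:::jacobian_uv(layer, f, x, y, t)
      J$jxx + J$jyy
    },
    acceleration = {
      A <- imoflow:::dflow_uv(layer, f, x, y, t, order = 1)
      A$u * cos(beta) + A$v * sin(beta)
    },
    spatial_curvature = {
      J <- imoflow:::jacobian_uv(layer, f, x, y, t)
      spatial_curvature(fl$u, fl$v, J$jxx, J$jxy, J$jyx, J$jyy)
    },
    temporal_curvature = {
      A <- imoflow:::dflow_uv(layer, f, x, y, t, order = 1)
      temporal_curvature(fl$u, fl$v, A$u, A$v)
    }
  )
}

grid_points <- function(camera, n = 33) {
  dx <- camera$width / n
  xs <- -camera$width / 2 + (seq_len(n) - 0.5) * dx
  tidyr::expand_grid(x = xs, y = xs)
}
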