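cam <- pinhole_camera(focal_length = 0.0174, width = 0.01)

test_that("FOE estimation is exact on a rigid background", {
  set.seed(23)
  for (k in 1:25) {
    v <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, 0.5, 4))
    scene <- layered_scene(cam, translational_layer(runif(1, 4, 20), v))
    fit <- estimate_foe(scene, t = runif(1, 0, 0.9))
    expect_equal(fit$eta_hat, v[1] / v[3], tolerance = 1e-12)
    expect_equal(fit$zeta_hat, v[2] / v[3], tolerance = 1e-12)
    expect_equal(fit$bias, 0, tolerance = 1e-12)
  }
  # the rasterised route shares the exactness: the integrand x - u/gamma is
  # pointwise constant at f * eta for a matched gamma
  scene <- layered_scene(cam, translational_layer(10, c(0.35, -0.2, 2)))
  ff <- render_flow_field(scene, nx = 17)
  fit <- estimate_foe_field(ff, gamma = 2 / 10, v_background = c(0.35, -0.2, 2))
  expect_equal(fit$eta_hat, 0.175, tolerance = 1e-12)
  expect_equal(fit$zeta_hat, -0.1, tolerance = 1e-12)
})

test_that("full segmentation removes the IMO's influence entirely", {
  set.seed(29)
  draws <- random_translational_pair(400)
  for (k in seq_len(nrow(draws))) {
    p <- draws[k, ]
    scene <- translational_scene_from_row(p)
    fit <- estimate_foe(scene, s = 1)
    expect_equal(fit$bias, 0, tolerance = 1e-12)
    # and the estimate equals the rigid-background estimate
    rigid <- estimate_foe(layered_scene(cam, scene$background))
    expect_equal(fit$eta_hat, rigid$eta_hat, tolerance = 1e-12)
  }
  # closed form, vectorised
  expect_equal(
    heading_bias(1 / draws$d0_B, 1 / draws$d0_I,
                 cbind(draws$v_x_B, draws$v_y_B, draws$v_z_B),
                 cbind(draws$v_x_I, draws$v_y_I, draws$v_z_I),
                 draws$x_I, draws$w_I, draws$h_I,
                 cam$width, cam$height, cam$f, s = 1),
    rep(0, nrow(draws))
  )
})

test_that("closed-form heading bias equals the split-integral estimator", {
  set.seed(31)
  draws <- random_translational_pair(500)
  for (k in seq_len(nrow(draws))) {
    p <- draws[k, ]
    scene <- translational_scene_from_row(p)
    fit <- estimate_foe(scene, s = p$s)
    hb <- heading_bias(1 / p$d0_B, 1 / p$d0_I,
                       c(p$v_x_B, p$v_y_B, p$v_z_B),
                       c(p$v_x_I, p$v_y_I, p$v_z_I),
                       p$x_I, p$w_I, p$h_I, cam$width, cam$height, cam$f,
                       s = p$s)
    expect_equal(fit$bias, hb, tolerance = 1e-8)
  }
})

test_that("heading bias scales with object area and ignores vertical structure", {
  p <- random_translational_pair(1)
  base <- heading_bias(1 / p$d0_B, 1 / p$d0_I,
                       c(p$v_x_B, p$v_y_B, p$v_z_B),
                       c(p$v_x_I, p$v_y_I, p$v_z_I),
                       p$x_I, p$w_I, p$h_I, cam$width, cam$height, cam$f, 0)
  doubled <- heading_bias(1 / p$d0_B, 1 / p$d0_I,
                          c(p$v_x_B, p$v_y_B, p$v_z_B),
                          c(p$v_x_I, p$v_y_I, p$v_z_I),
                          p$x_I, 2 * p$w_I, p$h_I, cam$width, cam$height,
                          cam$f, 0)
  expect_equal(doubled, 2 * base, tolerance = 1e-12)
  # zero-area object: no bias
  expect_equal(
    heading_bias(1 / p$d0_B, 1 / p$d0_I, c(p$v_x_B, p$v_y_B, p$v_z_B),
                 c(p$v_x_I, p$v_y_I, p$v_z_I), p$x_I, 0, p$h_I,
                 cam$width, cam$height, cam$f, 0), 0)

  # independence of y_I, v_y_B and v_y_I (integral route)
  set.seed(37)
  p <- random_translational_pair(1)
  variants <- lapply(c(-2e-3, 0, 2e-3), function(dy) {
    q <- p
    q$y_I <- dy
    q$v_y_B <- runif(1, -2, 2)
    q$v_y_I <- runif(1, -2, 2)
    estimate_foe(translational_scene_from_row(q), s = q$s)$bias
  })
  expect_equal(variants[[1]], variants[[2]], tolerance = 1e-12)
  expect_equal(variants[[2]], variants[[3]], tolerance = 1e-12)
})

test_that("bias suppression is monotone in the segmentation weight", {
  set.seed(41)
  for (k in 1:10) {
    p <- random_translational_pair(1)
    scene <- translational_scene_from_row(p)
    biases <- sapply(seq(0, 1, by = 0.25),
                     function(s) abs(estimate_foe(scene, s = s)$bias))
    expect_true(all(diff(biases) <= 1e-13))

    q <- random_curvilinear_pair(1)
    csc <- curvilinear_scene_from_row(q)
    devs <- sapply(seq(0, 1, by = 0.25),
                   function(s) abs(estimate_radius(csc, s = s)$ratio - 1))
    expect_true(all(diff(devs) <= 1e-13))
  }
})

test_that("local radius constraint recovers the path radius exactly", {
  layer <- curvilinear_ground_layer(-1.65, 0.12, 110)
  set.seed(43)
  x <- runif(50, -5e-3, 5e-3)
  y <- -runif(50, 2e-4, 5e-3)
  fl <- layer_flow(layer, x, y, cam)
  r_hat <- estimate_radius_local(x, y, fl$u, fl$v, -1.65, cam)
  expect_equal(r_hat, rep(110, 50), tolerance = 1e-9)
  # invariant under rescaling of the flow (the yaw rate cancels)
  expect_equal(estimate_radius_local(x, y, 3.7 * fl$u, 3.7 * fl$v, -1.65, cam),
               r_hat, tolerance = 1e-9)
  # horizon samples are degenerate
  expect_true(is.na(estimate_radius_local(1e-3, 0, 0.1, 0.2, -1.65, cam)))
})

test_that("integrated radius is exact on rigid ground flow and unbiased at s = 1", {
  set.seed(47)
  for (k in 1:25) {
    q <- random_curvilinear_pair(1)
    rigid <- layered_scene(
      cam, curvilinear_ground_layer(q$height, q$omega_B, q$r_B))
    expect_equal(estimate_radius(rigid)$r_hat, q$r_B, tolerance = 1e-12)

    scene <- curvilinear_scene_from_row(q)
    expect_equal(estimate_radius(scene, s = 1)$ratio, 1, tolerance = 1e-12)
  }
})

test_that("closed-form radius ratio equals the split-integral estimator", {
  set.seed(53)
  draws <- random_curvilinear_pair(500)
  for (k in seq_len(nrow(draws))) {
    q <- draws[k, ]
    fit <- estimate_radius(curvilinear_scene_from_row(q), s = q$s)
    rr <- radius_ratio(q$omega_B, q$omega_I, q$r_B, q$r_I, q$d_I, q$y_I,
                       q$w_I, q$h_I, cam$width, cam$height, q$height, cam$f,
                       s = q$s)
    expect_equal(fit$ratio, rr, tolerance = 1e-8)
  }
  # the ratio ignores the object's horizontal position
  q <- draws[1, ]
  f1 <- estimate_radius(curvilinear_scene_from_row(q), s = 0.3)$ratio
  q$x_I <- q$x_I + 2e-3
  f2 <- estimate_radius(curvilinear_scene_from_row(q), s = 0.3)$ratio
  expect_equal(f1, f2, tolerance = 1e-12)
  # zero-width object: unit ratio
  expect_equal(
    radius_ratio(q$omega_B, q$omega_I, q$r_B, q$r_I, q$d_I, q$y_I,
                 0, q$h_I, cam$width, cam$height, q$height, cam$f, 0), 1)
})

test_that("rasterised estimates converge to the analytic ones at second order", {
  ## IMO aligned with cell boundaries so only the quadrature error remains
  reg <- imo_region(0, -cam$height / 8, cam$width / 4, cam$height / 4)
  scene <- layered_scene(
    cam,
    background = curvilinear_ground_layer(-1.65, 0.15, 88),
    imo = reg,
    imo_layer = curvilinear_fronto_layer(5, 0.1, 95)
  )
  exact <- estimate_radius(scene, s = 0.4)$r_hat
  errs <- sapply(c(16, 32, 64, 128), function(nx) {
    ff <- render_flow_field(scene, nx = nx)
    abs(estimate_radius_field(ff, -1.65, region = reg, s = 0.4,
                              r_true = 88)$r_hat - exact)
  })
  rates <- log2(errs[-4] / errs[-1])
  expect_gt(mean(rates), 1.8)

  ## FOE route: integrands linear, so alignment makes it exact already
  tscene <- layered_scene(
    cam,
    background = translational_layer(10, c(0.35, 0, 2)),
    imo = reg,
    imo_layer = translational_layer(5, c(0.4, 0.1, 1))
  )
  ef <- estimate_foe(tscene, s = 0.25)
  ff <- render_flow_field(tscene, nx = 64)
  er <- estimate_foe_field(ff, gamma = 2 / 10, region = reg, s = 0.25,
                           v_background = c(0.35, 0, 2))
  expect_equal(er$eta_hat, ef$eta_hat, tolerance = 1e-12)
})

test_that("predicted path has the stated closed-form landmarks", {
  omega <- 0.2
  r <- 100
  h <- -1.65
  t45 <- (pi / 4) / omega
  path <- predicted_path(t45, omega, r, h, cam)
  expect_equal(path$x, cam$f * (sqrt(2) - 1), tolerance = 1e-12)

  # approaching a quarter orbit the vertical coordinate tends to -f h / r
  tq <- (pi / 2 - 1e-9) / omega
  expect_equal(predicted_path(tq, omega, r, h, cam)$y, -cam$f * h / r,
               tolerance = 1e-6)

  # the vertical coordinate ignores the yaw sign
  tgrid <- seq(0.2, 1, length.out = 5) * (pi / 2) / omega * 0.9
  expect_equal(predicted_path(tgrid, omega, r, h, cam)$y,
               predicted_path(-tgrid, -omega, r, h, cam)$y)
  expect_error(predicted_path(2 * pi / omega, omega, r, h, cam))
})

test_that("tidy and glance methods expose estimator results as tibbles", {
  p <- random_translational_pair(1)
  fit <- estimate_foe(translational_scene_from_row(p), s = 0.2)
  td <- tidy(fit)
  expect_identical(td$term, c("eta", "zeta"))
  expect_equal(td$estimate[1], fit$eta_hat)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$method, "analytic")

  q <- random_curvilinear_pair(1)
  rfit <- estimate_radius(curvilinear_scene_from_row(q), s = 0.1)
  expect_equal(tidy(rfit)$ratio, rfit$ratio)
  expect_identical(glance(rfit)$s, 0.1)
})
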