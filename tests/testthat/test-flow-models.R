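cam <- pinhole_camera(focal_length = 0.0174, width = 0.01)

test_that("general flow vanishes without motion and at the FOE", {
  g <- grid_points(cam, 7)
  still <- general_flow(g$x, g$y, 5, rigid_motion(), cam)
  expect_true(all(still$u == 0 & still$v == 0))

  v <- c(0.4, -0.3, 2)
  foe <- general_flow(cam$f * v[1] / v[3], cam$f * v[2] / v[3], 7,
                      rigid_motion(v), cam)
  expect_equal(foe$u, 0, tolerance = 1e-15)
  expect_equal(foe$v, 0, tolerance = 1e-15)

  # frozen hand-computed value: f = 0.01, Z = 10, v = (0,0,2), p = (0.005, 0)
  cam2 <- pinhole_camera(focal_length = 0.01, width = 0.02)
  fl <- general_flow(0.005, 0, 10, rigid_motion(c(0, 0, 2)), cam2)
  expect_equal(c(fl$u, fl$v), c(0.001, 0))
})

test_that("linear and rotational flow superimpose; translational flow scales with 1/Z", {
  set.seed(41)
  for (k in 1:20) {
    x <- runif(1, -5e-3, 5e-3)
    y <- runif(1, -5e-3, 5e-3)
    Z <- runif(1, 1, 20)
    v <- runif(3, -2, 2)
    w <- runif(3, -0.5, 0.5)
    full <- general_flow(x, y, Z, rigid_motion(v, w), cam)
    tr <- general_flow(x, y, Z, rigid_motion(v), cam)
    ro <- general_flow(x, y, Z, rigid_motion(omega = w), cam)
    expect_equal(full$u, tr$u + ro$u, tolerance = 1e-14)
    expect_equal(full$v, tr$v + ro$v, tolerance = 1e-14)
    # depth scaling of the translational part
    tr2 <- general_flow(x, y, 2 * Z, rigid_motion(v), cam)
    expect_equal(c(tr$u, tr$v), 2 * c(tr2$u, tr2$v), tolerance = 1e-12)
  }
})

test_that("x/y symmetry: swapping axes maps the flow components onto each other", {
  set.seed(42)
  for (k in 1:20) {
    x <- runif(1, -5e-3, 5e-3)
    y <- runif(1, -5e-3, 5e-3)
    Z <- runif(1, 1, 20)
    v <- runif(3, -2, 2)
    w <- runif(3, -0.5, 0.5)
    a <- general_flow(x, y, Z, rigid_motion(v, w), cam)
    b <- general_flow(y, x, Z,
                      rigid_motion(c(v[2], v[1], v[3]),
                                   c(-w[2], -w[1], -w[3])), cam)
    expect_equal(a$u, b$v, tolerance = 1e-14)
    expect_equal(a$v, b$u, tolerance = 1e-14)
  }
})

test_that("plane depth: fronto-parallel, looming, and ground-plane cases", {
  g <- grid_points(cam, 5)
  fronto <- translational_layer(10, c(0.3, 0, 2))
  expect_equal(plane_depth(g$x, g$y, 0, fronto, cam), rep(10, nrow(g)))
  expect_equal(plane_depth(g$x, g$y, 1.5, fronto, cam),
               rep(10 - 1.5 * 2, nrow(g)))

  # ground plane: n = (0, 1, 0), distance h above ground -> Z = f h / y
  ground <- translational_layer(1.65, c(0, 0, 2), normal = c(0, 1, 0))
  y <- c(1e-3, 3e-3)
  expect_equal(plane_depth(c(0, 1e-3), y, 0, ground, cam),
               cam$f * 1.65 / y)
  # horizon ray is degenerate
  expect_error(plane_depth(0, 0, 0, ground, cam), "degenerate")
  expect_true(is.na(plane_depth(0, 0, 0, ground, cam, on_degenerate = "na")))
})

test_that("translational plane flow equals general flow composed with plane depth", {
  g <- grid_points(cam, 33)
  layer <- translational_layer(8, c(0.5, -0.2, 1.5),
                               normal = c(0.1, -0.2, sqrt(1 - 0.05)))
  for (t in c(0, 1.1)) {
    direct <- layer_flow(layer, g$x, g$y, cam, t)
    Z <- plane_depth(g$x, g$y, t, layer, cam)
    composed <- general_flow(g$x, g$y, Z, rigid_motion(layer$v), cam)
    expect_equal(direct$u, composed$u, tolerance = 1e-12)
    expect_equal(direct$v, composed$v, tolerance = 1e-12)
  }
})

test_that("curvilinear fronto-parallel flow matches its depth/motion composition", {
  layer <- curvilinear_fronto_layer(d0 = 5, omega = 0.15, radius = 80)
  g <- grid_points(cam, 17)
  for (t in c(0, 0.35)) {
    s <- sin(layer$omega * t)
    co <- cos(layer$omega * t)
    Z <- cam$f * (layer$d0 - layer$radius * s) / (g$x * s + cam$f * co)
    composed <- general_flow(g$x, g$y, Z,
                             rigid_motion(c(0, 0, layer$omega * layer$radius),
                                          c(0, layer$omega, 0)), cam)
    direct <- layer_flow(layer, g$x, g$y, cam, t)
    expect_equal(direct$u, composed$u, tolerance = 1e-12)
    expect_equal(direct$v, composed$v, tolerance = 1e-12)
  }
  # zero yaw rate means zero tangential speed and no rotation: no flow
  nullf <- layer_flow(curvilinear_fronto_layer(5, 0, 80), 1e-3, -2e-3, cam)
  expect_equal(c(nullf$u, nullf$v), c(0, 0))
})

test_that("curvilinear ground flow equals general flow at ground depth", {
  layer <- curvilinear_ground_layer(height = -1.65, omega = 0.11, radius = 120)
  g <- grid_points(cam, 17)
  g <- g[g$y < -1e-4, ] # ground visible below the horizon for h < 0
  Z <- cam$f * layer$height / g$y
  composed <- general_flow(g$x, g$y, Z,
                           rigid_motion(c(0, 0, layer$omega * layer$radius),
                                        c(0, layer$omega, 0)), cam)
  direct <- layer_flow(layer, g$x, g$y, cam)
  expect_equal(direct$u, composed$u, tolerance = 1e-12)
  expect_equal(direct$v, composed$v, tolerance = 1e-12)

  # on the horizon the quadratic rotational term survives alone
  hor <- layer_flow(layer, 2e-3, 0, cam)
  expect_equal(hor$u, -layer$omega / cam$f * (cam$f^2 + (2e-3)^2))
  expect_equal(hor$v, 0)
})

test_that("analytic Jacobians and temporal derivatives match numerical differentiation", {
  layers <- list(
    translational_layer(8, c(0.5, -0.2, 1.5), normal = c(0.1, -0.2, sqrt(0.95))),
    curvilinear_fronto_layer(5, 0.15, 80),
    curvilinear_ground_layer(-1.65, 0.11, 120)
  )
  x <- c(-3e-3, 1e-3, 4e-3)
  y <- c(-4e-3, -1e-3, 2e-3)
  hs <- 1e-7
  for (layer in layers) {
    t0 <- 0.2
    J <- imoflow:::jacobian_uv(layer, cam$f, x, y, t0)
    fxp <- imoflow:::flow_uv(layer, cam$f, x + hs, y, t0)
    fxm <- imoflow:::flow_uv(layer, cam$f, x - hs, y, t0)
    fyp <- imoflow:::flow_uv(layer, cam$f, x, y + hs, t0)
    fym <- imoflow:::flow_uv(layer, cam$f, x, y - hs, t0)
    expect_equal(J$jxx, (fxp$u - fxm$u) / (2 * hs), tolerance = 1e-6)
    expect_equal(J$jxy, (fyp$u - fym$u) / (2 * hs), tolerance = 1e-6)
    expect_equal(J$jyx, (fxp$v - fxm$v) / (2 * hs), tolerance = 1e-6)
    expect_equal(J$jyy, (fyp$v - fym$v) / (2 * hs), tolerance = 1e-6)

    ht <- 1e-4
    d1 <- imoflow:::dflow_uv(layer, cam$f, x, y, t0, order = 1)
    d2 <- imoflow:::dflow_uv(layer, cam$f, x, y, t0, order = 2)
    ftp <- imoflow:::flow_uv(layer, cam$f, x, y, t0 + ht)
    ftm <- imoflow:::flow_uv(layer, cam$f, x, y, t0 - ht)
    ft0 <- imoflow:::flow_uv(layer, cam$f, x, y, t0)
    expect_equal(d1$u, (ftp$u - ftm$u) / (2 * ht), tolerance = 1e-6)
    expect_equal(d1$v, (ftp$v - ftm$v) / (2 * ht), tolerance = 1e-6)
    expect_equal(d2$u, (ftp$u - 2 * ft0$u + ftm$u) / ht^2, tolerance = 1e-4)
    expect_equal(d2$v, (ftp$v - 2 * ft0$v + ftm$v) / ht^2, tolerance = 1e-4)
  }
})

test_that("layered flow assigns the closed IMO region to the object layer", {
  reg <- imo_region_deg(-6, 0, 10, 10, cam)
  scene <- layered_scene(
    cam,
    background = translational_layer(10, c(0.35, 0, 2)),
    imo = reg,
    imo_layer = translational_layer(5, c(0.71, 0, 0))
  )
  edge_x <- reg$x + reg$width / 2 # boundary sample
  lf <- layered_flow(scene, c(edge_x, edge_x + 1e-6, reg$x), c(0, 0, 0))
  expect_identical(lf$layer, c("I", "B", "I"))

  # inside the region the flow is the object-layer flow: mu_I = 1/5, v_x = 0.71
  expect_equal(lf$u[3], (1 / 5) * (-cam$f * 0.71), tolerance = 1e-15)
  expect_equal(lf$v[3], 0)

  # an IMO identical to the background leaves the field unchanged
  twin <- layered_scene(
    cam,
    background = translational_layer(10, c(0.35, 0, 2)),
    imo = reg,
    imo_layer = translational_layer(10, c(0.35, 0, 2))
  )
  g <- grid_points(cam, 21)
  plain <- layer_flow(twin$background, g$x, g$y, cam)
  both <- layered_flow(twin, g$x, g$y)
  expect_equal(both$u, plain$u)
  expect_equal(both$v, plain$v)
})

test_that("rendered fields are deterministic cell-centred grids", {
  scene <- layered_scene(cam, translational_layer(10, c(0.35, 0, 2)))
  one <- render_flow_field(scene, nx = 1)
  expect_identical(nrow(one), 1L)
  expect_equal(c(one$x, one$y), c(0, 0))
  direct <- layered_flow(scene, 0, 0)
  expect_equal(one$u, direct$u)

  a <- render_flow_field(scene, nx = 9)
  b <- render_flow_field(scene, nx = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(range(a$x), c(-1, 1) * (cam$width / 2 - attr(a, "dx") / 2))
})
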