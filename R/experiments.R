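#' Frozen configurations of the three replicated heading/path studies
#'
#' Each constructor returns the camera, layer parameters, condition grid and
#' segmentation coefficients of one psychophysics configuration, exactly as
#' used by the replications:
#'
#' * `config_warren_saunders()`: linear motion toward two fronto-parallel
#'   planes, both initially at 10 m, background approaching at 2 m/s and the
#'   object at 3 m/s. Heading (FOE) at probe + offset with probe
#'   eccentricities 4, 6, 8, 10 degrees and offsets 0.5, 1, 2, 4 degrees
#'   (16 combinations, evaluated on the positive-probe side; the model is
#'   left/right antisymmetric); object path angles -6, 0, +6 degrees; the
#'   object is centred at 6 degrees on the opposite side of the probe
#'   (FOE-visible group) or on the probe's side (FOE-obscured group). The
#'   flow snapshot is taken at the end of the 1.5 s presentation, when the
#'   looming object subtends 16 x 16 degrees. Display 32 x 32 degrees
#'   (1 cm, f = 1.74 cm); cue coefficients `(1e5, -6e2, 4.5e5)`.
#' * `config_royden_hildreth()`: background plane at 10 m approaching at
#'   2 m/s; the object stays at 5 m (zero approach) and translates sideways
#'   at 0.71 m/s (8.1 deg/s at 25 Hz against 5 m). FOE at 4-7 degrees
#'   horizontal by -2, 0, +2 degrees vertical (12 positions); object
#'   10 x 10 degrees, starting at 0.6 degrees (non-crossing, moving outward)
#'   or 10.7 degrees (crossing, moving toward and across the path). Display
#'   30 x 30 degrees (1 cm, f = 1.87 cm); coefficients
#'   `(3.5e5, -10.5e2, 3e5)`.
#' * `config_fajen_kim()`: curvilinear travel at 13.2 m/s over a ground
#'   plane at eye height -1.65 m, radii 80, 120, 160, 320 m (yaw = v/r);
#'   the object orbits 2.86 deg/s slower, as a fronto-parallel plane at 5 m
#'   subtending 5 x 5 degrees at 5 degrees below the horizon (horizontal
#'   centre 0 degrees). Paths A/B keep the object's radius equal to the
#'   background's (right/left mirror; identical under the model), path C
#'   decreases and path D increases it by 7.2 m. Display 32 x 32 degrees;
#'   coefficients `(1e4, 1e1, 1e4)`.
#'
#' @return A list of class `study_config` with elements `study`, `camera`,
#'   `coefficients`, `snapshot_time`, `conditions` (a tibble) and
#'   study-specific parameters.
#' @export
config_warren_saunders <- function() {
  camera <- pinhole_camera(focal_length = 0.0174, width = 0.01)
  conditions <- tidyr::expand_grid(
    group = c("visible", "obscured"),
    probe_deg = c(4, 6, 8, 10),
    offset_deg = c(0.5, 1, 2, 4),
    path_angle_deg = c(-6, 0, 6)
  )
  structure(
    list(
      study = "warren_saunders", camera = camera,
      d0_B = 10, d0_I = 10, v_z_B = 2, v_z_I = 3,
      imo_ecc_deg = 6, imo_size_deg = 16,
      snapshot_time = 1.5,
      coefficients = c(1e5, -6e2, 4.5e5),
      conditions = conditions
    ),
    class = "study_config"
  )
}

#' @rdname config_warren_saunders
#' @export
config_royden_hildreth <- function() {
  camera <- pinhole_camera(focal_length = 0.0187, width = 0.01)
  conditions <- tidyr::expand_grid(
    condition = c("non_crossing", "crossing"),
    foe_h_deg = c(4, 5, 6, 7),
    foe_v_deg = c(-2, 0, 2)
  )
  structure(
    list(
      study = "royden_hildreth", camera = camera,
      d0_B = 10, d0_I = 5, v_z_B = 2, v_z_I = 0,
      v_x_I = angular_velocity_to_metric(8.1 / 25, 5) * 25, # 0.71 m/s
      imo_size_deg = 10,
      imo_start_deg = c(non_crossing = 0.6, crossing = 10.7),
      snapshot_time = 0,
      coefficients = c(3.5e5, -10.5e2, 3e5),
      conditions = conditions
    ),
    class = "study_config"
  )
}

#' @rdname config_warren_saunders
#' @export
config_fajen_kim <- function() {
  camera <- pinhole_camera(focal_length = 0.0174, width = 0.01)
  conditions <- tidyr::expand_grid(
    radius = c(80, 120, 160, 320),
    path = c("A", "B", "C", "D")
  )
  structure(
    list(
      study = "fajen_kim", camera = camera,
      speed = 13.2, height = -1.65,
      omega_offset = deg2rad(2.86), # object orbits this much slower
      radius_offset = 7.2,
      d_I = 5, imo_size_deg = 5, imo_x_deg = 0, imo_y_deg = -5,
      snapshot_time = 0,
      coefficients = c(1e4, 1e1, 1e4),
      conditions = conditions
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config: %s> %d conditions\n",
              x$study, nrow(x$conditions)))
  invisible(x)
}

ws_scene <- function(config, group, probe_deg, offset_deg, path_angle_deg) {
  cam <- config$camera
  foe_deg <- probe_deg + offset_deg
  v_x_B <- angular_velocity_to_metric(foe_deg, config$v_z_B)
  imo_side <- if (group == "visible") -1 else 1
  imo_dir_deg <- foe_deg - path_angle_deg
  v_x_I <- angular_velocity_to_metric(imo_dir_deg, config$v_z_I)
  layered_scene(
    cam,
    background = translational_layer(config$d0_B, c(v_x_B, 0, config$v_z_B)),
    imo = imo_region_deg(imo_side * config$imo_ecc_deg, 0,
                         config$imo_size_deg, config$imo_size_deg, cam),
    imo_layer = translational_layer(config$d0_I, c(v_x_I, 0, config$v_z_I))
  )
}

rh_scene <- function(config, condition, foe_h_deg, foe_v_deg) {
  cam <- config$camera
  v_x_B <- angular_velocity_to_metric(foe_h_deg, config$v_z_B)
  v_y_B <- angular_velocity_to_metric(foe_v_deg, config$v_z_B)
  ## non-crossing: object translates outward (away from the observer's
  ## path); crossing: it translates toward and across it.
  v_x_I <- if (condition == "crossing") config$v_x_I else -config$v_x_I
  layered_scene(
    cam,
    background = translational_layer(config$d0_B,
                                     c(v_x_B, v_y_B, config$v_z_B)),
    imo = imo_region_deg(config$imo_start_deg[[condition]], 0,
                         config$imo_size_deg, config$imo_size_deg, cam),
    imo_layer = translational_layer(config$d0_I, c(v_x_I, 0, config$v_z_I))
  )
}

fk_scene <- function(config, radius, path) {
  cam <- config$camera
  omega_B <- config$speed / radius
  omega_I <- omega_B - config$omega_offset
  r_I <- switch(path,
    A = radius, B = radius,
    C = radius - config$radius_offset,
    D = radius + config$radius_offset
  )
  layered_scene(
    cam,
    background = curvilinear_ground_layer(config$height, omega_B, radius),
    imo = imo_region_deg(config$imo_x_deg, config$imo_y_deg,
                         config$imo_size_deg, config$imo_size_deg, cam),
    imo_layer = curvilinear_fronto_layer(config$d_I, omega_I, r_I)
  )
}

scene_segmentation <- function(scene, config) {
  strengths <- cue_strengths(scene, t = config$snapshot_time)
  combined_segmentation(strengths, config$coefficients)
}

#' Run a heading-experiment replication
#'
#' Builds the layered scene of every condition of a linear-motion study,
#' optionally computes the combined segmentation signal `s` from the contour
#' cue strengths, runs the least-squares FOE estimator with the IMO region
#' weighted by `(1 - s)`, and reports the heading error in degrees
#' (`atan(eta_hat) - atan(eta_B)`). The model is deterministic; the reported
#' per-group standard deviations span the study's condition set, not noise.
#'
#' @param config A [config_warren_saunders()] or [config_royden_hildreth()].
#' @param segmentation Use the combined cue signal (`TRUE`) or `s = 0`.
#' @return A tibble of class `experiment_report`, one row per condition,
#'   with the segmentation signal, estimated and true heading, and error.
#' @export
run_heading_experiment <- function(config, segmentation = TRUE) {
  stopifnot(inherits(config, "study_config"))
  t <- config$snapshot_time
  if (config$study == "warren_saunders") {
    rows <- purrr::pmap(config$conditions, function(group, probe_deg,
                                                    offset_deg,
                                                    path_angle_deg) {
      scene <- ws_scene(config, group, probe_deg, offset_deg, path_angle_deg)
      s <- if (segmentation) scene_segmentation(scene, config) else 0
      fit <- estimate_foe(scene, t = t, s = s)
      tibble(
        group = group, probe_deg = probe_deg, offset_deg = offset_deg,
        path_angle_deg = path_angle_deg,
        foe_deg = probe_deg + offset_deg,
        s = s, eta_hat = fit$eta_hat,
        heading_deg = rad2deg(atan(fit$eta_hat)),
        bias = fit$bias, bias_deg = fit$bias_deg
      )
    })
  } else if (config$study == "royden_hildreth") {
    rows <- purrr::pmap(config$conditions, function(condition, foe_h_deg,
                                                    foe_v_deg) {
      scene <- rh_scene(config, condition, foe_h_deg, foe_v_deg)
      s <- if (segmentation) scene_segmentation(scene, config) else 0
      fit <- estimate_foe(scene, t = t, s = s)
      tibble(
        condition = condition, foe_h_deg = foe_h_deg, foe_v_deg = foe_v_deg,
        s = s, eta_hat = fit$eta_hat,
        heading_deg = rad2deg(atan(fit$eta_hat)),
        bias = fit$bias, bias_deg = fit$bias_deg
      )
    })
  } else {
    abort("heading experiments are defined for the two linear-motion studies")
  }
  out <- dplyr::bind_rows(rows)
  out$study <- config$study
  out$segmentation <- segmentation
  structure(out, class = c("experiment_report", class(out)))
}

#' Run the curvilinear path-perception replication
#'
#' For every radius-by-path condition, builds the ground-plane background
#' and object layers, optionally computes the segmentation signal, and
#' reports the radius-ratio `rho_r = r_hat / r_B` of the integrated radius
#' estimator. Paths A and B are identical under the model (the ratio is
#' independent of the object's horizontal position).
#'
#' @param config A [config_fajen_kim()].
#' @param segmentation Use the combined cue signal (`TRUE`) or `s = 0`.
#' @return A tibble of class `experiment_report`, one row per condition.
#' @export
run_path_experiment <- function(config, segmentation = TRUE) {
  stopifnot(inherits(config, "study_config"),
            config$study == "fajen_kim")
  rows <- purrr::pmap(config$conditions, function(radius, path) {
    scene <- fk_scene(config, radius, path)
    s <- if (segmentation) scene_segmentation(scene, config) else 0
    fit <- estimate_radius(scene, s = s)
    tibble(radius = radius, path = path, s = s,
           r_hat = fit$r_hat, ratio = fit$ratio)
  })
  out <- dplyr::bind_rows(rows)
  out$study <- config$study
  out$segmentation <- segmentation
  structure(out, class = c("experiment_report", class(out)))
}

#' Run all static-versus-dynamic sweeps
#'
#' Convenience driver around [sweep_translational()] and
#' [sweep_curvilinear()]: one row per scenario-cue pair with the percentage
#' of grid cases whose cue changes by more than the threshold fraction when
#' the discontinuity becomes dynamic.
#'
#' @param threshold Relative-difference criterion.
#' @param ... Passed to the individual sweep functions.
#' @return A tibble with columns `scenario`, `cue`, `percent`, and the case
#'   counts of [sweep_translational()].
#' @export
run_static_dynamic_sweeps <- function(threshold = 0.3, ...) {
  tr <- sweep_translational(threshold = threshold, ...)$summary
  cu <- sweep_curvilinear(threshold = threshold, ...)$summary
  dplyr::bind_rows(
    dplyr::mutate(tr, scenario = "translation_plane", .before = 1),
    dplyr::mutate(cu, scenario = "curvilinear_ground", .before = 1)
  )
}

#' Summarise an experiment report by condition group
#'
#' Mean and standard deviation of the reported error across the conditions
#' of each group (FOE visibility by path angle; crossing condition by FOE
#' position; or radius by path).
#'
#' @param report An `experiment_report`.
#' @return A summary tibble.
#' @export
summarise_experiment <- function(report) {
  if ("group" %in% names(report)) {
    dplyr::summarise(
      dplyr::group_by(report, .data$group, .data$path_angle_deg),
      mean_bias_deg = mean(.data$bias_deg),
      sd_bias_deg = stats::sd(.data$bias_deg),
      .groups = "drop"
    )
  } else if ("condition" %in% names(report)) {
    dplyr::summarise(
      dplyr::group_by(report, .data$condition, .data$foe_h_deg),
      mean_heading_deg = mean(.data$heading_deg),
      mean_bias_deg = mean(.data$bias_deg),
      sd_bias_deg = stats::sd(.data$bias_deg),
      .groups = "drop"
    )
  } else {
    dplyr::summarise(
      dplyr::group_by(report, .data$radius, .data$path),
      ratio = mean(.data$ratio),
      .groups = "drop"
    )
  }
}
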