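#' Read a scene description from a YAML or JSON file
#'
#' A configuration file describes the camera, the background layer and
#' optionally an IMO. Angles may be given with a `_deg` suffix and are
#' converted once at this boundary. Example:
#'
#' ```yaml
#' camera: {fov_deg: 32, width_m: 0.01}
#' background: {type: translational, d0: 10, v: [0.35, 0, 2]}
#' imo:
#'   region: {x_deg: -6, y_deg: 0, width_deg: 10, height_deg: 10}
#'   layer: {type: translational, d0: 10, v: [-0.2, 0, 3]}
#' ```
#'
#' Layer `type` is one of `translational` (fields `d0`, `v`, optional
#' `normal`), `curvilinear_fronto` (`d0`, `omega` or `omega_deg`, `radius`)
#' or `curvilinear_ground` (`height`, `omega` or `omega_deg`, `radius`).
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [layered_scene()].
#' @export
read_scene_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$camera) || is.null(cfg$background)) {
    abort("config must contain `camera` and `background` blocks")
  }
  cc <- cfg$camera
  w <- if (!is.null(cc$width_m)) cc$width_m else 0.01
  h <- if (!is.null(cc$height_m)) cc$height_m else w
  cam <- if (!is.null(cc$focal_length_m)) {
    pinhole_camera(focal_length = cc$focal_length_m, width = w, height = h)
  } else {
    pinhole_camera(fov_deg = cc$fov_deg, width = w, height = h)
  }
  bg <- config_layer(cfg$background)
  if (is.null(cfg$imo)) {
    return(layered_scene(cam, bg))
  }
  reg <- cfg$imo$region
  region <- if (!is.null(reg$x_deg)) {
    imo_region_deg(reg$x_deg, reg$y_deg, reg$width_deg, reg$height_deg, cam)
  } else {
    imo_region(reg$x, reg$y, reg$width, reg$height)
  }
  layered_scene(cam, bg, imo = region, imo_layer = config_layer(cfg$imo$layer))
}

config_layer <- function(block) {
  type <- block$type
  omega <- if (!is.null(block$omega_deg)) deg2rad(block$omega_deg) else block$omega
  switch(type,
    translational = translational_layer(
      block$d0, unlist(block$v),
      normal = if (is.null(block$normal)) c(0, 0, 1) else unlist(block$normal)
    ),
    curvilinear_fronto = curvilinear_fronto_layer(block$d0, omega, block$radius),
    curvilinear_ground = curvilinear_ground_layer(block$height, omega, block$radius),
    abort(sprintf("unknown layer type '%s'", type))
  )
}
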