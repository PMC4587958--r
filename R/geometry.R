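# Analytic nested-cylinder model of the Co0.A86 source inside a cubic
# phantom. Coordinate origin at the geometric centre of the active volume,
# z along the source axis, transverse plane z = 0. The drive cable abuts
# the proximal (negative-z) capsule end.

REGION_NAMES <- c("core", "gap", "capsule", "cable", "phantom")
OUTSIDE_SENTINEL <- "outside"

#' Build the nested-cylinder source model
#'
#' The default dimensions are the manufacturer values: active core 3.5 mm
#' long, 0.5 mm diameter; stainless-steel capsule of 1 mm external
#' diameter with 0.15 mm thick wall and flat end caps of the same
#' thickness; 5 mm of steel drive cable of capsule diameter on the
#' negative-z side. Those dimensions leave a 0.1 mm air-filled annular gap
#' between the core surface and the capsule inner wall, which is modeled
#' explicitly as region `"gap"`.
#'
#' @param core_length_cm,core_diameter_cm active core dimensions (cm).
#' @param capsule_wall_cm capsule wall/end-cap thickness (cm).
#' @param capsule_outer_diameter_cm capsule external diameter (cm).
#' @param cable_length_cm drive cable length (cm).
#' @param phantom_side_cm side of the cubic phantom centred on the source.
#' @param phantom_medium `"water"` or `"air"`.
#' @return An object of class `source_model`.
#' @export
source_model <- function(core_length_cm = 0.35,
                         core_diameter_cm = 0.05,
                         capsule_wall_cm = 0.015,
                         capsule_outer_diameter_cm = 0.1,
                         cable_length_cm = 0.5,
                         phantom_side_cm = 100,
                         phantom_medium = c("water", "air")) {
  phantom_medium <- match.arg(phantom_medium)
  r_core <- core_diameter_cm / 2
  h_core <- core_length_cm / 2
  r_cap <- capsule_outer_diameter_cm / 2
  r_cap_in <- r_cap - capsule_wall_cm
  h_cap <- h_core + capsule_wall_cm
  if (r_core >= r_cap_in)
    stop("core is not strictly contained in the capsule interior")
  if (2 * h_cap >= phantom_side_cm || 2 * r_cap >= phantom_side_cm)
    stop("phantom must enclose the source")
  structure(list(
    r_core = r_core, h_core = h_core, r_cap_in = r_cap_in, r_cap = r_cap,
    h_cap = h_cap, cable_length = cable_length_cm,
    z_cable_min = -h_cap - cable_length_cm,
    half_side = phantom_side_cm / 2,
    phantom_medium = phantom_medium
  ), class = "source_model")
}

geom_payload <- function(model, point_source = FALSE) {
  list(r_core = model$r_core, h_core = model$h_core,
       r_cap_in = model$r_cap_in, r_cap = model$r_cap,
       h_cap = model$h_cap, z_cable_min = model$z_cable_min,
       half_side = model$half_side, point_source = point_source)
}

region_label <- function(idx) {
  ifelse(idx < 0, OUTSIDE_SENTINEL, REGION_NAMES[idx + 1L])
}

#' Locate the region containing a point
#'
#' Boundary points resolve to the inner region (closed inner surfaces).
#'
#' @param model a `source_model`.
#' @param points numeric 3-vector or n x 3 matrix of coordinates (cm).
#' @return Character vector of region names; `"outside"` for points beyond
#'   the phantom cube.
#' @export
locate_region <- function(model, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  region_label(cpp_locate(geom_payload(model), points))
}

#' Distance to the next region boundary along a ray
#'
#' Smallest positive ray-surface intersection over all cylinder walls, end
#' caps and the phantom cube. A ray starting exactly on a surface is
#' advanced by 1e-8 cm before tracing, which removes zero-distance loops.
#'
#' @param model a `source_model`.
#' @param position 3-vector, cm; must be inside the phantom.
#' @param direction 3-vector; normalized internally.
#' @return List with `distance` (cm), `region` and `next_region` (names).
#' @export
boundary_distance <- function(model, position, direction) {
  direction <- direction / sqrt(sum(direction^2))
  res <- cpp_boundary(geom_payload(model), as.numeric(position),
                      as.numeric(direction))
  if (res$region < 0) stop("position is outside the phantom")
  list(distance = res$distance,
       region = region_label(res$region),
       next_region = region_label(res$next_region))
}

#' Sample source photons
#'
#' Emission positions are uniform over the active core volume, directions
#' isotropic, and energies 1.17 or 1.33 MeV with the given line weights.
#'
#' @param model a `source_model`.
#' @param n number of photons.
#' @param seed RNG seed for the emission stream.
#' @param line_weights relative weights of the (1.17, 1.33) MeV lines.
#' @return List with `position` (n x 3), `direction` (n x 3, unit rows),
#'   `energy` (MeV) and `weight` (all 1).
#' @export
sample_emission <- function(model, n, seed = 1,
                            line_weights = c(0.5, 0.5)) {
  w133 <- line_weights[2] / sum(line_weights)
  out <- cpp_sample_emission(geom_payload(model), as.integer(n), seed, w133)
  out$weight <- rep(1, n)
  out
}
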