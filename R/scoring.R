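# Track-length collision-kerma scoring over full-azimuth ring cells, and
# the two standard scoring setups: air kerma at 100 cm in a 2.5 m air
# cube; water kerma at sixteen transverse-axis distances (optionally an
# (r, theta) polar grid) in a 100 cm water cube.

#' Transverse-axis ring cells
#'
#' Full-azimuth ring cells centred on the transverse plane, exploiting the
#' source's rotational symmetry.
#'
#' @param r_cm radial cell-centre distances, cm.
#' @param dr_cm radial thickness.
#' @param dz_cm height.
#' @param z_cm axial centre (default the transverse plane).
#' @return Data frame with r1, r2, z1, z2 plus the `r_cm`/`theta_deg`
#'   labels used in reports.
#' @export
ring_cells <- function(r_cm, dr_cm = 0.01, dz_cm = 0.01, z_cm = 0) {
  data.frame(r_cm = r_cm, theta_deg = 90,
             r1 = pmax(0, r_cm - dr_cm / 2), r2 = r_cm + dr_cm / 2,
             z1 = z_cm - dz_cm / 2, z2 = z_cm + dz_cm / 2)
}

#' Polar-grid ring cells
#'
#' Ring cells centred at polar coordinates (r, theta) from the source
#' centre, theta measured from the +z source axis; used for the
#' anisotropy-function grid.
#'
#' @param r_cm radial distances, cm.
#' @param theta_deg polar angles, degrees.
#' @param half_cm half-extent of each cell in the radial and axial
#'   directions.
#' @return Data frame as in [ring_cells()].
#' @export
polar_cells <- function(r_cm, theta_deg, half_cm = 0.05) {
  g <- expand.grid(r_cm = r_cm, theta_deg = theta_deg)
  rho <- g$r_cm * sin(g$theta_deg * pi / 180)
  z <- g$r_cm * cos(g$theta_deg * pi / 180)
  data.frame(r_cm = g$r_cm, theta_deg = g$theta_deg,
             r1 = pmax(0, rho - half_cm), r2 = rho + half_cm,
             z1 = z - half_cm, z2 = z + half_cm)
}

#' Score one track segment into ring cells
#'
#' Adds, for every cell the segment crosses, the track-length estimate
#' `weight * E * (mu_en/rho)(E) * chord / volume`, converted to Gy. The
#' segment must lie in a single medium; the caller is responsible for
#' splitting segments at region boundaries.
#'
#' @param cells ring-cell data frame.
#' @param start,end segment endpoints, cm.
#' @param energy photon energy, MeV.
#' @param weight statistical weight.
#' @param mu_en_rho mass energy-absorption coefficient of the cell medium
#'   at `energy`, cm^2/g.
#' @return Numeric vector of per-cell kerma contributions, Gy.
#' @export
score_segment <- function(cells, start, end, energy, weight = 1,
                          mu_en_rho) {
  cm <- as.matrix(cells[, c("r1", "r2", "z1", "z2")])
  cpp_score_segment(cm, mu_en_rho, as.numeric(start), as.numeric(end),
                    energy, weight)
}

#' Type-A relative uncertainty of batch means
#'
#' Standard error of the batch means divided by the grand mean, reported
#' at coverage factor k = 1.
#'
#' @param batch_means numeric vector of per-batch means (>= 2 batches).
#' @return Relative uncertainty; `NA` when the grand mean is zero.
#' @export
rel_uncertainty <- function(batch_means) {
  if (length(batch_means) < 2) stop("at least 2 batches are required")
  m <- mean(batch_means)
  if (m == 0) return(NA_real_)
  sd(batch_means) / sqrt(length(batch_means)) / m
}

#' Tally report table
#'
#' @param tallies an `mc_tallies` object.
#' @return Data frame with columns r_cm, theta_deg, kerma_Gy_per_history,
#'   rel_uncertainty_k1, n_batches.
#' @export
tally_table <- function(tallies) {
  data.frame(r_cm = tallies$cells$r_cm,
             theta_deg = tallies$cells$theta_deg,
             kerma_Gy_per_history = tallies$kerma_Gy_per_history,
             rel_uncertainty_k1 = tallies$rel_uncertainty_k1,
             n_batches = tallies$batches)
}

#' Air-kerma stage
#'
#' Source centred in a 2.5 m air cube; kerma scored in transverse-axis
#' ring cells 2 cm thick and 1 cm high (the reference cell at 100 cm).
#'
#' @param config a `run_config`; its phantom spec is overridden to the
#'   250 cm humid-air cube.
#' @param distances_cm scoring distances (default the 100 cm reference).
#' @param thickness_cm,height_cm ring-cell dimensions.
#' @param tables attenuation tables.
#' @param phantom_side_cm air cube side; enlarge it when scoring beyond
#'   the default cube.
#' @return List with `kerma_Gy_per_history` and `rel_uncertainty_k1` at
#'   each distance and the full `tallies` object.
#' @export
air_kerma_run <- function(config, distances_cm = 100, thickness_cm = 2,
                          height_cm = 1, tables = load_xs_tables(),
                          phantom_side_cm = 250) {
  if (max(distances_cm) + thickness_cm / 2 > phantom_side_cm / 2)
    stop("scoring distance beyond the phantom cube")
  config$phantom_side_cm <- phantom_side_cm
  config$phantom_medium <- "air"
  cells <- ring_cells(distances_cm, dr_cm = thickness_cm,
                      dz_cm = height_cm)
  tal <- run_simulation(config, cells, tables = tables)
  list(distances_cm = distances_cm,
       kerma_Gy_per_history = tal$kerma_Gy_per_history,
       rel_uncertainty_k1 = tal$rel_uncertainty_k1,
       tallies = tal)
}

#' Water-dose stage
#'
#' Source centred in a 100 cm water cube (density 0.998 g/cm^3); kerma
#' scored in 0.1 mm x 0.1 mm transverse-axis ring voxels at the sixteen
#' standard distances, optionally plus an (r, theta) polar grid.
#'
#' @param config a `run_config`; its phantom spec is overridden to the
#'   100 cm water cube.
#' @param distances_cm transverse scoring distances.
#' @param voxel_cm ring-voxel radial thickness and height (default
#'   0.01 cm = 0.1 mm).
#' @param f_grid optional list(r_cm, theta_deg, half_cm) adding a polar
#'   grid for the anisotropy function.
#' @param tables attenuation tables.
#' @return List with the transverse `dose_table` (r_cm, theta_deg, kerma,
#'   uncertainty), optional `polar_table`, and the `tallies` object.
#' @export
water_dose_run <- function(config, distances_cm = WATER_DISTANCES_CM,
                           voxel_cm = 0.01, f_grid = NULL,
                           tables = load_xs_tables()) {
  config$phantom_side_cm <- 100
  config$phantom_medium <- "water"
  cells <- ring_cells(distances_cm, dr_cm = voxel_cm, dz_cm = voxel_cm)
  if (!is.null(f_grid)) {
    half <- if (is.null(f_grid$half_cm)) 0.05 else f_grid$half_cm
    cells <- rbind(cells,
                   polar_cells(f_grid$r_cm, f_grid$theta_deg, half))
  }
  tal <- run_simulation(config, cells, tables = tables)
  tab <- tally_table(tal)
  n_t <- length(distances_cm)
  list(dose_table = tab[seq_len(n_t), ],
       polar_table = if (nrow(tab) > n_t) tab[-seq_len(n_t), ],
       tallies = tal)
}
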