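# Analog photon transport: free-path sampling against the current region's
# attenuation, interaction dispatch by branch fractions, free-electron
# Klein-Nishina Compton kinematics, Thomson-law Rayleigh redirection,
# photoelectric termination, pair production with annihilation photons.
# No electron transport: dose is identified with collision kerma.

MEC2 <- 0.51099895
WATER_DISTANCES_CM <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 7, 8,
                        10, 12, 15, 20)

#' Build a run configuration
#'
#' @param histories number of source photons.
#' @param seed root RNG seed; per-batch child streams are derived from it
#'   by a counter scheme so repeated runs are bit-identical.
#' @param batches number of batches for type-A uncertainty estimation.
#' @param cutoff_MeV photon cutoff energy; photons falling below it are
#'   terminated with their energy recorded as locally absorbed. Floor
#'   0.010 MeV (the table range).
#' @param electron_cutoff_MeV recorded for provenance only; electrons are
#'   not transported under the kerma approximation.
#' @param line_weights relative weights of the 1.17 and 1.33 MeV lines.
#' @param phantom_side_cm,phantom_medium phantom cube spec.
#' @param vacuum_mode disable all interactions (testing: pure
#'   inverse-square transport).
#' @param primary_only terminate photons at their first collision
#'   (testing: exponential primary fluence).
#' @param point_source emit from the origin and ignore the capsule
#'   geometry (testing: bare point emitter).
#' @return An object of class `run_config`.
#' @export
run_config <- function(histories = 1e6, seed = 1, batches = 50,
                       cutoff_MeV = 0.010, electron_cutoff_MeV = 0.010,
                       line_weights = c(0.5, 0.5),
                       phantom_side_cm = 100,
                       phantom_medium = c("water", "air"),
                       vacuum_mode = FALSE, primary_only = FALSE,
                       point_source = FALSE) {
  phantom_medium <- match.arg(phantom_medium)
  if (batches < 2) stop("at least 2 batches are required")
  if (histories < batches) stop("histories must be >= batches")
  if (cutoff_MeV < 0.010) stop("cutoff energy floor is 0.010 MeV")
  structure(list(histories = histories, seed = seed, batches = batches,
                 cutoff_MeV = cutoff_MeV,
                 electron_cutoff_MeV = electron_cutoff_MeV,
                 line_weights = line_weights,
                 phantom_side_cm = phantom_side_cm,
                 phantom_medium = phantom_medium,
                 vacuum_mode = vacuum_mode, primary_only = primary_only,
                 point_source = point_source),
            class = "run_config")
}

#' Exponential free path by inverse CDF
#'
#' @param mu_linear linear attenuation coefficient, cm^-1 (positive).
#' @param u uniform deviates in `[0, 1)`.
#' @return Flight distance `-log(1 - u) / mu`, cm.
#' @export
free_path <- function(mu_linear, u) {
  if (any(mu_linear <= 0)) stop("mu_linear must be positive")
  -log(1 - u) / mu_linear
}

#' Compton kinematic relation
#'
#' @param energy incident photon energy, MeV.
#' @param cos_theta cosine of the polar scattering angle.
#' @return Scattered photon energy E' = E / (1 + (E/m_e c^2)(1 - cos)).
#' @export
compton_kinematics <- function(energy, cos_theta) {
  energy / (1 + (energy / MEC2) * (1 - cos_theta))
}

#' Sample Klein-Nishina Compton scatters
#'
#' Free-electron Klein-Nishina differential cross section, sampled by
#' rejection under a constant envelope; azimuth uniform.
#'
#' @param energy incident photon energy, MeV.
#' @param n number of samples.
#' @param seed RNG seed.
#' @return Data frame with `energy` (scattered, MeV), `cos_theta`, `phi`.
#' @export
sample_compton <- function(energy, n, seed = 1) {
  if (energy <= 0.010 || energy > 1.35)
    stop("energy must be in (0.010, 1.35] MeV")
  m <- cpp_compton_sample(energy, as.integer(n), seed)
  data.frame(energy = m[, 1], cos_theta = m[, 2], phi = m[, 3])
}

#' Pair-production event kinematics
#'
#' The pair's kinetic energy (E - 1.022 MeV) is treated as locally
#' absorbed (kerma approximation); annihilation at rest emits two
#' 0.511 MeV photons in opposite directions with isotropic orientation.
#'
#' @param energy incident photon energy, MeV; must exceed 1.022.
#' @param n number of events.
#' @param seed RNG seed.
#' @return List with `deposited_MeV`, `photon_energy_MeV` (always
#'   2 x 0.511) and `direction` (n x 3 unit rows; the partner photon is
#'   the negation).
#' @export
sample_pair <- function(energy, n = 1, seed = 1) {
  if (energy <= 2 * MEC2)
    stop("pair production requires energy > 1.022 MeV")
  set.seed(seed)
  ct <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(1 - ct^2)
  list(deposited_MeV = rep(energy - 2 * MEC2, n),
       photon_energy_MeV = c(MEC2, MEC2),
       direction = cbind(st * cos(phi), st * sin(phi), ct))
}

table_payloads <- function(tables) {
  lapply(tables[c("water", "air", "steel", "cobalt")], unclass)
}

region_material_map <- function(phantom_medium) {
  # material order passed to the engine: water=1, air=2, steel=3, cobalt=4
  phantom <- if (phantom_medium == "water") 1L else 2L
  c(core = 4L, gap = 2L, capsule = 3L, cable = 3L, phantom = phantom)
}

#' Run a batched Monte Carlo simulation
#'
#' Transports `histories` source photons (and their descendants) through
#' the nested geometry and scores collision kerma in the given ring cells
#' with the linear track-length estimator. Deterministic given (seed,
#' histories, batches): repeated runs are bit-identical.
#'
#' @param config a `run_config`.
#' @param cells ring-cell data frame from [ring_cells()] /
#'   [polar_cells()].
#' @param model a `source_model`; built from the config phantom spec when
#'   `NULL`.
#' @param tables attenuation tables from [load_xs_tables()].
#' @return An object of class `mc_tallies`: per-cell kerma per history
#'   (Gy), k = 1 relative uncertainties, per-batch sums, event counters
#'   and the energy-ledger diagnostic.
#' @export
run_simulation <- function(config, cells, model = NULL,
                           tables = load_xs_tables()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(model))
    model <- source_model(phantom_side_cm = config$phantom_side_cm,
                          phantom_medium = config$phantom_medium)
  cm <- as.matrix(cells[, c("r1", "r2", "z1", "z2")])
  regmat <- region_material_map(model$phantom_medium)
  w133 <- config$line_weights[2] / sum(config$line_weights)
  res <- cpp_run_simulation(
    geom_payload(model, config$point_source), table_payloads(tables),
    as.integer(regmat) - 1L, as.integer(regmat[["phantom"]]) - 1L,
    cm, config$histories, as.integer(config$batches), config$seed,
    config$cutoff_MeV, w133, config$vacuum_mode, config$primary_only)
  batch_sums <- res$batch_sums
  per_batch <- res$histories / config$batches
  batch_means <- batch_sums / per_batch
  kerma <- colMeans(batch_means)
  se <- apply(batch_means, 2, sd) / sqrt(config$batches)
  rel_unc <- ifelse(kerma > 0, se / kerma, NA_real_)
  structure(list(
    cells = cells, kerma_Gy_per_history = kerma,
    rel_uncertainty_k1 = rel_unc, batch_means = batch_means,
    histories = res$histories, batches = config$batches,
    counters = res$counters,
    max_energy_imbalance = res$max_energy_imbalance,
    config = config, model = model
  ), class = "mc_tallies")
}

#' @export
print.mc_tallies <- function(x, ...) {
  cat(sprintf("Monte Carlo tallies: %g histories in %d batches (seed %g)\n",
              x$histories, x$batches, x$config$seed))
  print(tally_table(x), row.names = FALSE)
  invisible(x)
}
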