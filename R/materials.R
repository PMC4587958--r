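# Embedded photon interaction coefficient tables for the four media of the
# source model: liquid water, humid air (TG-43U1 40% humidity), stainless
# steel AISI 316L, metallic cobalt.

INTERACTION_KINDS <- c("photoelectric", "compton", "rayleigh", "pair")

#' Define a transport medium
#'
#' @param name identifier string.
#' @param density mass density in g/cm^3; must be positive.
#' @param composition named numeric vector of elemental mass fractions;
#'   must sum to 1 within 1e-6.
#' @return An object of class `material`.
#' @export
material <- function(name, density, composition) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || density <= 0)
    stop("density must be positive (g/cm^3)")
  if (abs(sum(composition) - 1) > 1e-6)
    stop(sprintf("mass fractions for '%s' sum to %.8f, not 1", name,
                 sum(composition)))
  structure(list(name = name, density = density,
                 composition = composition),
            class = "material")
}

#' Default media of the source model
#'
#' Liquid water at 0.998 g/cm^3, air with the TG-43U1 40%-humidity
#' composition, AISI 316L stainless steel (Fe balance, Cr 0.17, Ni 0.12,
#' Mo 0.025, Mn 0.02, Si 0.01) and metallic cobalt.
#'
#' @return Named list of `material` objects: water, air, steel, cobalt.
#' @export
hdr_materials <- function() {
  list(
    water = material("water", 0.998,
                     c(H = 0.111898, O = 0.888102)),
    air = material("air", 1.196e-3,
                   c(H = 0.000732, C = 0.000123, N = 0.750325,
                     O = 0.236077, Ar = 0.012743)),
    steel = material("steel", 8.02,
                     c(Fe = 0.655, Cr = 0.17, Ni = 0.12, Mo = 0.025,
                       Mn = 0.02, Si = 0.01)),
    cobalt = material("cobalt", 8.9, c(Co = 1.0))
  )
}

#' Read an attenuation table from its plain-text fixture format
#'
#' The format is one table per material: `#` comment lines (the density is
#' parsed from a `# density_g_cm3 <x>` line), a header line with the column
#' names `energy_MeV mu_rho f_photo f_incoh f_coh f_pair mu_en_rho`, then
#' whitespace-separated numeric rows.
#'
#' @param file path to the table file.
#' @param material optional `material` object; when `NULL` a minimal one is
#'   reconstructed from the file header.
#' @return An object of class `attenuation_table`.
#' @export
read_xs_table <- function(file, material = NULL) {
  lines <- readLines(file)
  comments <- lines[startsWith(lines, "#")]
  if (is.null(material)) {
    dens_line <- grep("^# density_g_cm3 ", comments, value = TRUE)
    if (!length(dens_line))
      stop("no material given and no '# density_g_cm3' header in ", file)
    density <- as.numeric(sub("^# density_g_cm3 ", "", dens_line[1]))
    name <- sub("^# photon interaction coefficients: ", "",
                comments[1])
    comp_line <- grep("^# composition ", comments, value = TRUE)
    comp <- c(X = 1.0)
    if (length(comp_line)) {
      kv <- strsplit(strsplit(sub("^# composition ", "", comp_line[1]),
                              " ")[[1]], ":")
      comp <- setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                       vapply(kv, `[`, "", 1))
    }
    material <- material(name, density, comp)
  }
  df <- read.table(file, header = TRUE, comment.char = "#")
  attenuation_table(material, df)
}

#' Construct and validate an attenuation table
#'
#' @param material a `material` object.
#' @param data data frame with columns energy_MeV, mu_rho, f_photo,
#'   f_incoh, f_coh, f_pair, mu_en_rho.
#' @return An object of class `attenuation_table`.
#' @export
attenuation_table <- function(material, data) {
  need <- c("energy_MeV", "mu_rho", "f_photo", "f_incoh", "f_coh",
            "f_pair", "mu_en_rho")
  if (!all(need %in% names(data)))
    stop("table is missing columns: ",
         paste(setdiff(need, names(data)), collapse = ", "))
  E <- data$energy_MeV
  if (any(diff(E) <= 0)) stop("energy grid must be strictly increasing")
  if (E[1] > 0.010 + 1e-12 || E[length(E)] < 1.35 - 1e-12)
    stop("energy grid must span at least [0.010, 1.35] MeV")
  fsum <- data$f_photo + data$f_incoh + data$f_coh + data$f_pair
  if (any(abs(fsum - 1) > 1e-6))
    stop("branch fractions must sum to 1 at every grid point")
  if (any(data$f_pair[E < 1.022] > 0))
    stop("pair-production fraction must be 0 below 1.022 MeV")
  if (any(data$mu_en_rho > data$mu_rho + 1e-12))
    stop("mu_en/rho must not exceed mu/rho")
  if (any(data$mu_rho <= 0) || any(data$mu_en_rho <= 0))
    stop("all coefficients must be strictly positive")
  structure(c(list(material = material, density = material$density),
              as.list(data)),
            class = "attenuation_table")
}

#' Write an attenuation table in the plain-text fixture format
#'
#' Values are written with 17 significant digits so that a read/write
#' round trip is bit-exact.
#'
#' @param table an `attenuation_table`.
#' @param file output path.
#' @export
write_xs_table <- function(table, file) {
  m <- table$material
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# photon interaction coefficients: %s", m$name), con)
  writeLines(sprintf("# density_g_cm3 %.17g", m$density), con)
  writeLines(paste0("# composition ",
                    paste(sprintf("%s:%.17g", names(m$composition),
                                  m$composition), collapse = " ")), con)
  writeLines("energy_MeV mu_rho f_photo f_incoh f_coh f_pair mu_en_rho",
             con)
  rows <- sprintf("%.17g %.17g %.17g %.17g %.17g %.17g %.17g",
                  table$energy_MeV, table$mu_rho, table$f_photo,
                  table$f_incoh, table$f_coh, table$f_pair,
                  table$mu_en_rho)
  writeLines(rows, con)
}

#' Load the bundled attenuation tables
#'
#' @param dir directory holding the per-material table files; defaults to
#'   the tables shipped with the package.
#' @return Named list of `attenuation_table` objects (water, air, steel,
#'   cobalt).
#' @export
load_xs_tables <- function(dir = system.file("extdata", "xs",
                                             package = "cobrachy")) {
  mats <- hdr_materials()
  tabs <- lapply(names(mats), function(nm) {
    read_xs_table(file.path(dir, paste0(nm, ".txt")), mats[[nm]])
  })
  setNames(tabs, names(mats))
}

check_energy_range <- function(table, energy) {
  E <- table$energy_MeV
  bad <- energy < E[1] - 1e-12 | energy > E[length(E)] + 1e-12
  if (any(bad))
    stop(sprintf("energy %g MeV outside table range [%g, %g] for %s",
                 energy[which(bad)[1]], E[1], E[length(E)],
                 table$material$name))
}

#' Mass attenuation coefficient at arbitrary energy
#'
#' Log-log linear interpolation between bracketing grid points; exact at
#' grid points.
#'
#' @param table an `attenuation_table`.
#' @param energy photon energy (MeV), scalar or vector, within the grid.
#' @return mu/rho in cm^2/g.
#' @export
lookup_mu <- function(table, energy) {
  check_energy_range(table, energy)
  cpp_lookup(table, energy, 0L)
}

#' Mass energy-absorption coefficient at arbitrary energy
#'
#' @inheritParams lookup_mu
#' @return mu_en/rho in cm^2/g.
#' @export
lookup_mu_en <- function(table, energy) {
  check_energy_range(table, energy)
  cpp_lookup(table, energy, 1L)
}

#' Interaction branch fractions at arbitrary energy
#'
#' Fractions of the total cross section for photoelectric, incoherent
#' (Compton), coherent (Rayleigh) and pair production, interpolated
#' linearly in log-energy and renormalized to unit sum. The pair fraction
#' is forced to zero below the 1.022 MeV threshold.
#'
#' @inheritParams lookup_mu
#' @return Named numeric vector of four fractions.
#' @export
branch_fractions <- function(table, energy) {
  check_energy_range(table, energy)
  setNames(cpp_branch_fractions(table, energy), INTERACTION_KINDS)
}

#' Sample an interaction kind by inverse CDF
#'
#' The cumulative ordering is photoelectric, compton, rayleigh, pair; a
#' uniform deviate of 0 therefore always selects photoelectric.
#'
#' @inheritParams lookup_mu
#' @param u uniform random deviates in `[0, 1)`.
#' @return Character vector of interaction kinds.
#' @export
sample_interaction <- function(table, energy, u) {
  check_energy_range(table, energy)
  stopifnot(all(u >= 0), all(u < 1))
  INTERACTION_KINDS[cpp_sample_interaction(table, energy, u)]
}
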