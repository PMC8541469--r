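#' Axis-aligned cylinder for phantoms and sources
#'
#' @param center length-3 center (mm).
#' @param radius cylinder radius (mm).
#' @param half_height half of the cylinder height (mm).
#' @param material `"water"` or `"air"`.
#' @export
cylinder <- function(center = c(0, 0, 0), radius, half_height,
                     material = c("water", "air")) {
  material <- match.arg(material)
  stopifnot(length(center) == 3, radius >= 0, half_height >= 0)
  structure(list(center = as.numeric(center), radius = radius,
                 half_height = half_height, material = material),
            class = "pet_cylinder")
}

#' Phantom: an ordered list of cylinders
#'
#' Overlaps are resolved by list order: later entries override earlier ones,
#' so an air cylinder listed after a water cylinder carves a cold/air insert.
#'
#' @param ... [cylinder()] objects (or a single list of them).
#' @export
phantom <- function(...) {
  cyls <- list(...)
  if (length(cyls) == 1 && !inherits(cyls[[1]], "pet_cylinder")) cyls <- cyls[[1]]
  stopifnot(all(vapply(cyls, inherits, TRUE, "pet_cylinder")))
  structure(list(cylinders = cyls), class = "pet_phantom")
}

phantom_matrix <- function(ph) {
  if (!length(ph$cylinders)) return(matrix(0, 0, 6))
  do.call(rbind, lapply(ph$cylinders, function(c) {
    c(c$center, c$radius, c$half_height, if (c$material == "water") 1 else 0)
  }))
}

#' One component of an activity distribution
#'
#' Lines are thin cylinders; decays are sampled uniformly inside the shape,
#' rejecting points that fall in any `exclude` cylinder (used to carve cold
#' rods out of a background compartment). Sampling probabilities across
#' components are proportional to `activity`.
#'
#' @param shape `"cylinder"` or `"line"` (a line is stored as a cylinder).
#' @param center length-3 center (mm).
#' @param radius radius (mm); for a line, its half-thickness.
#' @param half_height half-height (mm).
#' @param activity non-negative relative activity (arbitrary units).
#' @param exclude list of [cylinder()] regions to carve out.
#' @export
source_component <- function(shape = c("cylinder", "line"), center = c(0, 0, 0),
                             radius, half_height, activity = 1,
                             exclude = list()) {
  shape <- match.arg(shape)
  stopifnot(activity >= 0, radius >= 0, half_height >= 0)
  structure(list(shape = shape, center = as.numeric(center), radius = radius,
                 half_height = half_height, activity = activity,
                 exclude = exclude),
            class = "pet_source_component")
}

#' Activity distribution made of several components
#' @param ... [source_component()] objects (or a single list of them).
#' @export
source_distribution <- function(...) {
  comps <- list(...)
  if (length(comps) == 1 && !inherits(comps[[1]], "pet_source_component"))
    comps <- comps[[1]]
  stopifnot(length(comps) > 0,
            all(vapply(comps, inherits, TRUE, "pet_source_component")))
  structure(list(components = comps), class = "pet_source")
}

source_matrix <- function(src) {
  do.call(rbind, lapply(src$components, function(c) {
    c(c$center, c$radius, c$half_height, c$activity)
  }))
}

source_exclusions <- function(src) {
  lapply(src$components, function(c) {
    if (!length(c$exclude)) return(matrix(0, 0, 5))
    do.call(rbind, lapply(c$exclude, function(e) {
      c(e$center, e$radius, e$half_height)
    }))
  })
}

#' Photon interaction coefficients in water
#'
#' Linear attenuation coefficients (mm^-1) over an energy grid: the Compton
#' part is the water electron density times the analytically integrated total
#' Klein-Nishina cross-section; the photoelectric remainder is an `E^-3` fit,
#' negligible above 350 keV but relevant for terminating low-energy tracked
#' photons.
#'
#' @param energies energy grid in keV (default 50-700).
#' @return a data.frame with columns `energy_keV`, `mu_compton`,
#'   `mu_photoelectric`, `mu_total`.
#' @export
physics_tables <- function(energies = seq(50, 700, by = 5)) {
  stopifnot(all(energies > 0))
  m <- cpp_mu_water(as.numeric(energies))
  data.frame(energy_keV = energies, mu_compton = m[, 1],
             mu_photoelectric = m[, 2], mu_total = m[, 3])
}

#' Compton scattered-photon energy
#'
#' `E' = E / (1 + (E/511)(1 - cos(theta)))`.
#'
#' @param energy incident photon energy (keV).
#' @param theta scattering angle (rad).
#' @export
compton_energy <- function(energy, theta) {
  stopifnot(all(energy > 0))
  cpp_compton_energy(as.numeric(energy), as.numeric(theta))
}

#' Sample Compton scattering angles from the Klein-Nishina cross-section
#'
#' Rejection sampling against the differential cross-section, distributed as
#' `dsigma/dOmega * sin(theta)`. Uses R's RNG (seed with [set.seed()]).
#'
#' @param energy incident photon energy (keV), scalar.
#' @param n number of samples.
#' @return scattering angles in radians.
#' @export
sample_klein_nishina <- function(energy, n) {
  stopifnot(energy > 0, n >= 0)
  cpp_sample_kn(energy, as.integer(n))
}

world_bounds <- function(ph, src = NULL) {
  r <- 1; z <- 1
  for (c in ph$cylinders) {
    r <- max(r, sqrt(sum(c$center[1:2]^2)) + c$radius)
    z <- max(z, abs(c$center[3]) + c$half_height)
  }
  if (!is.null(src)) {
    for (c in src$components) {
      r <- max(r, sqrt(sum(c$center[1:2]^2)) + c$radius)
      z <- max(z, abs(c$center[3]) + c$half_height)
    }
  }
  list(radius = r, half_height = z)
}

#' Transport photons through a phantom
#'
#' Tracks `n` photons launched from one origin and direction through the
#' phantom with Compton (Klein-Nishina) scattering and photoelectric
#' absorption, using delta tracking with the water attenuation as majorant.
#' Tracking stops on absorption, on falling below `cutoff` keV, or on leaving
#' the phantom bounding volume.
#'
#' @param phantom a [phantom()].
#' @param origin,direction length-3 vectors (direction need not be normalized).
#' @param energy initial energy (keV).
#' @param n number of independent photons.
#' @param cutoff tracking cutoff energy (keV).
#' @return a data.frame with columns `alive` (FALSE = absorbed), `x, y, z`
#'   (last in-phantom point), `dx, dy, dz`, `energy` and `nscat`.
#' @export
transport_photon <- function(phantom, origin, direction, energy = 511, n = 1,
                             cutoff = 50) {
  stopifnot(length(origin) == 3, length(direction) == 3, energy > 0)
  d <- direction / sqrt(sum(direction^2))
  w <- world_bounds(phantom)
  m <- cpp_transport_pencil(as.numeric(origin), as.numeric(d), energy,
                            phantom_matrix(phantom), w$radius, w$half_height,
                            cutoff, as.integer(n))
  out <- as.data.frame(m)
  names(out) <- c("alive", "x", "y", "z", "dx", "dy", "dz", "energy", "nscat")
  out$alive <- as.logical(out$alive)
  out$nscat <- as.integer(out$nscat)
  out
}

#' Simulate a PET acquisition
#'
#' For each decay an emission point is drawn from the activity distribution
#' and a back-to-back 511 keV photon pair is emitted isotropically (photon
#' acollinearity and positron range are neglected, both below the virtual
#' pixel scale). Both photons are transported through the phantom; survivors
#' are intersected with the detector ring (detection = crossing a block's
#' inner face). Deposited energies are the arrival energies blurred with a
#' Gaussian of FWHM `energy_resolution * 511 * sqrt(E/511)` keV, and a
#' coincidence is kept iff both photons land on an allowed block pair with
#' blurred energies inside the acceptance window. Ground-truth labels
#' (per-photon phantom-scatter multiplicity, pre-blur energy, annihilation z)
#' are recorded for every accepted event.
#'
#' Randomness goes through R's RNG: pass `seed` or call [set.seed()] yourself.
#' Exactly one of `n_decays` (fixed decay budget) and `min_accepted`
#' (simulate in chunks until at least this many coincidences are accepted)
#' must be given.
#'
#' @param phantom a [phantom()].
#' @param source a [source_distribution()] (or single [source_component()]).
#' @param geometry a [scanner_geometry()].
#' @param n_decays number of decays to simulate.
#' @param min_accepted target number of accepted coincidences.
#' @param seed optional integer seed.
#' @param cutoff tracking cutoff (keV).
#' @param chunk_size decays per chunk in `min_accepted` mode.
#' @return a [listmode_set()] with truth labels; acquisition counters, the
#'   per-component decay tallies and all parameters are in `$provenance`.
#' @export
simulate_acquisition <- function(phantom, source, geometry, n_decays = NULL,
                                 min_accepted = NULL, seed = NULL,
                                 cutoff = 50, chunk_size = 2e5) {
  if (inherits(source, "pet_source_component")) source <- source_distribution(source)
  if (is.null(n_decays) == is.null(min_accepted))
    stop("give exactly one of n_decays and min_accepted")
  if (!is.null(seed)) set.seed(seed)
  w <- world_bounds(phantom, source)
  if (w$radius >= geometry$apothem)
    stop("phantom/source world radius must be smaller than the detector apothem")
  smat <- source_matrix(source)
  sexc <- source_exclusions(source)
  pmat <- phantom_matrix(phantom)
  run <- function(nd, t0) {
    cpp_simulate(nd, smat, sexc, pmat, geometry$n_blocks, geometry$apothem,
                 geometry$block_width / 2, geometry$block_height / 2,
                 geometry$block_depth, geometry$energy_resolution,
                 geometry$acceptance_window[1], geometry$acceptance_window[2],
                 geometry$min_block_sep, cutoff, w$radius, w$half_height, t0)
  }
  chunks <- list()
  counters <- NULL
  comp_decays <- numeric(nrow(smat))
  done <- 0
  accepted <- 0
  if (sum(smat[, 6]) <= 0) {
    n_decays <- 0  # zero-activity source: empty acquisition
    min_accepted <- NULL
  }
  repeat {
    nd <- if (!is.null(n_decays)) n_decays - done
          else {
            rate <- if (done > 0) max(accepted / done, 1e-6) else NA
            if (is.na(rate)) chunk_size
            else min(5e6, ceiling(1.15 * (min_accepted - accepted) / rate))
          }
    if (nd <= 0 && is.null(n_decays)) nd <- chunk_size
    if (!is.null(n_decays) && nd <= 0) break
    res <- run(nd, done)
    chunks[[length(chunks) + 1]] <- res$events
    accepted <- accepted + nrow(res$events)
    done <- done + nd
    comp_decays <- comp_decays + res$component_decays
    counters <- if (is.null(counters)) res$counters else counters + res$counters
    if (!is.null(n_decays)) break
    if (accepted >= min_accepted) break
    if (done > 5e9) stop("simulation did not reach min_accepted within 5e9 decays")
  }
  m <- if (length(chunks)) do.call(rbind, chunks) else matrix(0, 0, 17)
  if (is.null(counters))
    counters <- setNames(numeric(6), c("emitted", "both_exited", "both_hit",
                                       "same_block", "pair_rejected",
                                       "window_rejected"))
  ev <- data.table::data.table(
    block1 = as.integer(m[, 1]), u1 = m[, 2], v1 = m[, 3], doi1 = m[, 4],
    e1 = m[, 5], e_true1 = m[, 6], nscat1 = as.integer(m[, 7]),
    block2 = as.integer(m[, 8]), u2 = m[, 9], v2 = m[, 10], doi2 = m[, 11],
    e2 = m[, 12], e_true2 = m[, 13], nscat2 = as.integer(m[, 14]),
    origin_z = m[, 15], source_id = as.integer(m[, 16]), t = m[, 17])
  ev$scatter1 <- ev$nscat1 > 0
  ev$scatter2 <- ev$nscat2 > 0
  ev$origin_in_fov <- abs(ev$origin_z) <= geometry$axial_fov / 2
  listmode_set(ev, geometry, provenance = list(
    n_decays = done, counters = as.list(counters),
    component_decays = comp_decays, seed = seed, cutoff = cutoff,
    phantom = phantom, source = source))
}

# ---- fixture phantoms matching the validation setups -----------------------

#' Water cylinder with a central line source
#'
#' 60 mm tall water cylinder of the given radius with a 5 mm diameter x 60 mm
#' axial line source at its center; the calibration/validation workhorse.
#'
#' @param radius cylinder radius, mm (40-160 studied).
#' @export
fixture_cylinder <- function(radius) {
  stopifnot(radius > 0)
  list(phantom = phantom(cylinder(c(0, 0, 0), radius, 30, "water")),
       source = source_distribution(
         source_component("line", c(0, 0, 0), 2.5, 30, activity = 1)))
}

#' Out-of-FOV fixture: source and phantom taller than the axial FOV
#'
#' A 25 mm radius x 160 mm tall uniform cylindrical source inside a 120 mm
#' radius x 160 mm tall water cylinder; roughly a third of the detected
#' scattered coincidences originate outside the 60 mm axial FOV.
#' @export
fixture_out_of_fov <- function() {
  list(phantom = phantom(cylinder(c(0, 0, 0), 120, 80, "water")),
       source = source_distribution(
         source_component("cylinder", c(0, 0, 0), 25, 80, activity = 1)))
}

#' Utah-style contrast phantom
#'
#' External water cylinder (100 mm radius x 50 mm height) with two 25 mm
#' radius rods offset 35 mm from the center: one cold (no activity), one hot
#' with a 10:1 activity concentration relative to the background compartment.
#' @export
fixture_utah <- function() {
  hot <- cylinder(c(35, 0, 0), 25, 25, "water")
  cold <- cylinder(c(-35, 0, 0), 25, 25, "water")
  bg_vol <- pi * 100^2 * 50 - 2 * pi * 25^2 * 50
  hot_vol <- pi * 25^2 * 50
  list(phantom = phantom(cylinder(c(0, 0, 0), 100, 25, "water")),
       source = source_distribution(
         source_component("cylinder", c(0, 0, 0), 100, 25,
                          activity = 1 * bg_vol,
                          exclude = list(hot, cold)),
         source_component("cylinder", c(35, 0, 0), 25, 25,
                          activity = 10 * hot_vol)),
       hot_center = c(35, 0, 0), cold_center = c(-35, 0, 0), rod_radius = 25)
}
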