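#' Scanner geometry: a single ring of monolithic detector blocks
#'
#' Models a dedicated-brain-PET style ring of `n_blocks` monolithic crystal
#' blocks placed as a regular polygon around the scanner axis (the z axis).
#' Block `k`'s inner face center sits at azimuth `2*pi*k/n_blocks`, at
#' perpendicular distance `apothem` from the axis. Local face coordinates are
#' `u` (tangential, transaxial) and `v` (axial), both centered on the face;
#' depth of interaction (`doi`) is measured inward from the inner face.
#'
#' The default 20-gon of 50 mm faces has a polygon apothem of about 157.8 mm,
#' which is geometrically in tension with the nominal 330 mm transaxial FOV;
#' the inner-face distance is therefore configurable and defaults to 165 mm
#' (implying small inter-block gaps) so that the stated FOV is the operative
#' quantity for phantom coverage.
#'
#' @param n_blocks number of detector blocks (>= 3).
#' @param block_width,block_height,block_depth block dimensions in mm
#'   (tangential x axial x radial).
#' @param apothem perpendicular distance from the axis to each inner face (mm).
#' @param axial_fov,transaxial_fov nominal fields of view (mm); the axial FOV
#'   bounds the "in-FOV" truth label for annihilation origins.
#' @param energy_resolution fractional energy resolution (FWHM/centroid) at
#'   511 keV.
#' @param acceptance_window two keV values, the hardware energy cut applied to
#'   every detected photon.
#' @param min_block_sep minimum circular block separation for an accepted
#'   coincidence pair; the default 5 (of 20) excludes pairs that cannot see
#'   the transaxial FOV.
#' @return an object of class `scanner_geometry`.
#' @export
scanner_geometry <- function(n_blocks = 20L, block_width = 50, block_height = 50,
                             block_depth = 20, apothem = 165, axial_fov = 60,
                             transaxial_fov = 330, energy_resolution = 0.10,
                             acceptance_window = c(350, 650),
                             min_block_sep = 5L) {
  stopifnot(n_blocks >= 3, block_width > 0, block_height > 0, block_depth > 0,
            apothem > 0, axial_fov > 0, transaxial_fov > 0,
            energy_resolution > 0, energy_resolution < 1,
            length(acceptance_window) == 2,
            acceptance_window[1] < acceptance_window[2],
            min_block_sep >= 1)
  g <- list(n_blocks = as.integer(n_blocks), block_width = block_width,
            block_height = block_height, block_depth = block_depth,
            apothem = apothem, axial_fov = axial_fov,
            transaxial_fov = transaxial_fov,
            energy_resolution = energy_resolution,
            acceptance_window = as.numeric(acceptance_window),
            min_block_sep = as.integer(min_block_sep))
  class(g) <- "scanner_geometry"
  g
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf("<scanner_geometry> %d blocks of %g x %g x %g mm, apothem %g mm\n",
              x$n_blocks, x$block_width, x$block_height, x$block_depth,
              x$apothem))
  cat(sprintf("  axial FOV %g mm, transaxial FOV %g mm, %g%% FWHM at 511 keV, window [%g, %g] keV\n",
              x$axial_fov, x$transaxial_fov, 100 * x$energy_resolution,
              x$acceptance_window[1], x$acceptance_window[2]))
  invisible(x)
}

block_azimuth <- function(geom, block) 2 * pi * block / geom$n_blocks

#' Convert block-local coordinates to the lab frame
#'
#' @param geom a [scanner_geometry()].
#' @param block block id(s), 0-based.
#' @param u,v face-local coordinates (mm); `u` tangential, `v` axial.
#' @param doi depth of interaction inward from the inner face (mm).
#' @return an n x 3 matrix of lab-frame points (mm).
#' @export
local_to_global <- function(geom, block, u, v, doi = 0) {
  n <- max(length(block), length(u), length(v), length(doi))
  block <- rep_len(as.integer(block), n); u <- rep_len(u, n)
  v <- rep_len(v, n); doi <- rep_len(doi, n)
  bad <- abs(u) > geom$block_width / 2 + 1e-9 |
    abs(v) > geom$block_height / 2 + 1e-9 | doi < -1e-9 |
    doi > geom$block_depth + 1e-9 | block < 0 | block >= geom$n_blocks
  if (any(bad)) {
    stop(sprintf("%d local coordinate(s) outside the block face/depth extents (first bad index %d)",
                 sum(bad), which(bad)[1]))
  }
  phi <- block_azimuth(geom, block)
  r <- geom$apothem + doi
  cbind(x = r * cos(phi) - u * sin(phi),
        y = r * sin(phi) + u * cos(phi),
        z = v)
}

#' Convert lab-frame points to block-local coordinates
#'
#' The block is chosen as the one whose azimuthal sector contains the point.
#'
#' @param geom a [scanner_geometry()].
#' @param points n x 3 matrix of lab-frame points (mm).
#' @return a data.frame with columns `block`, `u`, `v`, `doi`.
#' @export
global_to_local <- function(geom, points) {
  points <- rbind(points)
  phi <- atan2(points[, 2], points[, 1])
  k <- as.integer(round(phi / (2 * pi / geom$n_blocks))) %% geom$n_blocks
  bphi <- block_azimuth(geom, k)
  data.frame(
    block = k,
    u = -points[, 1] * sin(bphi) + points[, 2] * cos(bphi),
    v = points[, 3],
    doi = points[, 1] * cos(bphi) + points[, 2] * sin(bphi) - geom$apothem)
}

#' Is a block pair allowed to form coincidences?
#'
#' True iff the circular separation `min(|a - b|, n_blocks - |a - b|)` is at
#' least `min_sep`.
#'
#' @param geom a [scanner_geometry()].
#' @param block_a,block_b block ids (0-based), vectorized.
#' @param min_sep minimum circular separation; defaults to the geometry's.
#' @export
allowed_pair <- function(geom, block_a, block_b, min_sep = geom$min_block_sep) {
  stopifnot(all(block_a >= 0), all(block_a < geom$n_blocks),
            all(block_b >= 0), all(block_b < geom$n_blocks))
  d <- abs(block_a - block_b)
  pmin(d, geom$n_blocks - d) >= min_sep
}

#' Enumerate allowed block pairs in canonical order (block_a < block_b)
#' @param geom a [scanner_geometry()].
#' @return a 2-column integer matrix of 0-based block ids.
#' @export
allowed_pairs <- function(geom) {
  cmb <- t(utils::combn(geom$n_blocks, 2L)) - 1L
  cmb[allowed_pair(geom, cmb[, 1], cmb[, 2]), , drop = FALSE]
}

#' Virtual pixel grid on the block faces
#'
#' Discretizes each block face into virtual pixels of the requested pitch
#' (half-open intervals, 0-based indices, `u`-major flat pixel index
#' `iu * n_v + iv`). Pitches of 1.4-2 mm match the resolution regime this
#' binning is intended for; coarser pitches are accepted for fast exploratory
#' reconstructions.
#'
#' @param geom a [scanner_geometry()].
#' @param pixel_pitch pixel pitch in mm.
#' @return an object of class `virtual_pixel_grid`.
#' @export
virtual_pixel_grid <- function(geom, pixel_pitch = 2) {
  stopifnot(pixel_pitch > 0)
  n_u <- max(1L, as.integer(floor(geom$block_width / pixel_pitch)))
  n_v <- max(1L, as.integer(floor(geom$block_height / pixel_pitch)))
  pairs <- allowed_pairs(geom)
  lookup <- rep(NA_integer_, geom$n_blocks^2)
  lookup[pairs[, 1] * geom$n_blocks + pairs[, 2] + 1L] <- seq_len(nrow(pairs)) - 1L
  grid <- list(
    geometry = geom, pitch = pixel_pitch, n_u = n_u, n_v = n_v,
    n_pixels = n_u * n_v,
    u_centers = -geom$block_width / 2 + (seq_len(n_u) - 0.5) * pixel_pitch,
    v_centers = -geom$block_height / 2 + (seq_len(n_v) - 0.5) * pixel_pitch,
    pairs = pairs, pair_lookup = lookup)
  class(grid) <- "virtual_pixel_grid"
  grid
}

#' @export
print.virtual_pixel_grid <- function(x, ...) {
  cat(sprintf("<virtual_pixel_grid> pitch %g mm, %d x %d pixels/face, %d allowed block pairs, %.0f LOR bins\n",
              x$pitch, x$n_u, x$n_v, nrow(x$pairs), n_lor_bins(x)))
  invisible(x)
}

#' Total number of distinct LOR bins
#' @param grid a [virtual_pixel_grid()].
#' @export
n_lor_bins <- function(grid) nrow(grid$pairs) * (grid$n_pixels)^2

pixel_index_1d <- function(x, half_extent, pitch, n) {
  pmin(n - 1L, pmax(0L, as.integer(floor((x + half_extent) / pitch))))
}

#' Assign coincidence events to canonical LOR bins
#'
#' Each event's two photon impacts are ordered canonically (lower block id
#' first), mapped to virtual pixels (half-open intervals; the face's upper
#' edge falls into the last pixel), and combined into a unique LOR-bin id.
#' Events whose photons land on the same block or on a disallowed pair are
#' flagged with `NA` bins; their count is exposed as `attr(, "n_rejected")`.
#'
#' @param set a [listmode_set()] (or bare events data.frame).
#' @param grid a [virtual_pixel_grid()].
#' @return a `data.table` with the canonical per-event columns `block_a`,
#'   `block_b`, `ua`, `va`, `ub`, `vb` (mm), `pa`, `pb` (flat pixel indices),
#'   `pair` (0-based allowed-pair index) and `bin` (0-based LOR-bin id),
#'   row-aligned with the input events.
#' @export
bin_events <- function(set, grid) {
  ev <- if (inherits(set, "listmode_set")) set$events else set
  geom <- grid$geometry
  swap <- ev$block1 > ev$block2
  block_a <- ifelse(swap, ev$block2, ev$block1)
  block_b <- ifelse(swap, ev$block1, ev$block2)
  ua <- ifelse(swap, ev$u2, ev$u1); va <- ifelse(swap, ev$v2, ev$v1)
  ub <- ifelse(swap, ev$u1, ev$u2); vb <- ifelse(swap, ev$v1, ev$v2)
  iu_a <- pixel_index_1d(ua, geom$block_width / 2, grid$pitch, grid$n_u)
  iv_a <- pixel_index_1d(va, geom$block_height / 2, grid$pitch, grid$n_v)
  iu_b <- pixel_index_1d(ub, geom$block_width / 2, grid$pitch, grid$n_u)
  iv_b <- pixel_index_1d(vb, geom$block_height / 2, grid$pitch, grid$n_v)
  pa <- iu_a * grid$n_v + iv_a
  pb <- iu_b * grid$n_v + iv_b
  pair <- grid$pair_lookup[block_a * geom$n_blocks + block_b + 1L]
  pair[block_a == block_b] <- NA_integer_
  P <- grid$n_pixels
  bin <- (as.numeric(pair) * P + pa) * P + pb
  out <- data.table::data.table(block_a = as.integer(block_a),
                                block_b = as.integer(block_b),
                                ua = ua, va = va, ub = ub, vb = vb,
                                pa = as.integer(pa), pb = as.integer(pb),
                                pair = as.integer(pair), bin = bin)
  data.table::setattr(out, "n_rejected", sum(is.na(pair)))
  out
}

#' Lab-frame endpoints of a LOR bin's center line
#'
#' @param grid a [virtual_pixel_grid()].
#' @param pair 0-based allowed-pair indices.
#' @param pa,pb flat pixel indices on the two faces.
#' @return an n x 6 matrix `(x1, y1, z1, x2, y2, z2)`.
#' @export
bin_endpoints <- function(grid, pair, pa, pb) {
  geom <- grid$geometry
  ka <- grid$pairs[pair + 1L, 1L]; kb <- grid$pairs[pair + 1L, 2L]
  ua <- grid$u_centers[pa %/% grid$n_v + 1L]
  va <- grid$v_centers[pa %% grid$n_v + 1L]
  ub <- grid$u_centers[pb %/% grid$n_v + 1L]
  vb <- grid$v_centers[pb %% grid$n_v + 1L]
  cbind(local_to_global(geom, ka, ua, va),
        local_to_global(geom, kb, ub, vb))
}

#' Stable content hash of a scanner geometry
#'
#' FNV-1a hash over the canonical parameter string; used for provenance in
#' file headers and for keying cached sensitivity images.
#' @param geom a [scanner_geometry()].
#' @return an 8-hex-digit string.
#' @export
geometry_hash <- function(geom) {
  s <- paste(geom$n_blocks, geom$block_width, geom$block_height,
             geom$block_depth, geom$apothem, geom$axial_fov,
             geom$transaxial_fov, geom$energy_resolution,
             geom$acceptance_window[1], geom$acceptance_window[2],
             geom$min_block_sep, sep = "|")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h a double in [0, 2^32)
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime, split to stay within 2^53
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
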