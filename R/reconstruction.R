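#' Image volume container
#'
#' A regular voxel grid centered on the scanner axis unless an origin is
#' given. Values are activity estimates (arbitrary units), non-negative at
#' every EM iteration.
#'
#' @param dim length-3 integer voxel counts `(nx, ny, nz)`.
#' @param voxel_size cubic voxel edge (mm); the validation studies use 1-2 mm.
#' @param origin lab-frame corner of voxel (0,0,0); defaults to centering the
#'   volume on the origin.
#' @param values optional initial voxel values (default 0).
#' @export
image_volume <- function(dim, voxel_size, origin = NULL, values = 0) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1), voxel_size > 0)
  if (is.null(origin)) origin <- -dim * voxel_size / 2
  vol <- list(dim = dim, voxel_size = voxel_size, origin = as.numeric(origin),
              values = array(values, dim = dim))
  class(vol) <- "image_volume"
  vol
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %d x %d x %d voxels of %g mm, total %.4g\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_size, sum(x$values)))
  invisible(x)
}

#' Voxel center coordinates of a volume
#' @param vol an [image_volume()].
#' @return an nvox x 3 matrix, in array order (x fastest).
#' @export
voxel_centers <- function(vol) {
  gx <- vol$origin[1] + (seq_len(vol$dim[1]) - 0.5) * vol$voxel_size
  gy <- vol$origin[2] + (seq_len(vol$dim[2]) - 0.5) * vol$voxel_size
  gz <- vol$origin[3] + (seq_len(vol$dim[3]) - 0.5) * vol$voxel_size
  cbind(x = rep(gx, times = vol$dim[2] * vol$dim[3]),
        y = rep(rep(gy, each = vol$dim[1]), times = vol$dim[3]),
        z = rep(gz, each = vol$dim[1] * vol$dim[2]))
}

#' Ray-voxel intersection lengths of one LOR
#'
#' Exact intersection lengths (Siddon-style incremental traversal) of the
#' segment `p1`-`p2` with the voxel grid; the system-matrix row `a_ij`.
#'
#' @param p1,p2 length-3 endpoints (mm).
#' @param vol an [image_volume()].
#' @return a list with `index` (1-based voxel linear indices), `length` (mm)
#'   and `chord` (total chord length through the volume; equals
#'   `sum(length)`).
#' @export
project_lor <- function(p1, p2, vol) {
  cpp_project(as.numeric(p1), as.numeric(p2), vol$dim, vol$origin,
              vol$voxel_size)
}

subset_of_pairs <- function(n_pairs, n_subsets) {
  as.integer(seq_len(n_pairs) - 1L) %% n_subsets  # angular round-robin
}

#' Sensitivity image over all allowed bin-level LORs
#'
#' Per-voxel sum of `a_ij` over the full system LOR set (every virtual-pixel
#' pair of every allowed block pair), the EM denominator. Computed once per
#' (geometry, grid, volume, subsets) combination and memoized in the package
#' cache. For `n_subsets > 1` the columns hold the per-subset sensitivities
#' under the block-pair round-robin rule; rows sum to the full sensitivity.
#'
#' @param grid a [virtual_pixel_grid()].
#' @param vol an [image_volume()].
#' @param n_subsets number of ordered subsets.
#' @param cache memoize (keyed by geometry hash, pitch, volume, subsets).
#' @return an `nvox x n_subsets` matrix.
#' @export
sensitivity_image <- function(grid, vol, n_subsets = 1, cache = TRUE) {
  if (nrow(grid$pairs) == 0) stop("geometry has no allowed block pairs")
  key <- paste(geometry_hash(grid$geometry), grid$pitch,
               paste(vol$dim, collapse = "x"), vol$voxel_size,
               paste(sprintf("%.6g", vol$origin), collapse = ","),
               n_subsets, sep = "|")
  if (cache && !is.null(.petscatter_cache[[key]]))
    return(.petscatter_cache[[key]])
  sens <- cpp_sensitivity(grid$pairs, subset_of_pairs(nrow(grid$pairs), n_subsets),
                          as.integer(n_subsets), grid$geometry$n_blocks,
                          grid$geometry$apothem, grid$u_centers, grid$v_centers,
                          vol$dim, vol$origin, vol$voxel_size)
  if (cache) .petscatter_cache[[key]] <- sens
  sens
}

# Per-event additive scatter term: SF is looked up on the scatter map's own
# binning grid (which may be coarser than the reconstruction grid, so the
# per-bin fractions carry usable statistics), while the magnitude is the raw
# event count of the event's reconstruction-grid bin, keeping the EM fixed
# point forward + S = measured counts per reconstructed LOR bin.
prepare_recon_events <- function(set, grid, scatter_map = NULL) {
  bins <- bin_events(set, grid)
  keep <- !is.na(bins$pair)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning(sprintf("%d event(s) on disallowed pairs dropped from reconstruction",
                    n_dropped))
  bins <- bins[keep]
  ep <- bin_endpoints(grid, bins$pair, bins$pa, bins$pb)
  S <- rep(0, nrow(bins))
  if (!is.null(scatter_map)) {
    sgrid <- attr(scatter_map, "grid") %||% grid
    sbins <- if (identical(sgrid$pitch, grid$pitch)) bins
             else bin_events(set, sgrid)[keep]
    sf_ev <- scatter_map$sf[match(sbins$bin, scatter_map$bin)]
    sf_ev[is.na(sf_ev)] <- 0
    bins[, m_fine := .N, by = bin]
    S <- sf_ev * bins$m_fine
  }
  list(ep = ep, S = S, pair = bins$pair, bin = bins$bin)
}

#' List-mode OSEM reconstruction with an additive scatter term
#'
#' Ordered-subsets EM over bin-level LORs:
#' `n_j^(k+1) = n_j^k / sum_(i in I_s) a_ij * sum_(i in M_s) a_ij / (sum_j a_ij n_j^k + S_i)`
#' with the additive scatter estimate `S_i` inside the forward model, subset
#' sensitivities in the denominator, and events assigned to subsets by the
#' block-pair round-robin rule (or by event index, with the total sensitivity
#' split evenly). One subset reproduces MLEM exactly. Voxel values stay
#' non-negative; voxels the system never sees (zero sensitivity) are masked
#' and returned as zero.
#'
#' @param set a [listmode_set()] (all accepted events are reconstructed).
#' @param grid a [virtual_pixel_grid()].
#' @param vol an [image_volume()] defining the output grid.
#' @param scatter_map optional [scatter_fraction_map()]; omitting it (or
#'   `NULL`) reconstructs without scatter correction (`S = 0`).
#' @param n_iter full iterations (default 4, the validation setting).
#' @param n_subsets ordered subsets (default 3).
#' @param subset_rule `"pair"` (angular round-robin over block pairs) or
#'   `"index"` (event index modulo subsets).
#' @param initial positive initial voxel value.
#' @param eps denominator floor.
#' @param sens optional precomputed sensitivity matrix (tests; overrides the
#'   cache).
#' @return a list: `image` (an [image_volume()]), `loglik` (list-mode Poisson
#'   log-likelihood, up to a constant, after each full iteration), `S_total`.
#' @export
reconstruct_osem <- function(set, grid, vol, scatter_map = NULL, n_iter = 4,
                             n_subsets = 3, subset_rule = c("pair", "index"),
                             initial = 1, eps = 1e-12, sens = NULL) {
  subset_rule <- match.arg(subset_rule)
  pr <- prepare_recon_events(set, grid, scatter_map)
  if (subset_rule == "pair") {
    if (is.null(sens)) sens <- sensitivity_image(grid, vol, n_subsets)
    ev_subset <- subset_of_pairs(nrow(grid$pairs), n_subsets)[pr$pair + 1L]
  } else {
    if (is.null(sens)) {
      total <- sensitivity_image(grid, vol, 1)
      sens <- matrix(rep(total / n_subsets, n_subsets), ncol = n_subsets)
    }
    ev_subset <- as.integer(seq_len(nrow(pr$ep)) - 1L) %% n_subsets
  }
  stopifnot(ncol(sens) == n_subsets)
  img0 <- rep(as.numeric(initial), prod(vol$dim))
  res <- cpp_osem(pr$ep, pr$S, ev_subset, img0, sens, vol$dim, vol$origin,
                  vol$voxel_size, as.integer(n_iter), as.integer(n_subsets),
                  eps)
  out <- vol
  img <- res$image
  img[rowSums(sens) <= 0] <- 0
  out$values <- array(img, dim = vol$dim)
  list(image = out, loglik = res$loglik, S_total = sum(pr$S))
}

#' List-mode MLEM reconstruction
#'
#' Single-subset [reconstruct_osem()]: the plain EM update with the additive
#' scatter term, monotone in the Poisson log-likelihood.
#'
#' @inheritParams reconstruct_osem
#' @param n_iter EM iterations.
#' @export
reconstruct_mlem <- function(set, grid, vol, scatter_map = NULL, n_iter = 4,
                             initial = 1, eps = 1e-12, sens = NULL) {
  reconstruct_osem(set, grid, vol, scatter_map, n_iter = n_iter,
                   n_subsets = 1, subset_rule = "pair", initial = initial,
                   eps = eps, sens = sens)
}

#' Write an image volume to disk
#'
#' `format = "nifti"` uses RNifti (if installed); `format = "raw"` writes
#' little-endian float64 values plus a YAML sidecar with dimensions, voxel
#' size and origin.
#'
#' @param vol an [image_volume()].
#' @param path output path (extension added for the sidecar).
#' @param format `"raw"` or `"nifti"`.
#' @export
write_volume <- function(vol, path, format = c("raw", "nifti")) {
  format <- match.arg(format)
  if (format == "nifti") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is not installed; use format = 'raw'")
    img <- RNifti::asNifti(vol$values, pixdim = rep(vol$voxel_size, 3))
    RNifti::writeNifti(img, path)
  } else {
    con <- file(path, "wb")
    writeBin(as.numeric(vol$values), con, size = 8, endian = "little")
    close(con)
    yaml::write_yaml(list(dim = vol$dim, voxel_size = vol$voxel_size,
                          origin = vol$origin, dtype = "float64-le"),
                     paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Mean voxel value inside a cylindrical region of interest
#'
#' @param vol an [image_volume()].
#' @param center length-2 or 3 ROI axis position (mm); the ROI spans
#'   `|z| <= half_height` around `center[3]` (0 if absent).
#' @param radius ROI radius (mm).
#' @param half_height ROI axial half-extent (mm).
#' @export
roi_mean <- function(vol, center, radius, half_height = vol$voxel_size) {
  cz <- if (length(center) >= 3) center[3] else 0
  vc <- voxel_centers(vol)
  sel <- (vc[, 1] - center[1])^2 + (vc[, 2] - center[2])^2 <= radius^2 &
    abs(vc[, 3] - cz) <= half_height
  mean(vol$values[sel])
}

#' Central transaxial profile of a volume
#'
#' Voxel values along x at y = 0, averaged over the slices within
#' `|z| <= half_height`.
#' @param vol an [image_volume()].
#' @param half_height axial averaging half-extent (mm).
#' @return a data.frame with columns `x` (mm) and `value`.
#' @export
central_profile <- function(vol, half_height = vol$voxel_size) {
  vc <- voxel_centers(vol)
  iy <- which.min(abs(vol$origin[2] + (seq_len(vol$dim[2]) - 0.5) *
                        vol$voxel_size))
  zsel <- which(abs(vol$origin[3] + (seq_len(vol$dim[3]) - 0.5) *
                      vol$voxel_size) <= half_height)
  vals <- apply(vol$values[, iy, zsel, drop = FALSE], 1, mean)
  data.frame(x = vol$origin[1] + (seq_len(vol$dim[1]) - 0.5) * vol$voxel_size,
             value = vals)
}
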