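#' Silverman rule-of-thumb bandwidth for 4-D LOR coordinates
#'
#' Diagonal bandwidth matrix `H_ii = (2/(3n))^(1/4) * sigma_i^2` (mm^2), the
#' multivariate Gaussian rule of thumb in four dimensions, with `sigma_i` the
#' sample standard deviation of the i-th LOR coordinate over the `n` events.
#' Degenerate inputs (`n < 2`, or a coordinate with zero spread) fall back to
#' `fallback` (typically the squared pixel pitch) in every affected dimension,
#' with a message.
#'
#' @param coords n x 4 matrix of LOR coordinates `(u_a, v_a, u_b, v_b)` in mm.
#' @param fallback bandwidth (mm^2) used for degenerate dimensions.
#' @return a 4 x 4 diagonal bandwidth matrix (mm^2).
#' @export
silverman_bandwidth <- function(coords, fallback = 4) {
  coords <- rbind(coords)
  n <- nrow(coords)
  if (n < 2) {
    message("silverman_bandwidth: fewer than 2 events, using fallback bandwidth")
    return(diag(rep(fallback, 4)))
  }
  sig2 <- apply(coords, 2, stats::var)
  h <- (2 / (3 * n))^(1 / 4) * sig2
  bad <- !is.finite(h) | h <= 0
  if (any(bad)) {
    message(sprintf("silverman_bandwidth: %d degenerate coordinate(s), using fallback",
                    sum(bad)))
    h[bad] <- fallback
  }
  diag(h)
}

#' The 95% truncation threshold of the 4-D Gaussian kernel
#'
#' Squared Mahalanobis distance containing 95% of the kernel volume,
#' `qchisq(0.95, df = 4)`.
#' @export
kernel_truncation <- function() qchisq(0.95, df = 4)

#' Truncated Gaussian kernel weight
#'
#' `w = exp(-1/2 dx' H^-1 dx)` for squared Mahalanobis distance at most the
#' 95% kernel volume contour, 0 beyond. Weights are returned unnormalized;
#' the smoothing step normalizes each event's kernel over its in-bounds
#' discrete neighborhood so counts are conserved exactly.
#'
#' @param dx n x 4 matrix (or length-4 vector) of coordinate offsets (mm).
#' @param H 4 x 4 diagonal bandwidth matrix (mm^2), e.g. from
#'   [silverman_bandwidth()].
#' @export
kernel_weight <- function(dx, H) {
  dx <- rbind(dx)
  h2 <- diag(H)
  stopifnot(length(h2) == 4, all(h2 > 0))
  m <- as.vector(dx^2 %*% (1 / h2))
  ifelse(m <= kernel_truncation(), exp(-0.5 * m), 0)
}

pooled_bandwidths <- function(bins, win, lv, pitch, min_window_events = 100) {
  ok <- !is.na(bins$pair)
  coords <- as.matrix(bins[, c("ua", "va", "ub", "vb"), with = FALSE])
  pooled <- silverman_bandwidth(coords[ok, , drop = FALSE],
                                fallback = pitch^2)
  lapply(setNames(lv, lv), function(w) {
    sel <- ok & win == w
    if (sum(sel) >= min_window_events)
      silverman_bandwidth(coords[sel, , drop = FALSE], fallback = pitch^2)
    else pooled
  })
}

#' Kernel-smoothed per-window LOR-bin counts
#'
#' Replaces each bin's raw window counts by the kernel-weighted sum of all
#' events of that window in its 4-D LOR-coordinate neighborhood (same block
#' pair only; LORs on different pairs traverse different image regions, so the
#' 4-coordinate distance is only meaningful within a faced pair). Each event
#' deposits exactly one count over its truncated in-bounds neighborhood, so
#' per-window totals are conserved exactly.
#'
#' Bandwidths default to the per-window Silverman rule; windows with fewer
#' than `min_window_events` events borrow the bandwidth pooled across all
#' windows (sparsity guard).
#'
#' @param set a [listmode_set()].
#' @param cfg an [energy_windows()].
#' @param grid a [virtual_pixel_grid()].
#' @param bandwidths optional named list (per window) of 4 x 4 diagonal
#'   bandwidth matrices, overriding the Silverman rule.
#' @param output `"occupied"`: evaluate smoothed counts at the bins that
#'   contain at least one raw event (the bins every later stage consumes);
#'   `"full"`: also return every nonzero smoothed bin (dense; small problems
#'   and oracle tests).
#' @param min_window_events sparsity guard for per-window bandwidths.
#' @return a `data.table` keyed by `bin` (columns `pair`, `pa`, `pb`, one
#'   smoothed-count column per window, `total`, and the raw per-bin total
#'   `raw_total`). Attributes: `bandwidths`, `window_totals` (exact deposited
#'   mass per window), and with `output = "full"` a `full` data.table of all
#'   nonzero smoothed bins per window.
#' @export
smooth_window_counts <- function(set, cfg, grid, bandwidths = NULL,
                                 output = c("occupied", "full"),
                                 min_window_events = 100) {
  output <- match.arg(output)
  geom <- grid$geometry
  bins <- bin_events(set, grid)
  win <- classify_events(set, cfg)
  lv <- window_levels(cfg)
  if (is.null(bandwidths))
    bandwidths <- pooled_bandwidths(bins, win, lv, grid$pitch,
                                    min_window_events)
  stopifnot(all(lv %in% names(bandwidths)))

  ok <- !is.na(bins$pair)
  raw <- data.table::data.table(bin = bins$bin[ok], pair = bins$pair[ok],
                                pa = bins$pa[ok], pb = bins$pb[ok])
  occ <- raw[, .(raw_total = .N), by = .(bin, pair, pa, pb)]
  data.table::setkey(occ, bin)

  P <- grid$n_pixels
  full_out <- list()
  totals <- numeric(0)
  for (w in lv) {
    sel <- ok & win == w
    res <- cpp_kde_smooth(
      ev_pair = bins$pair[sel],
      coords = as.matrix(bins[sel, c("ua", "va", "ub", "vb"), with = FALSE]),
      h2 = diag(bandwidths[[w]]), pitch = grid$pitch,
      n_u = grid$n_u, n_v = grid$n_v,
      half_w = geom$block_width / 2, half_h = geom$block_height / 2,
      chi2 = kernel_truncation(),
      q_pair = occ$pair, q_pa = as.numeric(occ$pa), q_pb = as.numeric(occ$pb),
      full = output == "full", n_pairs = nrow(grid$pairs))
    occ[[w]] <- res$values
    totals[w] <- res$total_mass
    if (output == "full") {
      pa <- res$full_index %/% P
      pb <- res$full_index %% P
      full_out[[w]] <- data.table::data.table(
        window = w, pair = as.integer(res$full_pair),
        pa = as.integer(pa), pb = as.integer(pb),
        bin = (res$full_pair * P + pa) * P + pb,
        value = res$full_value)
    }
  }
  occ$total <- Reduce(`+`, lapply(lv, function(w) occ[[w]]))
  data.table::setattr(occ, "grid", grid)
  data.table::setattr(occ, "windows", lv)
  data.table::setattr(occ, "bandwidths", bandwidths)
  data.table::setattr(occ, "window_totals", totals)
  if (output == "full")
    data.table::setattr(occ, "full", data.table::rbindlist(full_out))
  occ
}
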