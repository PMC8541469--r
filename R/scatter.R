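#' Estimated scattered counts in the photopeak window, per LOR bin
#'
#' DEW: `k_LEW * C_LEW(b)`; TEW: `k_LEW * C_LEW(b) + k_HEW * C_UEW(b)`,
#' evaluated on (typically kernel-smoothed) window counts and clamped to
#' `[0, C_ph(b)]` — an estimate above the photopeak content of the bin is
#' unphysical and signals local mis-calibration. The clamp rate is exposed as
#' `attr(, "clamp_rate")`.
#'
#' @param counts output of [smooth_window_counts()] (or [count_windows()]).
#' @param k a [fit_coefficients()] result matching the window configuration.
#' @return numeric vector of per-bin scattered photopeak counts, aligned with
#'   `counts` rows.
#' @export
photopeak_scatter <- function(counts, k) {
  lv <- attr(counts, "windows")
  stopifnot(identical(lv, window_levels(k$windows)))
  aux <- setdiff(lv, "photopeak")
  est <- rep(0, nrow(counts))
  for (w in aux) est <- est + coef_for_bins(k, counts$bin, w) * counts[[w]]
  clamped <- est > counts$photopeak
  out <- pmin(pmax(est, 0), counts$photopeak)
  attr(out, "clamp_rate") <- if (length(out)) mean(clamped) else 0
  out
}

#' Per-LOR-bin scatter fraction map
#'
#' `SF(b) = (C_LEW(b) + C_ph,scatter(b)) / C_Total(b)` with `C_Total` the sum
#' over all accepted windows (LEW + photopeak + UEW under TEW), clamped to
#' `[0, 1]`. Bins with zero total counts carry `NA` and are excluded from the
#' reconstruction correction. The LEW term follows the estimator's definition
#' of counting the whole low window as scatter; `lew_purity` optionally
#' down-weights it by a known true-event contamination (off by default).
#'
#' @param counts output of [smooth_window_counts()].
#' @param scatter per-bin scattered photopeak counts from
#'   [photopeak_scatter()].
#' @param lew_purity fraction of LEW counts treated as scatter (default 1,
#'   the literal definition).
#' @return a `data.table` (class `scatter_fraction_map`) with columns of
#'   `counts` plus `c_scatter` and `sf`.
#' @export
scatter_fraction_map <- function(counts, scatter, lew_purity = 1) {
  stopifnot(nrow(counts) == length(scatter), lew_purity > 0, lew_purity <= 1)
  map <- data.table::copy(counts)
  map$c_scatter <- as.numeric(scatter)
  num <- lew_purity * map$lew + map$c_scatter
  map$sf <- ifelse(map$total > 0, pmin(1, pmax(0, num / map$total)), NA_real_)
  data.table::setattr(map, "lew_purity", lew_purity)
  data.table::setattr(map, "class", c("scatter_fraction_map", class(map)))
  map
}

#' Count-weighted global scatter fraction
#'
#' Aggregates the per-bin estimate over the bins of `map`:
#' `sum_b (C_LEW + C_ph,scatter) / sum_b C_Total`. Note that a map evaluated
#' only at occupied bins under-represents windows whose events are spatially
#' diffuse; for the global estimate over the full LOR lattice use
#' [global_sf_from_totals()], which the count-weighted aggregate telescopes to
#' by kernel mass conservation.
#'
#' @param map a [scatter_fraction_map()].
#' @export
global_scatter_fraction <- function(map) {
  stopifnot(nrow(map) > 0)
  lp <- attr(map, "lew_purity") %||% 1
  sum(lp * map$lew + map$c_scatter) / sum(map$total)
}

#' Global scatter fraction from per-window count totals
#'
#' The count-weighted aggregate of the per-bin scatter fraction over the full
#' LOR lattice: because the smoothing kernel conserves each window's total
#' mass, `sum_b (C_LEW(b) + sum_w k_w C_w(b)) / sum_b C_Total(b)` reduces to
#' `(N_LEW + sum_w k_w N_w) / N_Total` with `N_w` the per-window event totals
#' (per-bin clamping is a local repair for the map and is not applied to the
#' global aggregate). Clamped to `[0, 1]`.
#'
#' @param totals named per-window event totals (`lew`, `photopeak`, `uew`).
#' @param k a [fit_coefficients()] result (global coefficients are used).
#' @param lew_purity fraction of LEW counts treated as scatter.
#' @export
global_sf_from_totals <- function(totals, k, lew_purity = 1) {
  aux <- setdiff(window_levels(k$windows), "photopeak")
  num <- lew_purity * totals[["lew"]] +
    sum(vapply(aux, function(w) k$k[[w]] * totals[[w]], 1))
  min(1, max(0, num / sum(unlist(totals[window_levels(k$windows)]))))
}

#' Ground-truth global scatter fraction of a labeled set
#'
#' Scattered accepted coincidences (at least one photon phantom-scattered)
#' over all accepted coincidences.
#' @param set a labeled [listmode_set()].
#' @export
truth_scatter_fraction <- function(set) mean(truth_scattered(set))

#' Additive scatter term for the reconstruction forward model
#'
#' Converts the scatter-fraction map into the per-LOR-bin constant added to
#' the forward projection: `S(b) = SF(b) * C_raw(b)`, the expected scatter
#' counts in bin `b`, where `C_raw` is the *unsmoothed* event count of the bin
#' (smoothing estimates the ratio; raw counts set the magnitude, so kernel
#' mass is not double counted). At the bin-level LOR discretization the EM
#' fixed point then satisfies `forward + S = measured counts` per bin. Bins
#' without an estimate (`NA` scatter fraction) get `S = 0`.
#'
#' @param map a [scatter_fraction_map()] (its `raw_total` column is `C_raw`).
#' @return a `data.table` with columns `bin` and `S` (counts, >= 0).
#' @export
additive_term <- function(map) {
  stopifnot(!is.null(map$raw_total))
  data.table::data.table(bin = map$bin,
                         S = ifelse(is.na(map$sf), 0, map$sf * map$raw_total))
}

#' End-to-end scatter estimation for one list-mode set
#'
#' Convenience pipeline: bin, classify, smooth (optional), apply the
#' calibrated coefficients and form the scatter-fraction map and its global
#' aggregate.
#'
#' @param set a [listmode_set()].
#' @param cfg an [energy_windows()].
#' @param k a [fit_coefficients()] result.
#' @param grid a [virtual_pixel_grid()].
#' @param smooth kernel-smooth the window counts first (recommended).
#' @param lew_purity see [scatter_fraction_map()].
#' @return a list with `map` (per-bin scatter fractions at the occupied bins,
#'   feeding the reconstruction), `global_sf` (full-lattice aggregate via
#'   [global_sf_from_totals()]) and `clamp_rate`.
#' @export
estimate_scatter <- function(set, cfg, k, grid, smooth = TRUE,
                             lew_purity = 1) {
  lv <- window_levels(cfg)
  if (smooth) {
    counts <- smooth_window_counts(set, cfg, grid)
    totals <- as.list(attr(counts, "window_totals"))
  } else {
    counts <- count_windows(set, cfg, grid)
    counts$raw_total <- counts$total
    totals <- lapply(setNames(lv, lv), function(w) sum(counts[[w]]))
  }
  sc <- photopeak_scatter(counts, k)
  map <- scatter_fraction_map(counts, sc, lew_purity = lew_purity)
  list(map = map,
       global_sf = global_sf_from_totals(totals, k, lew_purity),
       clamp_rate = attr(sc, "clamp_rate"))
}
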