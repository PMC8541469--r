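#' Energy window configuration
#'
#' Dual (DEW) or triple (TEW) energy window layouts over the 350-650 keV
#' acceptance range. DEW: low window 350-430 keV and photopeak 430-650 keV.
#' TEW: low 350-430, photopeak 430-550 and upper window 550-650 keV. Windows
#' are contiguous, non-overlapping and cover the acceptance window; interior
#' boundaries are half-open (a photon exactly at 430 keV is photopeak).
#'
#' @param mode `"TEW"` or `"DEW"`.
#' @param acceptance the hardware acceptance window (keV).
#' @param lew_upper LEW/photopeak boundary (keV).
#' @param uew_lower photopeak/UEW boundary (keV, TEW only).
#' @return an object of class `energy_windows`.
#' @export
energy_windows <- function(mode = c("TEW", "DEW"), acceptance = c(350, 650),
                           lew_upper = 430, uew_lower = 550) {
  mode <- match.arg(mode)
  stopifnot(acceptance[1] < lew_upper, lew_upper < acceptance[2])
  cfg <- list(mode = mode, acceptance = as.numeric(acceptance),
              lew = c(acceptance[1], lew_upper))
  if (mode == "TEW") {
    stopifnot(lew_upper < uew_lower, uew_lower < acceptance[2])
    cfg$photopeak <- c(lew_upper, uew_lower)
    cfg$uew <- c(uew_lower, acceptance[2])
  } else {
    cfg$photopeak <- c(lew_upper, acceptance[2])
  }
  structure(cfg, class = "energy_windows")
}

#' @export
print.energy_windows <- function(x, ...) {
  cat(sprintf("<energy_windows> %s: LEW [%g, %g), photopeak [%g, %g)%s\n",
              x$mode, x$lew[1], x$lew[2], x$photopeak[1], x$photopeak[2],
              if (x$mode == "TEW")
                sprintf(", UEW [%g, %g]", x$uew[1], x$uew[2]) else ""))
  invisible(x)
}

window_levels <- function(cfg) {
  if (cfg$mode == "TEW") c("lew", "photopeak", "uew") else c("lew", "photopeak")
}

#' Classify coincidence events into energy windows
#'
#' A photopeak event has both photons inside the photopeak window; an
#' auxiliary-window event has at least one photon inside that auxiliary
#' window. When the two photons fall into different auxiliary windows the low
#' window takes priority over the upper one: a photon that lost more than the
#' LEW deficit has certainly scattered, so the event is maximally
#' scatter-like. The resulting rule, applied per event:
#' LEW if either photon is in 350-430; otherwise (TEW) UEW if either photon is
#' in 550-650; otherwise photopeak.
#'
#' @param set a [listmode_set()], or a numeric vector of first-photon energies
#'   (then `e2` must be given).
#' @param cfg an [energy_windows()].
#' @param e2 second-photon energies when `set` is a numeric vector.
#' @return a factor with levels `lew`, `photopeak` (and `uew` for TEW).
#' @export
classify_events <- function(set, cfg, e2 = NULL) {
  if (inherits(set, "listmode_set")) {
    e1 <- set$events$e1; e2 <- set$events$e2
  } else {
    e1 <- set
    if (is.null(e2)) stop("e2 required when passing bare energies")
  }
  acc <- cfg$acceptance
  if (length(e1) && (min(e1, e2) < acc[1] || max(e1, e2) > acc[2]))
    stop("photon energies outside the acceptance window; filter at load")
  in_lew <- function(e) e >= cfg$lew[1] & e < cfg$lew[2]
  lab <- rep("photopeak", length(e1))
  if (cfg$mode == "TEW") {
    in_uew <- function(e) e >= cfg$uew[1] & e <= cfg$uew[2]
    lab[in_uew(e1) | in_uew(e2)] <- "uew"
  }
  lab[in_lew(e1) | in_lew(e2)] <- "lew"
  factor(lab, levels = window_levels(cfg))
}

#' Per-LOR-bin window counts
#'
#' Tallies accepted events per (LOR bin, energy window); with `truth = TRUE`
#' (requires labels) also the per-bin counts of truth-scattered events per
#' window, which calibration consumes.
#'
#' @param set a [listmode_set()].
#' @param cfg an [energy_windows()].
#' @param grid a [virtual_pixel_grid()].
#' @param truth also tally truth-scattered counts per window.
#' @return a `data.table` keyed by `bin` with columns `pair`, `pa`, `pb`, one
#'   column per window, `total` (and `scat_<window>` columns with `truth`).
#'   Events on disallowed pairs are excluded; their count is in
#'   `attr(, "n_unbinnable")`.
#' @export
count_windows <- function(set, cfg, grid, truth = FALSE) {
  bins <- bin_events(set, grid)
  win <- classify_events(set, cfg)
  dt <- data.table::data.table(bin = bins$bin, pair = bins$pair, pa = bins$pa,
                               pb = bins$pb, window = win)
  if (truth) dt$scattered <- truth_scattered(set)
  n_unbinnable <- sum(is.na(dt$pair))
  dt <- dt[!is.na(pair)]
  lv <- window_levels(cfg)
  out <- dt[, {
    cnt <- lapply(lv, function(w) sum(window == w))
    names(cnt) <- lv
    if (truth) {
      sc <- lapply(lv, function(w) sum(window == w & scattered))
      names(sc) <- paste0("scat_", lv)
      c(cnt, sc)
    } else cnt
  }, by = .(bin, pair, pa, pb)]
  out$total <- Reduce(`+`, lapply(lv, function(w) out[[w]]))
  data.table::setkey(out, bin)
  data.table::setattr(out, "grid", grid)
  data.table::setattr(out, "n_unbinnable", n_unbinnable)
  data.table::setattr(out, "windows", lv)
  out
}

# exact 2-variable non-negative least squares (active set enumeration)
nnls2 <- function(X, y) {
  fit1 <- function(x) {
    s <- sum(x * x)
    if (s <= 0) 0 else max(0, sum(x * y) / s)
  }
  XtX <- crossprod(X)
  if (ncol(X) == 1 || abs(det(XtX)) < 1e-12 * max(diag(XtX))^2) {
    return(c(fit1(X[, 1]), if (ncol(X) > 1) 0 else NULL))
  }
  k <- drop(solve(XtX, crossprod(X, y)))
  if (all(k >= 0)) return(k)
  cand <- list(c(fit1(X[, 1]), 0), c(0, fit1(X[, 2])))
  rss <- vapply(cand, function(kk) sum((y - X %*% kk)^2), 1)
  cand[[which.min(rss)]]
}

#' Fit the energy-window scatter coefficients from labeled data
#'
#' The coefficient of auxiliary window `w` scales that window's counts into an
#' estimate of the scattered counts in the photopeak window
#' (`k_w = C_ph,scatter / C_w`). For DEW the global coefficient is the exact
#' quotient of pooled truth-scattered photopeak counts over pooled LEW counts.
#' For TEW the two quotients taken literally would each reproduce the whole
#' scattered photopeak on its own, so `(k_LEW, k_HEW)` are fit jointly by
#' non-negative least squares of per-set scattered-photopeak counts on
#' (LEW, UEW) counts across the calibration ensemble; a single calibration
#' set regresses across its block-pair aggregates instead (per-bin counts are
#' too sparse to carry a slope).
#'
#' In `per_bin` mode coefficients are fit per LOR bin (DEW quotient, or TEW
#' NNLS across the ensemble members at the matching bin); bins with fewer than
#' `min_bin_count` total events fall back to the global value, as do bins with
#' a zero auxiliary denominator.
#'
#' @param sets a labeled [listmode_set()] or a list of them (the calibration
#'   ensemble, e.g. the seven cylinder radii).
#' @param cfg an [energy_windows()].
#' @param mode `"global"` or `"per_bin"`.
#' @param grid a [virtual_pixel_grid()] (required for `per_bin`; for global
#'   DEW/TEW-ensemble fits it only routes the counting).
#' @param min_bin_count per-bin statistics floor.
#' @return an object of class `scatter_coefficients`: `$k` named global
#'   coefficients, `$per_bin` data.table (per_bin mode), provenance fields.
#' @export
fit_coefficients <- function(sets, cfg, mode = c("global", "per_bin"), grid,
                             min_bin_count = 50) {
  mode <- match.arg(mode)
  if (inherits(sets, "listmode_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1)
  for (s in sets) if (!has_truth(s)) stop("calibration requires truth labels")
  lv <- window_levels(cfg)
  aux <- setdiff(lv, "photopeak")
  counts <- lapply(sets, count_windows, cfg = cfg, grid = grid, truth = TRUE)

  totals <- do.call(rbind, lapply(counts, function(ct) {
    c(scat_ph = sum(ct$scat_photopeak),
      vapply(aux, function(w) sum(ct[[w]]), 1))
  }))
  k_global <- if (cfg$mode == "DEW") {
    den <- sum(totals[, "lew"])
    c(lew = if (den > 0) sum(totals[, "scat_ph"]) / den else 0)
  } else if (nrow(totals) >= 2) {
    setNames(nnls2(totals[, aux, drop = FALSE], totals[, "scat_ph"]), aux)
  } else {
    # single set: regress across block-pair aggregates (per-bin counts are
    # too sparse for a stable slope at typical pitches)
    ct <- counts[[1]][, lapply(.SD, sum), by = pair,
                      .SDcols = c("scat_photopeak", aux)]
    setNames(nnls2(as.matrix(ct[, aux, with = FALSE]), ct$scat_photopeak), aux)
  }

  per_bin <- NULL
  n_fallback <- 0L
  if (mode == "per_bin") {
    pooled <- data.table::rbindlist(lapply(seq_along(counts), function(i) {
      ct <- data.table::copy(counts[[i]]); ct$set <- i; ct
    }))
    if (cfg$mode == "DEW") {
      pb <- pooled[, .(scat_ph = sum(scat_photopeak), lew = sum(lew),
                       total = sum(total)), by = bin]
      pb[, k_lew := ifelse(total >= min_bin_count & lew > 0,
                           scat_ph / pmax(lew, 1), k_global[["lew"]])]
      n_fallback <- pb[, sum(!(total >= min_bin_count & lew > 0))]
      per_bin <- pb[, .(bin, k_lew)]
    } else {
      fit_bin <- function(sd) {
        if (sum(sd$total) < min_bin_count) return(NULL)
        nnls2(cbind(sd$lew, sd$uew), sd$scat_photopeak)
      }
      pb <- pooled[, {
        k <- fit_bin(.SD)
        if (is.null(k)) list(k_lew = k_global[["lew"]], k_uew = k_global[["uew"]],
                             fallback = TRUE)
        else list(k_lew = k[1], k_uew = k[2], fallback = FALSE)
      }, by = bin]
      n_fallback <- pb[, sum(fallback)]
      per_bin <- pb[, .(bin, k_lew, k_uew)]
    }
    data.table::setkey(per_bin, bin)
  }

  structure(list(mode = mode, windows = cfg, k = k_global, per_bin = per_bin,
                 n_fallback_bins = n_fallback,
                 calibration = list(n_sets = length(sets),
                                    n_events = sum(vapply(sets, n_events, 1)),
                                    min_bin_count = min_bin_count)),
            class = "scatter_coefficients")
}

#' @export
print.scatter_coefficients <- function(x, ...) {
  cat(sprintf("<scatter_coefficients> %s windows, %s mode: %s\n",
              x$windows$mode, x$mode,
              paste(sprintf("k_%s = %.4f", names(x$k), x$k), collapse = ", ")))
  if (!is.null(x$per_bin))
    cat(sprintf("  %d bins fit, %d fell back to global\n", nrow(x$per_bin),
                x$n_fallback_bins))
  invisible(x)
}

coef_for_bins <- function(k, bins, window) {
  col <- paste0("k_", window)
  glob <- k$k[[window]]
  if (is.null(k$per_bin)) return(rep(glob, length(bins)))
  idx <- match(bins, k$per_bin$bin)
  out <- k$per_bin[[col]][idx]
  out[is.na(out)] <- glob
  out
}

#' Estimated unscattered photopeak counts per bin
#'
#' `C_true = C_ph,total - sum_w k_w C_w`, optionally clamped at zero (counts
#' are physical; the unclamped value is what makes the calibration identity
#' exact).
#'
#' @param counts output of [count_windows()].
#' @param k a [fit_coefficients()] result.
#' @param clamp clamp negative estimates to zero.
#' @return numeric vector aligned with `counts` rows.
#' @export
true_counts <- function(counts, k, clamp = TRUE) {
  aux <- setdiff(attr(counts, "windows"), "photopeak")
  est <- counts$photopeak
  for (w in aux) est <- est - coef_for_bins(k, counts$bin, w) * counts[[w]]
  if (clamp) pmax(0, est) else est
}

#' Truth-scattered share of each energy window
#'
#' The per-window scatter purity table: for each window, the fraction of its
#' accepted coincidences whose truth labels mark at least one phantom scatter.
#'
#' @param set a labeled [listmode_set()].
#' @param cfg an [energy_windows()].
#' @return a data.frame with columns `window`, `n`, `n_scattered`,
#'   `scattered_share`.
#' @export
window_purity <- function(set, cfg) {
  win <- classify_events(set, cfg)
  sc <- truth_scattered(set)
  lv <- window_levels(cfg)
  data.frame(window = lv,
             n = vapply(lv, function(w) sum(win == w), 1),
             n_scattered = vapply(lv, function(w) sum(win == w & sc), 1),
             scattered_share = vapply(lv, function(w) {
               n <- sum(win == w)
               if (n == 0) NA_real_ else sum(win == w & sc) / n
             }, 1),
             row.names = NULL)
}

#' Serialize scatter coefficients with provenance
#' @param k a [fit_coefficients()] result.
#' @param path output YAML file.
#' @param geometry optional [scanner_geometry()] whose hash to record.
#' @export
write_coefficients <- function(k, path, geometry = NULL) {
  obj <- list(mode = k$mode, window_mode = k$windows$mode,
              k = as.list(k$k), calibration = k$calibration,
              geometry_hash = if (!is.null(geometry)) geometry_hash(geometry))
  if (!is.null(k$per_bin))
    obj$per_bin <- lapply(as.list(k$per_bin), as.numeric)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read scatter coefficients written by [write_coefficients()]
#' @param path YAML file.
#' @export
read_coefficients <- function(path) {
  obj <- yaml::read_yaml(path)
  cfg <- energy_windows(obj$window_mode)
  per_bin <- NULL
  if (!is.null(obj$per_bin)) {
    per_bin <- data.table::as.data.table(obj$per_bin)
    data.table::setkey(per_bin, bin)
  }
  structure(list(mode = obj$mode, windows = cfg,
                 k = unlist(obj$k), per_bin = per_bin,
                 n_fallback_bins = NA_integer_,
                 calibration = obj$calibration),
            class = "scatter_coefficients")
}
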