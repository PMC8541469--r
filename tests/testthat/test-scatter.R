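mock_counts <- function(lew, ph, uew, raw = NULL) {
  n <- length(lew)
  ct <- data.table::data.table(bin = as.numeric(seq_len(n) - 1), pair = 0L,
                               pa = 0L, pb = seq_len(n) - 1L,
                               lew = lew, photopeak = ph, uew = uew)
  ct$total <- lew + ph + uew
  ct$raw_total <- if (is.null(raw)) ct$total else raw
  data.table::setattr(ct, "windows", c("lew", "photopeak", "uew"))
  ct
}

mock_k <- function(k_lew, k_uew = NULL) {
  mode <- if (is.null(k_uew)) "DEW" else "TEW"
  kv <- if (is.null(k_uew)) c(lew = k_lew) else c(lew = k_lew, uew = k_uew)
  structure(list(mode = "global", windows = energy_windows(mode), k = kv,
                 per_bin = NULL),
            class = "scatter_coefficients")
}

test_that("photopeak scatter applies the window coefficients with clamping", {
  ct <- mock_counts(lew = c(20, 20, 50), ph = c(100, 100, 10),
                    uew = c(10, 10, 0))
  tew <- mock_k(0.4, 0.1)
  expect_equal(as.numeric(photopeak_scatter(ct, tew)), c(9, 9, 10))
  expect_equal(attr(photopeak_scatter(ct, tew), "clamp_rate"), 1 / 3)
  expect_equal(as.numeric(photopeak_scatter(ct, mock_k(0, 0))), c(0, 0, 0))
  # DEW variant on DEW-shaped counts
  ctd <- mock_counts(20, 100, 0)
  data.table::setattr(ctd, "windows", c("lew", "photopeak"))
  expect_equal(as.numeric(photopeak_scatter(ctd, mock_k(0.4))), 8)
})

test_that("scatter fractions follow Eq.-7 arithmetic with sentinels", {
  ct <- mock_counts(lew = c(20, 0, 0), ph = c(72, 50, 0), uew = c(8, 0, 0))
  map <- scatter_fraction_map(ct, c(8, 0, 0))
  expect_equal(map$sf[1], (20 + 8) / 100)
  expect_equal(map$sf[2], 0)
  expect_true(is.na(map$sf[3]))  # zero-total bin carries a sentinel
  expect_true(all(map$sf >= 0 & map$sf <= 1, na.rm = TRUE))
})

test_that("the global aggregate is the count-weighted mean of bin fractions", {
  ct <- mock_counts(lew = c(10, 120), ph = c(80, 150), uew = c(10, 30))
  map <- scatter_fraction_map(ct, c(10, 60))  # SF = 0.2 @ 100, 0.6 @ 300
  expect_equal(map$sf, c(0.2, 0.6))
  expect_equal(global_scatter_fraction(map), 0.5)
  # single bin: the aggregate is that bin's SF
  expect_equal(global_scatter_fraction(map[1]), 0.2)
})

test_that("truth-label scatter fractions reproduce the simulator's labels", {
  s <- sim_cylinder(100, 1e4)
  grid <- virtual_pixel_grid(test_geometry(), 10)
  bins <- bin_events(s, grid)
  sc <- truth_scattered(s)
  keep <- !is.na(bins$pair)
  dt <- data.table::data.table(bin = bins$bin[keep], sc = sc[keep])
  agg <- dt[, .(n = .N, nsc = sum(sc)), by = bin]
  # definition identity: count-weighted mean of per-bin truth SF
  expect_equal(sum(agg$nsc) / sum(agg$n), mean(dt$sc))
  expect_equal(mean(dt$sc), truth_scatter_fraction(s), tolerance = 1e-12)
})

test_that("the global estimate telescopes to the window totals", {
  s <- sim_cylinder(60, 5e3)
  cfg <- energy_windows("TEW")
  k <- mock_k(0.5, 0.2)
  gridbig <- virtual_pixel_grid(test_geometry(), 10)
  sm <- smooth_window_counts(s, cfg, gridbig, output = "full")
  full <- attr(sm, "full")
  wide <- data.table::dcast(full, bin ~ window, value.var = "value",
                            fill = 0)
  for (w in c("lew", "photopeak", "uew"))
    if (is.null(wide[[w]])) wide[[w]] <- 0
  num <- sum(wide$lew + pmax(0, k$k[["lew"]] * wide$lew +
                               k$k[["uew"]] * wide$uew))
  den <- sum(wide$lew + wide$photopeak + wide$uew)
  totals <- as.list(attr(sm, "window_totals"))
  expect_equal(num / den, global_sf_from_totals(totals, k),
               tolerance = 1e-9)
})

test_that("the additive term scales linearly with raw counts and respects sentinels", {
  ct <- mock_counts(lew = c(10, 0), ph = c(30, 0), uew = c(0, 0),
                    raw = c(50, 0))
  map <- scatter_fraction_map(ct, c(5, 0))
  st <- additive_term(map)
  expect_equal(st$S, c((10 + 5) / 40 * 50, 0))
  ct2 <- mock_counts(lew = c(10, 0), ph = c(30, 0), uew = c(0, 0),
                     raw = c(100, 0))
  expect_equal(additive_term(scatter_fraction_map(ct2, c(5, 0)))$S[1],
               2 * st$S[1])
  # SF = 0 everywhere -> no correction
  map0 <- scatter_fraction_map(mock_counts(c(0, 0), c(5, 5), c(0, 0)),
                               c(0, 0))
  expect_true(all(additive_term(map0)$S == 0))
})

test_that("the EM fixed point with a known scatter term recovers the activity", {
  # 2-voxel volume, three LORs: A crosses both voxels, B only voxel 1,
  # C only voxel 2; expected counts m = a n* + s with n* = (2, 1)
  vol_dim <- c(2L, 1L, 1L)
  origin <- c(0, 0, 0); vox <- 10
  ep <- rbind(A = c(-5, 5, 5, 25, 5, 5),    # along x through both voxels
              B = c(5, -5, 5, 5, 15, 5),    # along y through voxel 1
              C = c(15, -5, 5, 15, 15, 5))  # along y through voxel 2
  a <- rbind(c(10, 10), c(10, 0), c(0, 10))
  nstar <- c(2, 1)
  s_lor <- c(5, 2, 3)
  m <- as.vector(a %*% nstar) + s_lor
  stopifnot(all(m == round(m)))
  ev <- ep[rep(1:3, m), , drop = FALSE]
  S <- rep(s_lor, m)
  sens <- matrix(colSums(a), ncol = 1)
  res <- petscatter:::cpp_osem(ev, S, integer(nrow(ev)), c(1, 1), sens,
                               vol_dim, origin, vox, 200L, 1L, 1e-12)
  expect_equal(res$image, nstar, tolerance = 0.01)
  # with S = 0 and uniform sensitivity the total converges to the count sum
  m0 <- as.vector(a %*% nstar)
  m0 <- round(m0)
  ev0 <- ep[rep(1:3, m0), , drop = FALSE]
  res0 <- petscatter:::cpp_osem(ev0, rep(0, nrow(ev0)), integer(nrow(ev0)),
                                c(1, 1), sens, vol_dim, origin, vox, 200L,
                                1L, 1e-12)
  expect_equal(sum(res0$image * colSums(a)), nrow(ev0), tolerance = 1e-6)
})
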