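test_that("event classification follows the LEW > UEW > photopeak priority", {
  tew <- energy_windows("TEW")
  dew <- energy_windows("DEW")
  # all window-pair combinations, representative energies 400/500/600 keV
  e1 <- c(400, 400, 400, 500, 500, 500, 600, 600, 600)
  e2 <- c(400, 500, 600, 400, 500, 600, 400, 500, 600)
  expect_equal(as.character(classify_events(e1, tew, e2)),
               c("lew", "lew", "lew", "lew", "photopeak", "uew",
                 "lew", "uew", "uew"))
  expect_equal(as.character(classify_events(e1, dew, e2)),
               c("lew", "lew", "lew", "lew", "photopeak", "photopeak",
                 "lew", "photopeak", "photopeak"))
  # half-open boundaries: 430 is photopeak, 550 is UEW, 650 stays accepted
  expect_equal(as.character(classify_events(c(430, 550, 650), tew,
                                            c(500, 500, 500))),
               c("photopeak", "uew", "uew"))
  expect_equal(as.character(classify_events(429.999, tew, 500)), "lew")
  expect_error(classify_events(300, tew, 500), "acceptance")
})

test_that("classification partitions every accepted event exactly once", {
  s <- make_events(2000, seed = 3)
  for (mode in c("TEW", "DEW")) {
    cfg <- energy_windows(mode)
    w <- classify_events(s, cfg)
    expect_false(any(is.na(w)))
    expect_equal(sum(table(w)), 2000)
  }
})

test_that("window counts equal an independent per-event tally", {
  geom <- test_geometry()
  grid <- virtual_pixel_grid(geom, 5)
  cfg <- energy_windows("TEW")
  s <- make_events(1500, seed = 9)
  ct <- count_windows(s, cfg, grid, truth = TRUE)
  # brute-force single pass
  b <- bin_events(s, grid)
  w <- as.character(classify_events(s, cfg))
  sc <- truth_scattered(s)
  expect_equal(sum(ct$total), nrow(s$events))
  for (i in sample(nrow(ct), 25)) {
    sel <- !is.na(b$bin) & b$bin == ct$bin[i]
    expect_equal(ct$lew[i], sum(sel & w == "lew"))
    expect_equal(ct$photopeak[i], sum(sel & w == "photopeak"))
    expect_equal(ct$uew[i], sum(sel & w == "uew"))
    expect_equal(ct$scat_photopeak[i], sum(sel & w == "photopeak" & sc))
  }
  # empty and degenerate cases
  s0 <- make_events(5); s0$events <- s0$events[0]
  expect_equal(nrow(count_windows(s0, cfg, grid)), 0)
})

test_that("DEW coefficient is the scattered-photopeak over LEW quotient", {
  spec <- data.frame(window = c("lew", "photopeak", "photopeak"),
                     scattered = c(TRUE, TRUE, FALSE),
                     count = c(100, 40, 160))
  s <- make_labeled_counts(spec)
  grid <- virtual_pixel_grid(test_geometry(), 10)
  k <- fit_coefficients(s, energy_windows("DEW"), "global", grid)
  expect_equal(unname(k$k[["lew"]]), 0.4)
  # no scattered events at all -> zero coefficients
  spec0 <- data.frame(window = c("lew", "photopeak"), scattered = FALSE,
                      count = c(50, 100))
  k0 <- fit_coefficients(make_labeled_counts(spec0), energy_windows("DEW"),
                         "global", grid)
  expect_equal(unname(k0$k[["lew"]]), 0)
})

test_that("TEW coefficients are recovered exactly from a consistent ensemble", {
  # two phantoms generated with k_lew = 0.5, k_uew = 0.25 and no noise
  mk <- function(lew, uew, scat_ph, true_ph) {
    make_labeled_counts(data.frame(
      window = c("lew", "uew", "photopeak", "photopeak"),
      scattered = c(TRUE, FALSE, TRUE, FALSE),
      count = c(lew, uew, scat_ph, true_ph)))
  }
  s1 <- mk(40, 16, 0.5 * 40 + 0.25 * 16, 100)  # 24 scattered photopeak
  s2 <- mk(20, 32, 0.5 * 20 + 0.25 * 32, 100)  # 18
  grid <- virtual_pixel_grid(test_geometry(), 10)
  k <- fit_coefficients(list(s1, s2), energy_windows("TEW"), "global", grid)
  expect_equal(unname(k$k), c(0.5, 0.25), tolerance = 1e-10)
})

test_that("the DEW calibration identity holds to machine precision", {
  s <- sim_cylinder(120, 1e4)
  grid <- virtual_pixel_grid(test_geometry(), 2)
  cfg <- energy_windows("DEW")
  k <- fit_coefficients(s, cfg, "global", grid)
  ct <- count_windows(s, cfg, grid, truth = TRUE)
  est_true <- sum(true_counts(ct, k, clamp = FALSE))
  real_true <- sum(ct$photopeak - ct$scat_photopeak)
  expect_equal(est_true, real_true, tolerance = 1e-12)
})

test_that("true-count estimates apply Eq.-style subtraction with clamping", {
  grid <- virtual_pixel_grid(test_geometry(), 10)
  ct <- data.table::data.table(bin = c(0, 1), pair = 0L, pa = 0L, pb = c(0L, 1L),
                               lew = c(30, 0), photopeak = c(10, 50),
                               uew = c(0, 0), total = c(40, 50))
  data.table::setattr(ct, "windows", c("lew", "photopeak", "uew"))
  k <- structure(list(mode = "global", windows = energy_windows("TEW"),
                      k = c(lew = 0.5, uew = 0.1), per_bin = NULL),
                 class = "scatter_coefficients")
  expect_equal(true_counts(ct, k, clamp = TRUE), c(0, 50))
  expect_equal(true_counts(ct, k, clamp = FALSE), c(-5, 50))
  # zero coefficients leave the photopeak untouched
  k$k[] <- 0
  expect_equal(true_counts(ct, k), c(10, 50))
})

test_that("per-bin coefficients fall back to the global value on thin bins", {
  s <- sim_cylinder(100, 1e4)
  grid <- virtual_pixel_grid(test_geometry(), 10)
  k <- fit_coefficients(s, energy_windows("DEW"), "per_bin", grid,
                        min_bin_count = 1e6)  # force fallback everywhere
  expect_true(all(abs(k$per_bin$k_lew - k$k[["lew"]]) < 1e-12))
  expect_equal(k$n_fallback_bins, nrow(k$per_bin))
})

test_that("coefficients serialize with provenance and read back", {
  s <- sim_cylinder(100, 1e4)
  grid <- virtual_pixel_grid(test_geometry(), 2)
  k <- fit_coefficients(s, energy_windows("TEW"), "global", grid)
  f <- tempfile(fileext = ".yaml")
  write_coefficients(k, f, geometry = test_geometry())
  k2 <- read_coefficients(f)
  expect_equal(k2$k, k$k, tolerance = 1e-12)
  expect_equal(k2$windows$mode, "TEW")
})
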