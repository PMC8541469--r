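# analytic ray-box chord length (slab method), the projector oracle
chord_oracle <- function(p1, p2, lo, hi) {
  d <- p2 - p1
  a0 <- 0; a1 <- 1
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-12) {
      if (p1[ax] < lo[ax] || p1[ax] > hi[ax]) return(0)
    } else {
      t <- sort(c((lo[ax] - p1[ax]) / d[ax], (hi[ax] - p1[ax]) / d[ax]))
      a0 <- max(a0, t[1]); a1 <- min(a1, t[2])
    }
  }
  max(0, a1 - a0) * sqrt(sum(d^2))
}

test_that("the projector returns exact intersection lengths", {
  vol <- image_volume(c(10, 10, 10), 2)
  # axis-aligned LOR through 10 voxels of 2 mm
  row <- project_lor(c(-30, 1, 1), c(30, 1, 1), vol)
  expect_equal(length(row$index), 10)
  expect_true(all(abs(row$length - 2) < 1e-12))
  # main diagonal of a single voxel
  v1 <- image_volume(c(1, 1, 1), 3, origin = c(0, 0, 0))
  row <- project_lor(c(0, 0, 0), c(3, 3, 3), v1)
  expect_equal(row$index, 1)
  expect_equal(row$length, 3 * sqrt(3))
  # a LOR that misses the volume entirely
  expect_equal(length(project_lor(c(-30, 40, 0), c(30, 40, 0), vol)$index), 0)
})

test_that("projected lengths sum to the analytic chord for random LORs", {
  vol <- image_volume(c(11, 13, 7), 3.5, origin = c(-20, -22, -12))
  lo <- vol$origin; hi <- vol$origin + vol$dim * vol$voxel_size
  set.seed(66)
  for (i in 1:1000) {
    p1 <- runif(3, -60, 60); p2 <- runif(3, -60, 60)
    row <- project_lor(p1, p2, vol)
    expect_lt(abs(sum(row$length) - chord_oracle(p1, p2, lo, hi)), 1e-9)
  }
})

test_that("one-subset OSEM is exactly MLEM and iterates are non-negative", {
  s <- sim_cylinder(60, 4e3)
  grid <- virtual_pixel_grid(test_geometry(), 10)
  vol <- image_volume(c(20, 20, 8), 8)
  a <- reconstruct_mlem(s, grid, vol, n_iter = 3)
  b <- reconstruct_osem(s, grid, vol, n_iter = 3, n_subsets = 1)
  expect_identical(a$image$values, b$image$values)
  expect_true(all(a$image$values >= 0))
  # subset partition by event index is reproducible
  c1 <- reconstruct_osem(s, grid, vol, n_iter = 2, n_subsets = 3,
                         subset_rule = "index")
  c2 <- reconstruct_osem(s, grid, vol, n_iter = 2, n_subsets = 3,
                         subset_rule = "index")
  expect_identical(c1$image$values, c2$image$values)
})

test_that("the MLEM Poisson log-likelihood is non-decreasing, with and without S", {
  s <- sim_cylinder(120, 4e3)
  grid <- virtual_pixel_grid(test_geometry(), 10)
  vol <- image_volume(c(20, 20, 8), 8)
  k <- fit_coefficients(s, energy_windows("TEW"), "global", grid)
  est <- estimate_scatter(s, energy_windows("TEW"), k, grid)
  for (map in list(NULL, est$map)) {
    r <- reconstruct_mlem(s, grid, vol, scatter_map = map, n_iter = 8)
    dll <- diff(r$loglik)
    expect_true(all(dll > -1e-8 * abs(r$loglik[-length(r$loglik)])))
  }
})

test_that("a point source in air reconstructs into its single voxel", {
  geom <- test_geometry()
  grid <- virtual_pixel_grid(geom, 10)
  ph <- phantom(cylinder(c(0, 0, 0), 30, 30, "air"))
  src <- source_component("cylinder", c(0, 0, 0), 0.4, 0.4, activity = 1)
  s <- simulate_acquisition(ph, src, geom, min_accepted = 3000, seed = 17)
  vol <- image_volume(c(21, 21, 5), 10)
  r <- reconstruct_mlem(s, grid, vol, n_iter = 50)
  img <- r$image$values
  # every LOR crosses the central voxel; voxels elsewhere are seen by LORs
  # with no events, so EM drives them to zero
  expect_gt(img[11, 11, 3] / sum(img), 0.95)
})

test_that("sensitivity peaks centrally, respects ring symmetry and needs pairs", {
  geom <- test_geometry()
  grid <- virtual_pixel_grid(geom, 5)
  vol <- image_volume(c(21, 21, 5), 10)
  sens <- sensitivity_image(grid, vol, cache = FALSE)
  v <- array(sens[, 1], c(21, 21, 5))
  mid <- v[, , 3]
  expect_equal(mid[11, 11], max(mid))
  # a quarter turn (90 degrees) is a symmetry of the 20-block ring
  expect_equal(mid, t(mid[, ncol(mid):1]), tolerance = 0.02 * max(mid))
  # positive inside the FOV support
  centers <- voxel_centers(vol)
  inside <- sqrt(centers[, 1]^2 + centers[, 2]^2) < 60 & abs(centers[, 3]) < 20
  expect_true(all(sens[inside, 1] > 0))
  g0 <- scanner_geometry(min_block_sep = 10)  # only diametric pairs remain
  expect_silent(virtual_pixel_grid(g0, 10))
  g_none <- tryCatch(virtual_pixel_grid(scanner_geometry(min_block_sep = 11)),
                     error = function(e) NULL)
  if (!is.null(g_none))
    expect_error(sensitivity_image(g_none, vol, cache = FALSE), "allowed")
})

test_that("volumes serialize to raw floats with a faithful sidecar", {
  vol <- image_volume(c(4, 3, 2), 2.5)
  vol$values[] <- seq_len(24)
  f <- tempfile()
  write_volume(vol, f, "raw")
  side <- yaml::read_yaml(paste0(f, ".yaml"))
  expect_equal(unlist(side$dim), c(4, 3, 2))
  back <- readBin(f, "numeric", 24, size = 8, endian = "little")
  expect_equal(array(back, dim = vol$dim), vol$values)
  pr <- central_profile(vol)
  expect_equal(nrow(pr), 4)
})
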